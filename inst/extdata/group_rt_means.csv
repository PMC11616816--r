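group,trial_type,gate_switch,response,mean_rt_ms,sd_rt_ms,n
younger,overall,n/a,n/a,521.76,97.01,24
younger,reference,no_switch,same,476.76,91.22,24
younger,reference,no_switch,different,591.57,109.49,24
younger,reference,switch,same,508.87,125.89,24
younger,reference,switch,different,625.23,147.91,24
younger,comparison,no_switch,same,451.32,82.91,24
younger,comparison,no_switch,different,510.72,83.95,24
younger,comparison,switch,same,526.05,120.78,24
younger,comparison,switch,different,620,157.48,24
older,overall,n/a,n/a,652.41,118.5,23
older,reference,no_switch,same,577.61,113.75,23
older,reference,no_switch,different,775.32,148.79,23
older,reference,switch,same,616.38,128.51,23
older,reference,switch,different,846.95,170.7,23
older,comparison,no_switch,same,578.25,106.35,23
older,comparison,no_switch,different,652.72,114.83,23
older,comparison,switch,same,613.73,122.36,23
older,comparison,switch,different,742.3,140.36,23
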