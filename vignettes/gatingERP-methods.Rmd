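---
title: "Decomposing working-memory gating: models, simulation and inference"
author: "gatingERP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing working-memory gating: models, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatingERP)
```

# The scientific problem

The reference-back task separates four subprocesses of working-memory
gating. Letters (X or O) appear one at a time inside a red or a blue
frame. Red-framed *reference* trials require the observer to update
working memory with the current letter; blue-framed *comparison* trials
only require a match decision against the letter of the last reference
trial. Crossing the trial type with whether the frame colour just
changed (gate *switch* vs *no-switch*) and with the required response
(*same* vs *different*) yields eight conditions, and four contrasts over
them isolate:

* **updating** — no-switch reference minus no-switch comparison;
* **substitution** — (different − same | no-switch reference) minus
  (different − same | no-switch comparison), the double difference that
  isolates replacing memory content with *new* information;
* **gate opening** — switch reference minus no-switch reference;
* **gate closing** — switch comparison minus no-switch comparison.

Switch trials are excluded from the updating and substitution contrasts
so that gate toggling cannot contaminate them. The same signed weights
are applied to condition mean reaction times (giving costs in ms and
dimensionless RT-ratio indices) and to per-condition averaged ERPs
(giving difference potentials). `subprocessContrasts()` is the single
source of truth for these weights; the zero-sum property is asserted at
construction.

The RT ratio index divides each condition RT difference by the mean of
the two condition means, discounting general (e.g. age-related) slowing.
For substitution, a reference-cell ratio and a comparison-cell ratio are
computed and subtracted.

# The session generator

`generateSession()` reproduces the canonical design: nine blocks of 80
trials, reference probability .5, switch probability .25 among
gate-classifiable trials, and equal numbers of required same/different
responses. Balance is enforced by constrained resampling rather than
free i.i.d. draws: per block, a switch count is drawn from the binomial
restricted to the tolerance band (default 1.5 trials), switch positions
are resampled until the reference count lands inside the band, and
same/different assignments are balanced inside each trial-type x
gate-switch cell. Design choices where the task description is silent:

* The first trial of each block is forced to be a reference trial and is
  flagged unanalysable (no within-block predecessor); this also
  guarantees a defined required response for every later trial.
* Timing jitter is drawn uniformly from the 16.6 ms display-frame grid:
  stimulus 500 +/- 50 ms, fixation 1400 +/- 100 ms, inclusive of the grid
  endpoints.
* Whether the original design balanced same/different separately inside
  switch cells is unknowable from the published counts; we balance
  within every cell where the cell size permits, which makes the
  simulated switch-cell counts slightly more even than the published
  ranges suggest. The classifier (`classifyTrials()`) never relies on
  that balance.

# The synthetic-data model

`simulateBehaviour()` draws each RT from a shifted lognormal (shift
150 ms, log-scale spread `rtSd`) whose mean equals an additive latent
mean: base RT + group slowing + the costs triggered by the trial's
condition. The lognormal is not dictated by any task constraint; it was
chosen because it is strictly positive and right-skewed, the standard
minimal RT model. The 150 ms shift matches the task's validity floor:
faster responses are anticipations and the generator refuses parameter
sets that could produce them.

One composition choice deserves emphasis. Updating applies to all
reference trials, gate opening to switch-reference, gate closing to
switch-comparison trials — each exactly the cell set its contrast
measures, so those estimators are unbiased by construction. Substitution
is applied as a *centred* +/- cost/2 coding between different and same
responses within reference trials rather than as a one-sided surcharge
on different-reference trials. The two parameterisations produce the
same substitution contrast, but the one-sided version leaks half the
substitution cost into the updating contrast (which averages the
same/different sub-cells); the centred coding keeps the four estimators
orthogonal, which is the property the recovery tests verify. Misses
occur at a configured rate, and responses slower than the trial deadline
(stimulus duration plus the following fixation, 1900 +/- 150 ms) also
become misses; under realistic parameters the deadline censors less than
1e-4 of responses, so it does not measurably bias cell means.

`simulateEpochs()` builds each epoch as a sum of Gaussian-in-time
components (latency, width, amplitude, per-channel scalp weighting,
signed per-condition coefficients) plus spectrally shaped noise
(amplitude falling as 1/sqrt(f), the usual EEG background
approximation), with occasional single-channel step artifacts of
configurable rate and size — sufficient to exercise peak-to-peak
rejection without modelling ocular activity. Epoch sub-seeds key on
trial identity, so simulation commutes with trial reordering. What this
generator does *not* emulate: volume-conducted topographies from a head
model, ocular/muscle artifact morphology, autocorrelated single-trial
latency jitter, or non-stationary noise. Tests passing on these data
validate the pipeline's algebra and error control, not its robustness to
those real-data features.

Per-subject random effects (normal perturbations of base RT, SD 60 ms,
and of component amplitude scale, SD 0.25) create the between-subject
variance that group-level statistics operate on.

# Preprocessing

The low-pass is a Kaiser-windowed FIR (30 Hz cutoff = the −6 dB point,
beta 12.2653, i.e. a 120 dB design, 10 Hz transition band). The kernel
length is not a free parameter: it follows the Kaiser formula
`(A − 7.95) / (2.285 * dw)` from the attenuation implied by beta,
rounded up to odd length (781 taps at 1000 Hz). Zero phase is achieved
by symmetric-kernel convolution with reflection padding, so the output
is sample-aligned with the input and DC gain is exactly one. A matching
0.1 Hz high-pass (beta 5.6533, 0.2 Hz transition band) is available for
continuous data but is deliberately not applied to simulated epochs: its
kernel (about 18000 taps at 1000 Hz) is far longer than one epoch.

Epochs span −100 to 1000 ms; the mean over the 100 ms pre-stimulus
interval is the baseline. All time windows are half-open `[start, end)`
in ms, so the sample at t = 0 belongs to the post-stimulus period and
adjacent analysis windows never double-count a sample. Rejection is
peak-to-peak: an epoch is dropped iff max − min anywhere in the epoch
exceeds 100 uV on at least one channel (rejection is therefore monotone
in the threshold). Condition averages use correct-response trials only;
a subject left with fewer than `minEpochs` epochs in a required
condition raises a typed `tooFewEpochs` condition, and cohort-level code
drops that subject per effect rather than globally — slightly more
data-retentive than excluding the participant outright, and logged in
the report.

# Inference

**tmax permutation test.** For each difference potential, a one-sample
t is computed at every electrode x time point; the null is built by
sign-flipping whole subjects and recording the maximum |t| over the
family per permutation, which controls familywise error at the declared
alpha without sphericity or smoothness assumptions. Implementation
details that matter: corrected p-values use the add-one convention
`(1 + b)/(1 + nPerm)` so they are valid at any permutation count; when
all `2^n` sign patterns fit the permutation budget the test enumerates
them exhaustively and p-values are exact; zero-variance points are
excluded from the family (not assigned infinite t); a relative tie
tolerance of 1e-9 on the |t| comparison keeps the identity permutation
counted at the family maximum in floating point. The inferential output
is the point-wise corrected p-map; contiguous significant runs
(`significantRuns()`) are descriptive only. No cluster-mass statistic is
formed: the point-wise tmax already provides the familywise guarantee,
and run extents are reported as descriptions, not inferences.

**Window ANOVAs.** Mean amplitudes over the per-subprocess windows
(updating 80–180, 300–400, 400–1000 ms; substitution 250–600,
550–750 ms; gate opening 150–250, 300–500, 500–700 ms; gate closing
150–300, 300–600 ms) at the midline sites Fz/Cz/Pz/Oz enter a split-plot
ANOVA with ANTERIORITY within and GROUP between. Sums of squares are the
classical sequential decomposition; Greenhouse–Geisser epsilon is
computed from the pooled within-group covariance of the level scores and
is reported always, with corrected p-values alongside the uncorrected
ones (the alternative — correcting only when a sphericity pre-test
fires — makes the reported p depend on a second, noisier test). Effect
size is partial eta squared.

**Bayes factors.** The JZS t-test Bayes factor uses the Cauchy(0,
0.707) prior on standardized effect size, computed by one-dimensional
quadrature over the inverse-gamma mixing variable (relative tolerance
1e-10); the unit tests pin it to an independent noncentral-t quadrature
to four significant figures. ANOVA inclusion Bayes factors are
approximated by BIC: candidate fixed-effect structures respecting
marginality are fitted by maximum likelihood with a subject random
intercept, per-model marginal likelihoods are `exp(-BIC/2)`, and each
effect is compared across matched models. This is a deliberate,
documented approximation to the default-prior ANOVA Bayes factor — it
tracks direction and order of magnitude, not the exact matched-prior
value, and no acceptance check treats it as exact.

**Nonparametric comparisons.** Group comparisons of cost and ratio
scores use the Mann–Whitney U with midrank ties (exact p for small
tie-free samples) and the rank-biserial correlation `2U/(n1 n2) − 1` as
effect size, alongside the JZS BF.

# Source analysis

The source model is deliberately synthetic: sensors on the upper unit
sphere, sources in a concentric ball, and the quasi-static
current-dipole kernel for the gain — smooth, deterministic given the
seed, and full row rank after average-reference projection. On top of it
sits the standardized minimum-norm inverse: `J = L'(LL' + lambda H)^+ d`
with `H` the average-reference projector, and per-source standardized
power `J_i' S_ii^{-1} J_i` with `S_ii` the 3 x 3 block of the resolution
variance `L'(LL' + lambda H)^+ L`. This standardization has the
zero-localization-error property for noiseless point sources, which the
tests verify over 50 random dipoles. `lambda` is expressed relative to
the mean eigenvalue of `LL'`; the default 1e-8 is effectively the
noiseless limit, and noisy data should raise it to the noise-to-signal
power ratio (discrepancy principle). Group comparisons run a per-source
label-permutation t-test, Benjamini–Hochberg FDR at .01, and discard
contiguous runs (in source index, the 1-D analogue of a voxel-extent
rule) shorter than five sources. "Normalized to baseline and flattened"
is implemented as: standardized power of the window topography divided
by mean baseline-window power, orientations collapsed by the
standardization itself. Real anatomy, template head models and region
labelling are out of scope.

# Problem sizes and numerical choices

The default `studyConfig()` simulates 24 + 23 subjects, nine 80-trial
blocks each, on the 12-channel analysis montage at 250 Hz — sizes chosen
so a full `runStudy()` completes in a few minutes on one core while
every statistic keeps its designed operating characteristics; the
1000 Hz, 32-channel geometry is available through `erpTemplate()` when
fidelity to the recording configuration matters. The tmax tests default
to 10000 permutations. Deeper calibration checks live in the test suite
at sizes matching the design (e.g. familywise error over 200 null
cohorts of 24 subjects on a 12 x 1001 grid; cost recovery over 50
replicate cohorts), and every stochastic path is seeded: the same
configuration reproduces the same report bit for bit.

Degenerate inputs are handled explicitly rather than silently: designs
whose balance constraints are infeasible raise a constraint error;
latent mean RTs at or below the 150 ms floor refuse to simulate;
zero-variance data refuse a t statistic; a singular regularized system
advises a positive lambda; missing condition cells name the condition.

# Known limitations

* The BIC inclusion Bayes factor is an approximation; studies needing
  the matched-prior value should compute it externally.
* The epoch simulator's artifact model (single-channel steps) exercises
  peak-to-peak rejection but not ICA-style ocular correction, which is
  intentionally absent.
* The 1-D extent rule in source space is a stand-in for 3-D cluster
  extent on a real cortical mesh.
* Behavioural and ERP effect sizes in `defaultErpTemplate()` and the
  default behaviour parameters are calibrated to published group-level
  summaries of this task family, not fitted to any single-trial dataset.
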