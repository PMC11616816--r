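test_that("Kaiser FIR kernel meets its design targets", {
    h <- designKaiserFir(30, 1000, beta = 12.2653,
                         transitionBandwidth = 10)
    expect_true(length(h) %% 2 == 1)
    expect_equal(h, rev(h))                       # linear phase
    gain <- gatingERP:::kernelGain(h, c(0, 30, 29, 31, 50), 1000)
    expect_equal(gain[1L], 1, tolerance = 1e-9)   # unit DC gain
    # -6 dB point within 1 Hz of the cutoff
    expect_lt(abs(gain[2L] - 10^(-6 / 20)), 0.01)
    expect_gt(gain[3L], gain[2L])
    expect_lt(gain[4L], gain[2L])
    # deep stopband for the 120 dB design
    expect_lt(gain[5L], 1e-4)
    # beta = 0 degenerates to the rectangular-windowed sinc
    h0 <- designKaiserFir(30, 1000, beta = 0, transitionBandwidth = 10)
    m <- (length(h0) - 1) / 2
    nn <- seq(-m, m)
    sinc <- 0.06 * ifelse(nn == 0, 1, sin(2 * pi * 0.03 * nn) /
                              (2 * pi * 0.03 * nn))
    expect_equal(h0, sinc / sum(sinc), tolerance = 1e-12)
    expect_error(designKaiserFir(600, 1000), "Nyquist")
})

test_that("zero-phase filtering preserves alignment, DC and impulses", {
    h <- designKaiserFir(30, 500, beta = 7, transitionBandwidth = 20)
    n <- 600
    expect_equal(applyZeroPhase(rep(2.5, n), h), rep(2.5, n),
                 tolerance = 1e-6)
    # impulse comes back as the centred kernel
    x <- numeric(n); x[300] <- 1
    y <- applyZeroPhase(x, h)
    m <- (length(h) - 1) / 2
    expect_equal(y[(300 - m):(300 + m)], h, tolerance = 1e-12)
    # sinusoid attenuated by the kernel's own gain at that frequency
    f <- 60
    x <- sin(2 * pi * f * (0:(n - 1)) / 500)
    y <- applyZeroPhase(x, h)
    g <- gatingERP:::kernelGain(h, f, 500)
    expect_lt(abs(max(abs(y[200:400])) - g) / max(g, 1e-12), 0.05)
    expect_error(applyZeroPhase(numeric(10), h), "longer")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
    # constant epochs go to zero
    es <- epochSet(array(5, c(3, 2, 220)), sfreq = 200, tmin = -100)
    expect_equal(max(abs(epochData(baselineCorrect(es)))), 0)
    # linear ramp crossing zero at the centre of the (half-open)
    # baseline window is left unchanged
    times <- seq(-100, 995, by = 5)
    ramp <- times + 52.5
    es2 <- epochSet(array(rep(ramp, each = 2), c(1, 2, length(times))),
                    sfreq = 200, times = times)
    bc2 <- baselineCorrect(es2, c(-100, 0))
    expect_equal(epochData(bc2), epochData(es2), tolerance = 1e-9)
    # random epochs: all per-channel baseline means below 1e-9
    set.seed(11)
    es3 <- epochSet(array(rnorm(10 * 4 * 220, 3, 10), c(10, 4, 220)),
                    sfreq = 200, tmin = -100)
    bl <- apply(epochData(baselineCorrect(es3))[, , 1:20, drop = FALSE],
                c(1, 2), mean)
    expect_lt(max(abs(bl)), 1e-9)
    expect_error(baselineCorrect(es3, c(-500, -300)), "no samples")
})

test_that("peak-to-peak rejection is exact and monotone in threshold", {
    dat <- array(0, c(4, 2, 100))
    dat[2, 1, 51:100] <- 150          # 150 uV step on one channel
    dat[3, 2, ] <- seq(0, 99)         # 99 uV ramp: below threshold
    es <- epochSet(dat, sfreq = 100, tmin = -100)
    rej <- rejectArtifacts(es, threshold = 100)
    expect_equal(rej$rejected, c(FALSE, TRUE, FALSE, FALSE))
    expect_equal(nEpochs(rej$kept), 3L)
    # monotonicity over random epochs
    set.seed(12)
    es2 <- epochSet(array(rnorm(40 * 3 * 50, 0, 40), c(40, 3, 50)),
                    sfreq = 100, tmin = -100)
    r100 <- rejectArtifacts(es2, 100)$rejected
    r120 <- rejectArtifacts(es2, 120)$rejected
    expect_true(all(r100[r120]))      # rejections(120) subset of (100)
})

test_that("condition averaging uses correct trials and flags sparse cells", {
    trials <- smallSession(seed = 13, nBlocks = 1, trialsPerBlock = 20)
    tpl <- oneComponentTemplate(c(reference.no_switch.same = 1))
    es <- simulateEpochs(trials, tpl, seed = 1)
    # two identical epochs average to themselves
    ev <- averageConditions(es, correctOnly = FALSE)
    lab <- trialInfo(es)$label
    pick <- which(lab == "reference.no_switch.same")
    expect_equal(ev[["reference.no_switch.same"]]@data,
                 epochData(es)[pick[1L], , ], tolerance = 1e-12)
    expect_equal(nEpochs(ev[["reference.no_switch.same"]]),
                 length(pick))
    # incorrect trials excluded: +1 correct vs -1 incorrect
    dat <- array(c(1, -1), c(2, 1, 10))
    dat[1, , ] <- 1; dat[2, , ] <- -1
    info <- data.frame(label = "comparison.no_switch.same",
                       correct = c(TRUE, FALSE), rt_ms = c(400, 500))
    esc <- epochSet(dat, sfreq = 100, tmin = -50, trialInfo = info)
    avg <- averageConditions(esc, correctOnly = TRUE)
    expect_equal(unique(as.vector(
        avg[["comparison.no_switch.same"]]@data)), 1)
    # missing required condition raises the exclusion signal
    expect_error(
        averageConditions(esc, require = conditionLabels()),
        class = "tooFewEpochs")
})

test_that("filtering and averaging commute (linearity)", {
    set.seed(14)
    trials <- smallSession(seed = 14, nBlocks = 1, trialsPerBlock = 12)
    tpl <- oneComponentTemplate(c(reference.no_switch.same = 1),
                                noiseSd = 5)
    es <- simulateEpochs(trials, tpl, seed = 3)
    h <- designKaiserFir(30, 200, beta = 7, transitionBandwidth = 15)
    evFiltFirst <- averageConditions(applyZeroPhase(es, h),
                                     correctOnly = FALSE)
    evAvgFirst <- averageConditions(es, correctOnly = FALSE)
    for (lab in names(evAvgFirst)) {
        filtered <- applyZeroPhase(t(evAvgFirst[[lab]]@data), h)
        expect_equal(evFiltFirst[[lab]]@data, t(filtered),
                     tolerance = 1e-6)
    }
})

test_that("simulated epoch counts per condition match the design ranges", {
    # at the full design with realistic error/artifact rates, surviving
    # correct-epoch counts land in plausible per-condition ranges:
    # roughly 60-135 for no-switch cells and 11-55 for switch cells
    trials <- generateSession(sessionDesign(seed = 21))
    beh <- simulateBehaviour(trials, behaviourParams(), seed = 21)
    counts <- table(beh$label[beh$correct & !is.na(beh$correct)])
    ns <- counts[grep("no_switch", names(counts))]
    sw <- counts[grep("\\.switch", names(counts))]
    expect_true(all(ns >= 60 & ns <= 135))
    expect_true(all(sw >= 11 & sw <= 55))
})
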