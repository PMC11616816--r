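test_that("contrast weights are zero-sum and correctly signed", {
    w <- subprocessContrasts()
    expect_named(w, c("updating", "substitution", "gate_opening",
                      "gate_closing"))
    for (cw in w) expect_equal(sum(cw), 0)
    expect_equal(unname(w$substitution["reference.no_switch.different"]),
                 1)
    expect_equal(unname(w$substitution["comparison.no_switch.same"]), 1)
    # switch cells never enter updating or substitution
    swCells <- grep("\\.switch\\.", conditionLabels(), value = TRUE)
    expect_true(all(w$updating[swCells] == 0))
    expect_true(all(w$substitution[swCells] == 0))
})

test_that("cell-mean arithmetic reproduces the published group costs", {
    means <- exampleGroupRtMeans()
    young <- rtCostsFromCellMeans(cellMeanVector(means, "younger"))
    old <- rtCostsFromCellMeans(cellMeanVector(means, "older"))
    subY <- young$cost_ms[young$subprocess == "substitution"]
    subO <- old$cost_ms[old$subprocess == "substitution"]
    # independent arithmetic from the printed cells
    expect_equal(subY, (591.57 - 476.76) - (510.72 - 451.32),
                 tolerance = 1e-12)
    expect_equal(subO, (775.32 - 577.61) - (652.72 - 578.25),
                 tolerance = 1e-12)
    ratY <- young$ratio[young$subprocess == "substitution"]
    ratO <- old$ratio[old$subprocess == "substitution"]
    expect_equal(ratY,
                 (591.57 - 476.76) / ((591.57 + 476.76) / 2) -
                     (510.72 - 451.32) / ((510.72 + 451.32) / 2),
                 tolerance = 1e-12)
    expect_equal(ratO, 0.171275, tolerance = 1e-4)
    # all-equal means give zero everywhere
    flat <- rtCostsFromCellMeans(
        stats::setNames(rep(600, 8), conditionLabels()))
    expect_true(all(flat$cost_ms == 0) && all(flat$ratio == 0))
})

test_that("trial-level costs honour filters and per-effect exclusion", {
    trials <- smallSession(seed = 31)
    p <- behaviourParams(baseRt = 500, costUpdating = 40,
                         costSubstitution = 60, costGateOpening = 20,
                         costGateClosing = 30, rtSd = 0, pIncorrect = 0,
                         pMiss = 0)
    beh <- simulateBehaviour(trials, p, seed = 1)
    beh$subject <- "s1"
    costs <- rtCosts(beh)
    got <- stats::setNames(costs$cost_ms, costs$subprocess)
    expect_equal(unname(got["updating"]), 40, tolerance = 1e-9)
    expect_equal(unname(got["substitution"]), 60, tolerance = 1e-9)
    expect_equal(unname(got["gate_opening"]), 20, tolerance = 1e-9)
    expect_equal(unname(got["gate_closing"]), 30, tolerance = 1e-9)
    # subject missing a switch cell is NA for gating but kept for the rest
    beh2 <- beh[!(beh$label %in% c("reference.switch.same",
                                   "reference.switch.different")), ]
    costs2 <- rtCosts(beh2)
    expect_true(is.na(costs2$cost_ms[costs2$subprocess ==
                                         "gate_opening"]))
    expect_false(is.na(costs2$cost_ms[costs2$subprocess == "updating"]))
})

test_that("difference potentials isolate their generating component", {
    trials <- smallSession(seed = 32)
    tpl <- oneComponentTemplate(
        c(reference.no_switch.same = 1,
          reference.no_switch.different = 1))
    es <- simulateEpochs(trials, tpl, seed = 1)
    ev <- averageConditions(es, correctOnly = FALSE)
    diffs <- differencePotentials(ev)
    times <- epochTimes(es)
    bump <- outer(seq(1, 0.25, length.out = 4),
                  2 * exp(-(times - 300)^2 / (2 * 60^2)))
    expect_equal(diffs$updating, bump, tolerance = 1e-9)
    expect_lt(max(abs(diffs$substitution)), 1e-9)
    expect_lt(max(abs(diffs$gate_closing)), 1e-9)
    # gate opening sees the component with a minus sign (no-switch side)
    expect_equal(diffs$gate_opening, -bump, tolerance = 1e-9)
})

test_that("difference potentials are linear and report missing cells", {
    mk <- function(val) {
        labs <- conditionLabels()
        out <- lapply(seq_along(labs), function(i)
            new("Evoked", condition = labs[i],
                data = matrix(val[i], 2, 5), nEpochs = 1L,
                times = 1:5, channelLabels = c("a", "b"),
                subjectId = "s"))
        stats::setNames(out, labs)
    }
    v1 <- c(1, 2, 3, 4, 5, 6, 7, 8)
    v2 <- c(2, 1, 0, -1, 3, 5, -2, 0)
    d1 <- differencePotentials(mk(v1))
    d2 <- differencePotentials(mk(v2))
    d12 <- differencePotentials(mk(2 * v1 + 3 * v2))
    for (sp in names(d1))
        expect_equal(d12[[sp]], 2 * d1[[sp]] + 3 * d2[[sp]],
                     tolerance = 1e-12)
    # substitution on unit impulses: (b - a) - (d - c)
    labs <- conditionLabels()
    v <- stats::setNames(numeric(8), labs)
    v["reference.no_switch.same"] <- 1      # a
    v["reference.no_switch.different"] <- 2 # b
    v["comparison.no_switch.same"] <- 3     # c
    v["comparison.no_switch.different"] <- 5 # d
    ds <- differencePotentials(mk(unname(v[labs])))
    expect_equal(unique(as.vector(ds$substitution)), (2 - 1) - (5 - 3))
    expect_error(differencePotentials(mk(v1)[-1L]),
                 "reference.no_switch.same")
})

test_that("window means integrate correctly over half-open windows", {
    times <- seq(-100, 995, by = 5)
    flat <- matrix(1, 2, length(times),
                   dimnames = list(c("Fz", "Oz"), NULL))
    expect_equal(unname(windowMean(flat, times, c(80, 180))), c(1, 1))
    # triangular wave: mean equals analytic integral / width
    tri <- pmax(0, 1 - abs(times - 400) / 100)
    m <- windowMean(matrix(tri, 1, length(times)), times, c(300, 500),
                    channelLabels = "Oz")
    samples <- tri[times >= 300 & times < 500]
    expect_equal(unname(m), mean(samples), tolerance = 1e-12)
    expect_lt(abs(m - 0.5), 0.03)   # 1/2 base*height over the window
    expect_error(windowMean(flat, times, c(80, 180),
                            electrodes = "Cz"), "unknown electrode")
    # the canonical updating windows are all accepted
    for (w in analysisWindows()$updating)
        expect_silent(windowMean(flat, times, w))
})

test_that("cohort cost recovery is unbiased for known generating costs", {
    # 12 replicate cohorts here (the deeper 50-replicate recovery runs in
    # the acceptance suite); bias must stay within Monte Carlo error
    truth <- c(updating = 45, substitution = 90, gate_opening = 35,
               gate_closing = 75)
    reps <- 12
    est <- matrix(NA_real_, reps, 4,
                  dimnames = list(NULL, names(truth)))
    se <- matrix(NA_real_, reps, 4,
                 dimnames = list(NULL, names(truth)))
    for (r in seq_len(reps)) {
        co <- simulateCohort(8, sessionDesign(nBlocks = 4,
                                              trialsPerBlock = 80),
                             behaviourParams(costUpdating = 45,
                                             costSubstitution = 90,
                                             costGateOpening = 35,
                                             costGateClosing = 75),
                             template = NULL, seed = 4000 + r)
        costs <- rtCosts(co$behaviour)
        agg <- tapply(costs$cost_ms, costs$subprocess, mean,
                      na.rm = TRUE)
        spread <- tapply(costs$cost_ms, costs$subprocess,
                         function(v) stats::sd(v, na.rm = TRUE) /
                             sqrt(sum(!is.na(v))))
        est[r, ] <- agg[names(truth)]
        se[r, ] <- spread[names(truth)]
    }
    # expectation recovered within the cohort estimator's standard error
    for (sp in names(truth))
        expect_lt(abs(mean(est[, sp]) - truth[[sp]]),
                  2 * mean(se[, sp]))
})
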