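smallConfig <- function(seed = 17, sourceAnalysis = FALSE)
    studyConfig(nYounger = 3, nOlder = 3,
                design = sessionDesign(nBlocks = 2, trialsPerBlock = 40),
                sfreq = 125, nPerm = 200, nSources = 16,
                minEpochs = 1, sourceAnalysis = sourceAnalysis,
                seed = seed)

test_that("the full pipeline is deterministic given its configuration", {
    r1 <- runStudy(smallConfig())
    r2 <- runStudy(smallConfig())
    expect_identical(r1@rtTable, r2@rtTable)
    expect_identical(r1@behaviouralStats, r2@behaviouralStats)
    expect_identical(r1@erpStats, r2@erpStats)
    expect_identical(r1@costs, r2@costs)
    for (nm in names(r1@tmax))
        expect_identical(r1@tmax[[nm]]@pMap, r2@tmax[[nm]]@pMap)
    # a different seed changes the numbers but not the table shapes
    r3 <- runStudy(smallConfig(seed = 18))
    expect_identical(dim(r3@erpStats), dim(r1@erpStats))
    expect_identical(names(r3@tmax), names(r1@tmax))
    expect_false(identical(r3@rtTable$mean_rt_ms,
                           r1@rtTable$mean_rt_ms))
})

test_that("report tables have the expected structure", {
    rep <- runStudy(smallConfig())
    expect_setequal(unique(rep@rtTable$group), c("younger", "older"))
    expect_true(all(conditionLabels() %in% rep@rtTable$condition))
    expect_setequal(unique(rep@behaviouralStats$subprocess),
                    c("updating", "substitution", "gate_opening",
                      "gate_closing"))
    expect_setequal(unique(rep@behaviouralStats$measure),
                    c("cost_ms", "ratio"))
    # one ANOVA row triplet per subprocess x window
    nWin <- length(unlist(analysisWindows(), recursive = FALSE))
    expect_equal(nrow(rep@erpStats), 3L * nWin)
    expect_equal(length(rep@tmax), 8L)   # 2 groups x 4 subprocesses
})

test_that("accuracy summary partitions trials exactly", {
    cfg <- smallConfig()
    co <- simulateCohort(3, cfg$design, cfg$paramsYounger,
                         template = NULL, seed = 3,
                         groupLabel = "younger")
    beh <- do.call(rbind, co$behaviour)
    beh$group <- "younger"
    acc <- accuracySummary(beh)
    expect_equal(acc$accuracy_pct + acc$incorrect_pct + acc$miss_pct,
                 100, tolerance = 1e-9)
    # error-free simulation: 100 percent accuracy, no misses
    perfect <- simulateBehaviour(
        smallSession(seed = 41),
        behaviourParams(pIncorrect = 0, pMiss = 0), seed = 1)
    perfect$group <- "g"
    accP <- accuracySummary(perfect)
    expect_equal(accP$accuracy_pct, 100)
    expect_equal(accP$miss_pct, 0)
})

test_that("a null configuration produces null-looking results", {
    cfg <- smallConfig(seed = 23)
    flat <- behaviourParams(baseRt = 500, costUpdating = 0,
                            costSubstitution = 0, costGateOpening = 0,
                            costGateClosing = 0, rtSd = 0.15,
                            pIncorrect = 0.05, pMiss = 0.02)
    noComp <- erpTemplate(components = list(),
                          channelLabels = cfg$channels, noiseSd = 6,
                          artifactRate = 0.02, sfreq = 125)
    cfg$paramsYounger <- flat
    cfg$paramsOlder <- flat
    cfg$templateYounger <- noComp
    cfg$templateOlder <- noComp
    rep <- runStudy(cfg)
    costs <- rep@behaviouralStats[rep@behaviouralStats$measure ==
                                      "cost_ms", ]
    expect_lt(max(abs(c(costs$mean_younger, costs$mean_older))), 25)
    sigFrac <- mean(vapply(rep@tmax, function(r)
        any(r@significantMask), logical(1)))
    expect_lt(sigFrac, 0.5)
})

test_that("epoch containers round-trip through the directory format", {
    trials <- smallSession(seed = 42, nBlocks = 1, trialsPerBlock = 12)
    tpl <- oneComponentTemplate(c(reference.no_switch.same = 1),
                                noiseSd = 2)
    es <- simulateEpochs(trials, tpl,
                         behaviour = simulateBehaviour(
                             trials, behaviourParams(), seed = 2),
                         seed = 1)
    dir <- tempfile("epochs")
    writeEpochSet(es, dir)
    back <- readEpochSet(dir)
    expect_equal(epochData(back), epochData(es), tolerance = 1e-6)
    expect_equal(epochTimes(back), epochTimes(es))
    expect_equal(channelNames(back), channelNames(es))
    expect_equal(trialInfo(back)$label, trialInfo(es)$label)
    expect_equal(samplingRate(back), samplingRate(es))
})

test_that("YAML configurations override defaults faithfully", {
    path <- tempfile(fileext = ".yaml")
    writeLines(c(
        "nYounger: 4", "nOlder: 5", "seed: 7", "nPerm: 123",
        "design:", "  nBlocks: 2", "  trialsPerBlock: 20",
        "  seed: 3",
        "paramsYounger:", "  baseRt: 470", "  costSubstitution: 60",
        "filter:", "  lowpass:", "    cutoff: 25",
        "    kaiserBeta: 7.0", "    transitionBandwidth: 8"), path)
    cfg <- readStudyConfig(path)
    expect_equal(cfg$nYounger, 4L)
    expect_equal(cfg$nOlder, 5L)
    expect_equal(cfg$nPerm, 123L)
    expect_equal(cfg$design@trialsPerBlock, 20L)
    expect_equal(cfg$paramsYounger$baseRt, 470)
    expect_equal(cfg$paramsYounger$costSubstitution, 60)
    expect_equal(cfg$lowpass$cutoff, 25)
    # defaults survive where unspecified
    expect_equal(cfg$paramsOlder$costSubstitution, 123)
    expect_equal(cfg$alpha, 0.05)
})
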