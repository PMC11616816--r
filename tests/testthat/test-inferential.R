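test_that("tmax p-maps equal exhaustive sign-flip enumeration", {
    set.seed(41)
    X <- array(rnorm(8 * 3 * 5, 0.5), c(8, 3, 5))
    res <- tmaxTest(X, nPerm = 256)
    expect_true(res@exhaustive)
    oracle <- bruteForceTmax(matrix(X, 8))
    expect_equal(as.vector(res@pMap), oracle$p, tolerance = 1e-12)
    expect_equal(as.vector(res@tObserved), oracle$t, tolerance = 1e-9)
    expect_true(all(res@significantMask == (res@pMap <= 0.05)))
})

test_that("tmax handles degenerate input as specified", {
    expect_error(tmaxTest(matrix(0, 6, 10)), "zero variance")
    # one flat point is excluded, the rest analysed
    set.seed(42)
    X <- matrix(rnorm(60), 6, 10)
    X[, 4] <- 2
    res <- tmaxTest(X, nPerm = 64)
    expect_true(res@excluded[1, 4])
    expect_equal(sum(res@excluded), 1L)
    expect_equal(res@pMap[1, 4], 1)
    # fixed seed reproduces bit-identically in random mode
    set.seed(43)
    Y <- matrix(rnorm(26 * 8), 26, 8)
    r1 <- tmaxTest(Y, nPerm = 500, seed = 9)
    r2 <- tmaxTest(Y, nPerm = 500, seed = 9)
    expect_identical(r1@pMap, r2@pMap)
    expect_identical(r1@tmaxNull, r2@tmaxNull)
})

test_that("significant runs summarise the mask per channel", {
    mask <- matrix(FALSE, 2, 10)
    mask[1, 3:5] <- TRUE; mask[2, 8:10] <- TRUE
    res <- new("PermutationResult", tObserved = matrix(0, 2, 10),
               tmaxNull = 1, criticalValue = 1,
               pMap = ifelse(mask, 0.01, 0.5), significantMask = mask,
               excluded = matrix(FALSE, 2, 10), nPermutations = 100L,
               alpha = 0.05, exhaustive = FALSE)
    runs <- significantRuns(res)
    expect_equal(nrow(runs), 2L)
    expect_equal(runs$startSample, c(3L, 8L))
    expect_equal(runs$endSample, c(5L, 10L))
})

test_that("mixed ANOVA agrees with the brute-force SS oracle", {
    for (s in 1:6) {
        set.seed(600 + s)
        n1 <- sample(5:9, 1); n2 <- sample(5:9, 1)
        subj <- sprintf("s%02d", seq_len(n1 + n2))
        d <- expand.grid(subject = subj,
                         electrode = c("Fz", "Cz", "Pz", "Oz"))
        d$group <- ifelse(match(d$subject, subj) <= n1, "younger",
                          "older")
        d$amplitude <- rnorm(nrow(d), sd = 2) +
            0.6 * as.integer(factor(d$electrode)) +
            (d$group == "younger") *
                (0.8 + 0.3 * (d$electrode == "Oz"))
        an <- mixedAnova(d)
        o <- splitPlotOracle(d)
        expect_equal(an$F[an$effect == "between"], o$FA,
                     tolerance = 1e-8)
        expect_equal(an$F[an$effect == "within"], o$FW,
                     tolerance = 1e-8)
        expect_equal(an$F[an$effect == "between:within"], o$FI,
                     tolerance = 1e-8)
        expect_equal(an$ggEpsilon[an$effect == "within"], o$eps,
                     tolerance = 1e-8)
        expect_equal(an$partialEtaSq,
                     c(o$petaA, o$petaW, o$petaI), tolerance = 1e-8)
        # between df and epsilon bounds
        expect_equal(an$dfDen[an$effect == "between"], n1 + n2 - 2)
        eps <- an$ggEpsilon[an$effect == "within"]
        expect_true(eps >= 1 / 3 - 1e-12 && eps <= 1 + 1e-12)
        # GG correction never lowers the p-value in the standard case
        expect_true(an$pGG[2] >= an$p[2] - 1e-12)
    }
})

test_that("ANOVA identities and degenerate designs behave", {
    # identical groups: between F near zero
    set.seed(51)
    base <- rnorm(6)
    d <- expand.grid(subject = sprintf("s%d", 1:12),
                     electrode = paste0("e", 1:4))
    d$group <- rep(rep(c("a", "b"), each = 6), 4)
    d$amplitude <- rep(c(base, base), 4) +
        0.5 * as.integer(factor(d$electrode))
    an <- mixedAnova(d)
    expect_lt(an$F[an$effect == "between"], 1e-20)
    # compound-symmetric covariance: epsilon near 1
    set.seed(52)
    nS <- 120
    subjEff <- rnorm(nS, 0, 2)
    d2 <- expand.grid(subject = sprintf("s%03d", 1:nS),
                      electrode = paste0("e", 1:4))
    d2$group <- rep(rep(c("a", "b"), each = nS / 2), 4)
    d2$amplitude <- subjEff[match(d2$subject,
                                  sprintf("s%03d", 1:nS))] +
        rnorm(nrow(d2))
    an2 <- mixedAnova(d2)
    expect_gt(an2$ggEpsilon[2], 0.9)
    # unbalanced within-factor is refused
    expect_error(mixedAnova(d2[-1L, ]), "exactly one observation")
})

test_that("Bonferroni post-hocs scale and cap raw p-values", {
    set.seed(53)
    m <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, c("Fz", "Cz", "Pz", "Oz")))
    ph <- bonferroniPosthoc(m)
    expect_equal(nrow(ph), 6L)          # 4 levels -> 6 pairs
    expect_equal(unique(ph$m), 6)
    expect_equal(ph$pAdjusted, pmin(1, 6 * ph$p))
    # one comparison: adjusted equals raw
    ph1 <- bonferroniPosthoc(m[, 1:2])
    expect_equal(ph1$pAdjusted, ph1$p)
    # capped at 1
    expect_true(all(ph$pAdjusted <= 1))
})

test_that("JZS Bayes factors match the noncentral-t oracle", {
    set.seed(54)
    cases <- data.frame(t = runif(20, -4.5, 4.5),
                        n1 = sample(5:40, 20, replace = TRUE))
    cases$n2 <- ifelse(seq_len(20) %% 2 == 0,
                       sample(5:40, 20, replace = TRUE), NA)
    for (i in seq_len(20)) {
        n2 <- if (is.na(cases$n2[i])) NULL else cases$n2[i]
        got <- jzsBfFromT(cases$t[i], cases$n1[i], n2)$bf10
        want <- jzsOracle(cases$t[i], cases$n1[i], n2)
        expect_lt(abs(got - want) / want, 1e-4)   # 4 significant figures
    }
    # null favoured at zero effect, for any n
    for (n in c(5, 24, 100))
        expect_lt(jzsBfFromT(0, n)$bf10, 1)
    # strictly increasing in |t| at fixed n
    grid <- seq(0, 6, by = 0.25)
    bfs <- vapply(grid, function(tv) jzsBfFromT(tv, 24)$bf10,
                  numeric(1))
    expect_true(all(diff(bfs) > 0))
    # data interface agrees with the t interface
    set.seed(55)
    x <- rnorm(18, 0.6); y <- rnorm(15)
    tv <- stats::t.test(x, y, var.equal = TRUE)$statistic
    expect_equal(jzsBfTtest(x, y)$bf10,
                 jzsBfFromT(unname(tv), 18, 15)$bf10, tolerance = 1e-9)
    expect_error(jzsBfTtest(rep(1, 5)), "zero variance")
})

test_that("Mann-Whitney matches exhaustive enumeration and edge cases", {
    expect_equal(mannWhitney(c(1, 2, 3), c(4, 5, 6))$rankBiserial, -1)
    expect_equal(mannWhitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
    same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_equal(same$rankBiserial, 0)
    # exact p equals enumeration over all C(12, 6) group assignments
    set.seed(56)
    x <- rnorm(6); y <- rnorm(6, 0.8)
    got <- mannWhitney(x, y)
    pool <- c(x, y)
    combs <- utils::combn(12, 6)
    uFor <- function(idx) {
        r <- rank(pool)
        sum(r[idx]) - 6 * 7 / 2
    }
    uAll <- apply(combs, 2, uFor)
    uObs <- uFor(1:6)
    pEnum <- mean(abs(uAll - 18) >= abs(uObs - 18))  # two-tailed around E[U]
    expect_equal(got$U, uObs)
    expect_equal(got$p, pEnum, tolerance = 1e-12)
})

test_that("BIC inclusion Bayes factors track simulated effects", {
    mkData <- function(effect, seed) {
        set.seed(seed)
        d <- expand.grid(subject = sprintf("s%02d", 1:16),
                         electrode = paste0("e", 1:4))
        d$group <- rep(rep(c("a", "b"), each = 8), 4)
        d$amplitude <- rnorm(nrow(d), sd = 0.8) +
            effect * (d$group == "a")
        d
    }
    # huge between effect: decisive inclusion
    bfBig <- bfInclusion(mkData(4, 61))
    expect_gt(bfBig$bfIncl[bfBig$effect == "between"], 3)
    # null data: median inclusion BF below 1 across replicates
    meds <- vapply(1:10, function(s)
        bfInclusion(mkData(0, 70 + s))$bfIncl[1], numeric(1))
    expect_lt(stats::median(meds), 1)
})

test_that("familywise error stays controlled under the null", {
    # moderate-size null check; the full-scale 200-replicate simulation
    # at the 12 x 1001 grid runs in the acceptance suite
    reps <- 60
    rejected <- logical(reps)
    for (r in seq_len(reps)) {
        set.seed(800 + r)
        X <- array(rnorm(12 * 4 * 50), c(12, 4, 50))
        res <- tmaxTest(X, nPerm = 500, seed = r)
        rejected[r] <- any(res@significantMask)
    }
    # not significantly above the nominal .05 level
    expect_gt(stats::binom.test(sum(rejected), reps, 0.05,
                                alternative = "greater")$p.value,
              0.01)
})
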