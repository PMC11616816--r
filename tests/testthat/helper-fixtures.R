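# Shared fixtures, built in code at test time.

# the five-trial worked example: X/red, X/blue, O/blue, O/red, O/red
workedExampleTrials <- function() {
    data.frame(block = 1L, trial = 1:5,
               frame = c("reference", "comparison", "comparison",
                         "reference", "reference"),
               letter = c("X", "X", "O", "O", "O"),
               stringsAsFactors = FALSE)
}

# tiny noise-free template with a single component
oneComponentTemplate <- function(conditionWeights, nCh = 4, amplitude = 2,
                                 latencyMs = 300, widthMs = 60,
                                 noiseSd = 0, artifactRate = 0,
                                 sfreq = 200) {
    erpTemplate(components = list(list(
        label = "probe", latencyMs = latencyMs, widthMs = widthMs,
        amplitude = amplitude,
        channelWeights = seq(1, 0.25, length.out = nCh),
        conditionWeights = conditionWeights)),
        channelLabels = paste0("ch", seq_len(nCh)),
        noiseSd = noiseSd, noiseSpectrum = "white",
        artifactRate = artifactRate, sfreq = sfreq)
}

# small classified session
smallSession <- function(seed = 1, nBlocks = 2, trialsPerBlock = 40) {
    generateSession(sessionDesign(nBlocks = nBlocks,
                                  trialsPerBlock = trialsPerBlock,
                                  seed = seed))
}

# independent brute-force one-sample tmax enumeration for n <= 12
bruteForceTmax <- function(X) {
    n <- nrow(X)
    tFun <- function(M) apply(M, 2, function(v)
        mean(v) / (stats::sd(v) / sqrt(length(v))))
    tObs <- tFun(X)
    null <- vapply(0:(2^n - 1), function(b) {
        s <- ifelse(bitwAnd(b, 2^(seq_len(n) - 1)) > 0, -1, 1)
        max(abs(tFun(s * X)))
    }, numeric(1))
    p <- vapply(abs(tObs), function(x)
        sum(null >= x - 1e-9 * max(1, x)) / 2^n, numeric(1))
    list(t = tObs, p = p, null = null)
}

# independent high-precision JZS oracle: marginal over the effect size
# with the noncentral-t likelihood (different route than the package's
# inverse-gamma mixture quadrature)
jzsOracle <- function(t, n1, n2 = NULL, r = 0.707) {
    if (is.null(n2)) {
        effN <- n1; df <- n1 - 1
    } else {
        effN <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
    }
    m1 <- stats::integrate(function(d)
        suppressWarnings(stats::dt(t, df, ncp = d * sqrt(effN))) *
            stats::dcauchy(d, 0, r),
        -Inf, Inf, rel.tol = 1e-10, subdivisions = 2000L)$value
    m1 / stats::dt(t, df)
}

# independent split-plot sums-of-squares oracle from cell/subject means
splitPlotOracle <- function(d, dv = "amplitude", within = "electrode",
                            between = "group", subject = "subject") {
    Y <- tapply(d[[dv]], list(d[[subject]], d[[within]]), mean)
    grp <- tapply(d[[between]], d[[subject]],
                  function(x) as.character(x[1]))[rownames(Y)]
    N <- nrow(Y); k <- ncol(Y); ng <- table(grp)
    sm <- rowMeans(Y); mbar <- mean(sm)
    mg <- tapply(sm, grp, mean)
    em <- colMeans(Y)
    cellm <- apply(Y, 2, function(col) tapply(col, grp, mean))
    ssA <- k * sum(ng * (mg - mbar)^2)
    ssS <- k * sum((sm - mg[grp])^2)
    ssW <- N * sum((em - mbar)^2)
    ssI <- 0
    for (g in names(ng)) for (e in seq_len(k))
        ssI <- ssI + ng[[g]] * (cellm[g, e] - mg[[g]] - em[e] + mbar)^2
    ssTot <- sum((d[[dv]] - mean(d[[dv]]))^2)
    ssR <- ssTot - ssA - ssS - ssW - ssI
    Sp <- matrix(0, k, k)
    for (g in names(ng))
        Sp <- Sp + stats::cov(Y[grp == g, , drop = FALSE]) * (ng[[g]] - 1)
    Sp <- Sp / (N - length(ng))
    P <- diag(k) - matrix(1 / k, k, k)
    St <- P %*% Sp %*% P
    eps <- sum(diag(St))^2 / ((k - 1) * sum(St * St))
    lapply(list(FA = (ssA / 1) / (ssS / (N - 2)),
                FW = (ssW / (k - 1)) / (ssR / ((N - 2) * (k - 1))),
                FI = (ssI / (k - 1)) / (ssR / ((N - 2) * (k - 1))),
                eps = max(1 / (k - 1), min(1, eps)),
                petaA = ssA / (ssA + ssS), petaW = ssW / (ssW + ssR),
                petaI = ssI / (ssI + ssR)),
           function(v) unname(as.numeric(v)))
}
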