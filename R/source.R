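#' Synthetic EEG lead field
#'
#' Builds a smooth, deterministic forward gain matrix: sensors are placed
#' (with seeded jitter) on the upper unit sphere, sources inside a
#' concentric sphere of radius 0.8, and the gain of each source dipole at
#' each sensor follows the quasi-static current-dipole kernel in a
#' homogeneous medium, \code{g = e . (r - p) / |r - p|^3} for orientation
#' \code{e}, sensor position \code{r} and source position \code{p}. Three
#' orthogonal orientations per source (unconstrained solution). The matrix
#' has full row rank after average-reference projection.
#'
#' @param nChannels number of sensors (>= 4).
#' @param nSources number of sources (>= nChannels).
#' @param seed integer seed.
#' @return A \linkS4class{LeadField}.
#' @export
makeSyntheticLeadField <- function(nChannels, nSources, seed = 1) {
    if (nChannels < 4L) stop("need at least 4 channels")
    if (nSources < nChannels)
        stop("need at least as many sources as channels")
    withSeed(seed, {
        ## sensors: spiral over the upper hemisphere plus small jitter
        i <- seq_len(nChannels)
        z <- 0.15 + 0.85 * (i - 0.5) / nChannels
        phi <- i * pi * (3 - sqrt(5))
        chan <- cbind(sqrt(1 - z^2) * cos(phi),
                      sqrt(1 - z^2) * sin(phi), z)
        chan <- chan + matrix(stats::rnorm(3 * nChannels, 0, 0.02),
                              ncol = 3)
        chan <- chan / sqrt(rowSums(chan^2))
        ## sources: uniform in the inner ball of radius 0.8
        src <- matrix(stats::rnorm(3 * nSources), ncol = 3)
        src <- src / sqrt(rowSums(src^2)) *
            0.8 * stats::runif(nSources)^(1 / 3)
        gain <- matrix(0, nChannels, 3L * nSources)
        for (j in seq_len(nSources)) {
            dvec <- sweep(chan, 2L, src[j, ])
            d3 <- rowSums(dvec^2)^1.5
            gain[, 3L * j - 2L:0] <- dvec / d3
        }
        new("LeadField", gain = gain, sourcePositions = src,
            channelPositions = chan)
    })
}

## regularized average-referenced inverse operators for a lead field
sloretaOperators <- function(lf, lambda) {
    m <- nrow(lf@gain)
    H <- diag(m) - matrix(1 / m, m, m)
    L <- H %*% lf@gain
    G <- L %*% t(L)
    scale <- sum(diag(G)) / m
    K <- G + lambda * scale * H
    ev <- eigen(K, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    if (sum(pos) < m - 1L)
        stop("system is singular; use lambda > 0")
    Kinv <- ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    list(L = L, Kinv = Kinv, H = H)
}

#' sLORETA standardized minimum-norm source inverse
#'
#' Weighted minimum-norm estimate with Tikhonov regularization followed by
#' sLORETA standardization. With average-reference-projected lead field
#' \code{L} and data \code{d}, the current estimate is
#' \code{J = L' (L L' + lambda H)^+ d} (\code{H} the average-reference
#' projector, pseudo-inverse on its range) and the standardized power of
#' source \code{i} is \code{J_i' S_ii^-1 J_i}, where \code{S_ii} is the
#' 3 x 3 block of the resolution-based variance
#' \code{S = L' (L L' + lambda H)^+ L}. For noiseless single-dipole data
#' and small \code{lambda}, the power maximum coincides with the
#' generating source (zero localization error).
#'
#' @param lf A \linkS4class{LeadField}.
#' @param data channels vector or channels x samples matrix (data are
#'   average-referenced internally).
#' @param lambda relative Tikhonov regularization, scaled by the mean
#'   eigenvalue of \code{L L'} (default 1e-8; 0 requires a full-rank
#'   system).
#' @return A \linkS4class{SourceEstimate} (sources x samples standardized
#'   power).
#' @export
sloretaInverse <- function(lf, data, lambda = 1e-8) {
    stopifnot(is(lf, "LeadField"))
    if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
    if (nrow(data) != nrow(lf@gain))
        stop("data channel count does not match the lead field")
    if (lambda < 0) stop("lambda must be >= 0")
    op <- sloretaOperators(lf, lambda)
    J <- t(op$L) %*% op$Kinv %*% (op$H %*% data)
    nSrc <- nrow(lf@sourcePositions)
    power <- matrix(0, nSrc, ncol(data))
    for (j in seq_len(nSrc)) {
        rows <- 3L * j - 2L:0
        Sjj <- t(op$L[, rows, drop = FALSE]) %*% op$Kinv %*%
            op$L[, rows, drop = FALSE]
        Sinv <- MASS::ginv(Sjj)
        Jj <- J[rows, , drop = FALSE]
        power[j, ] <- colSums(Jj * (Sinv %*% Jj))
    }
    power[power < 0] <- 0                # numerical floor
    new("SourceEstimate", power = power,
        label = paste0("lambda=", format(lambda)))
}

#' Compare standardized source power between two groups
#'
#' Per-source two-sample permutation t-test (group-label shuffling),
#' Benjamini-Hochberg FDR control at \code{alpha}, and a minimum-extent
#' rule: contiguous runs (in source index) of suprathreshold sources
#' smaller than \code{minCluster} are discarded.
#'
#' @param groupA,groupB subjects x sources matrices of source power.
#' @param alpha FDR level (default .01).
#' @param minCluster minimum run length kept (default 5).
#' @param nPerm permutations for the per-source p-value.
#' @param seed integer seed.
#' @return data.frame with one row per source: \code{t}, \code{p},
#'   \code{q} (BH-adjusted), \code{significant}, \code{kept} (significant
#'   and in a run of >= minCluster).
#' @export
compareGroupSources <- function(groupA, groupB, alpha = 0.01,
                                minCluster = 5L, nPerm = 2000L,
                                seed = 1) {
    if (!is.matrix(groupA) || !is.matrix(groupB) ||
        ncol(groupA) != ncol(groupB))
        stop("groupA and groupB must be subjects x sources matrices ",
             "with matching sources")
    nA <- nrow(groupA); nB <- nrow(groupB)
    if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
    P <- ncol(groupA)
    X <- rbind(groupA, groupB)
    tStat <- function(idxA) {
        a <- X[idxA, , drop = FALSE]
        b <- X[-idxA, , drop = FALSE]
        ma <- colMeans(a); mb <- colMeans(b)
        va <- (colSums(a^2) - nA * ma^2) / (nA - 1)
        vb <- (colSums(b^2) - nB * mb^2) / (nB - 1)
        sp <- ((nA - 1) * va + (nB - 1) * vb) / (nA + nB - 2)
        sp[sp <= 0] <- NA
        (ma - mb) / sqrt(sp * (1 / nA + 1 / nB))
    }
    tObs <- tStat(seq_len(nA))
    counts <- withSeed(seed, {
        cnt <- rep(0L, P)
        for (i in seq_len(nPerm)) {
            tp <- tStat(sample.int(nA + nB, nA))
            cnt <- cnt + (abs(tp) >= abs(tObs) - 1e-12)
        }
        cnt
    })
    p <- (1 + counts) / (1 + nPerm)
    q <- stats::p.adjust(p, method = "BH")
    sig <- q <= alpha
    kept <- logical(P)
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= minCluster))
        kept[starts[i]:ends[i]] <- TRUE
    data.frame(source = seq_len(P), t = tObs, p = p, q = q,
               significant = sig, kept = kept)
}
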