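#' tmax sign-flip permutation test with familywise error control
#'
#' One-sample (against zero) mass-univariate test over an electrode x time
#' family. The observed statistic is the one-sample t at every point; the
#' null distribution is built by randomly flipping the sign of whole
#' subjects and recording, per permutation, the maximum |t| over the whole
#' family. The familywise-corrected p-value of a point is the proportion
#' of the null reaching its observed |t|, with the add-one convention
#' \code{(1 + b) / (1 + nPerm)} for random permutations. When all
#' \code{2^n} sign patterns are no more numerous than \code{nPerm} the
#' test enumerates them exhaustively and p-values are exact proportions.
#'
#' Points with zero variance across subjects have no defined t; they are
#' excluded from the family (flagged in the result) rather than assigned
#' an infinite statistic.
#'
#' @param diffs subjects x channels x samples array (or subjects x points
#'   matrix) of per-subject difference potentials.
#' @param nPerm number of permutations (default 10000).
#' @param alpha familywise error rate (two-tailed, default .05).
#' @param seed integer seed; ignored in exhaustive mode.
#' @param chunkSize permutations processed per block (memory bound).
#' @return A \linkS4class{PermutationResult}.
#' @export
tmaxTest <- function(diffs, nPerm = 10000, alpha = 0.05, seed = 1,
                     chunkSize = 1000L) {
    dm <- dim(diffs)
    if (is.null(dm) || length(dm) < 2L)
        stop("diffs must be a subjects x channels x samples array or a ",
             "subjects x points matrix")
    X <- if (length(dm) == 3L) matrix(diffs, dm[1L]) else diffs
    n <- nrow(X)
    if (n < 2L) stop("need at least 2 subjects")
    if (!all(is.finite(X))) stop("diffs must be finite")
    P <- ncol(X)

    ss <- colSums(X^2)
    m0 <- colMeans(X)
    v0 <- (ss - n * m0^2) / (n - 1)
    excluded <- v0 <= 1e-14 * (ss / n + 1e-300)
    if (all(excluded))
        stop("zero variance at every point: t is undefined")
    inc <- which(!excluded)
    Xi <- X[, inc, drop = FALSE]
    ssI <- ss[inc]
    tObs <- m0[inc] / sqrt(v0[inc] / n)

    exhaustive <- n <= 25 && 2^n <= nPerm
    ## |t| is monotone in u = (sum s_i x_i)^2 / sum x_i^2 (the sum of
    ## squares is sign-flip invariant), so the family maximum reduces to a
    ## row maximum of one scaled cross-product
    Z <- sweep(Xi, 2L, sqrt(ssI), `/`)
    tmaxFor <- function(S) {
        U <- (S %*% Z)^2
        j <- max.col(U, ties.method = "first")
        uMax <- U[cbind(seq_len(nrow(U)), j)]
        sqrt((n - 1) * uMax / pmax(n - uMax, 1e-300))
    }
    if (exhaustive) {
        nPat <- as.integer(2^n)
        null <- numeric(nPat)
        done <- 0L
        while (done < nPat) {
            take <- min(chunkSize, nPat - done)
            S <- matrix(1, take, n)
            for (j in seq_len(n))
                S[, j] <- ifelse(bitwAnd(done + seq_len(take) - 1L,
                                         bitwShiftL(1L, j - 1L)) > 0,
                                 -1, 1)
            null[done + seq_len(take)] <- tmaxFor(S)
            done <- done + take
        }
        nEff <- nPat
    } else {
        null <- withSeed(seed, {
            out <- numeric(nPerm)
            done <- 0L
            while (done < nPerm) {
                take <- min(chunkSize, nPerm - done)
                S <- matrix(sample(c(-1, 1), take * n, replace = TRUE),
                            take, n)
                out[done + seq_len(take)] <- tmaxFor(S)
                done <- done + take
            }
            out
        })
        nEff <- as.integer(nPerm)
    }

    sortedNull <- sort(null)
    ## count of null >= |t|, with a relative tie tolerance so the identity
    ## pattern is always counted at the family maximum
    absT <- abs(tObs)
    thr <- absT - 1e-9 * pmax(1, absT)
    countGe <- nEff - findInterval(thr, sortedNull)
    p <- if (exhaustive) countGe / nEff else (1 + countGe) / (1 + nEff)

    pMap <- matrix(1, nrow = if (length(dm) == 3L) dm[2L] else 1L,
                   ncol = if (length(dm) == 3L) dm[3L] else P)
    tMap <- matrix(0, nrow(pMap), ncol(pMap))
    exMap <- matrix(excluded, nrow(pMap), ncol(pMap))
    pMap[inc] <- p
    tMap[inc] <- tObs
    sig <- matrix(FALSE, nrow(pMap), ncol(pMap))
    sig[inc] <- p <= alpha

    new("PermutationResult", tObserved = tMap, tmaxNull = null,
        criticalValue = unname(stats::quantile(null, 1 - alpha,
                                               type = 1)),
        pMap = pMap, significantMask = sig, excluded = exMap,
        nPermutations = nEff, alpha = alpha, exhaustive = exhaustive)
}

#' Contiguous significant runs per channel
#'
#' Descriptive summary of a \linkS4class{PermutationResult}: for each
#' channel, the contiguous sample runs where the familywise-corrected
#' p-value is at or below alpha. Purely descriptive; the inferential
#' statement is the point-wise familywise control itself.
#'
#' @param result A \linkS4class{PermutationResult}.
#' @param times optional sample times (ms) to report run boundaries in ms.
#' @return data.frame with columns \code{channel}, \code{startSample},
#'   \code{endSample} (and \code{startMs}/\code{endMs} when \code{times}
#'   is given).
#' @export
significantRuns <- function(result, times = NULL) {
    mask <- result@significantMask
    out <- list()
    for (ch in seq_len(nrow(mask))) {
        r <- rle(mask[ch, ])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- which(r$values)
        for (k in keep)
            out[[length(out) + 1L]] <- data.frame(
                channel = ch, startSample = starts[k],
                endSample = ends[k])
    }
    if (!length(out))
        return(data.frame(channel = integer(), startSample = integer(),
                          endSample = integer()))
    df <- do.call(rbind, out)
    if (!is.null(times)) {
        df$startMs <- times[df$startSample]
        df$endMs <- times[df$endSample]
    }
    df
}
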