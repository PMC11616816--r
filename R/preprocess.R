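#' Design a Kaiser-windowed FIR filter kernel
#'
#' Windowed-sinc linear-phase design. The kernel length follows the Kaiser
#' formula: the window beta is mapped back to its stopband attenuation
#' (\code{A = beta / 0.1102 + 8.7} dB for the high-attenuation branch) and
#' the number of taps is \code{(A - 7.95) / (2.285 * dw)} with \code{dw}
#' the transition width in rad/sample, rounded up to an odd length. The
#' canonical low-pass used for ERP work here is 30 Hz cutoff, beta 12.2653
#' (120 dB), 10 Hz transition band; the matching high-pass is 0.1 Hz, beta
#' 5.6533 (60 dB), 0.2 Hz transition band. The -6 dB point of the kernel
#' sits at the cutoff. The kernel is normalized to unit DC gain (low-pass)
#' or exact zero DC gain (high-pass).
#'
#' @param cutoff cutoff frequency (Hz), the -6 dB point.
#' @param sfreq sampling frequency (Hz).
#' @param beta Kaiser window beta.
#' @param transitionBandwidth transition band width (Hz).
#' @param type \code{"lowpass"} or \code{"highpass"}.
#' @return Numeric kernel of odd length, symmetric about its centre.
#' @export
#' @examples
#' h <- designKaiserFir(30, 1000, beta = 12.2653, transitionBandwidth = 10)
#' length(h)  # odd
designKaiserFir <- function(cutoff, sfreq, beta = 12.2653,
                            transitionBandwidth = 10,
                            type = c("lowpass", "highpass")) {
    type <- match.arg(type)
    if (cutoff <= 0 || transitionBandwidth <= 0)
        stop("cutoff and transitionBandwidth must be > 0")
    if (cutoff >= sfreq / 2)
        stop("cutoff must be below the Nyquist frequency (",
             sfreq / 2, " Hz)")
    attenDb <- if (beta > 0) beta / 0.1102 + 8.7 else 21
    dw <- 2 * pi * transitionBandwidth / sfreq
    nTaps <- ceiling((attenDb - 7.95) / (2.285 * dw))
    if (nTaps %% 2 == 0) nTaps <- nTaps + 1
    m <- (nTaps - 1) / 2
    nn <- seq(-m, m)
    fc <- cutoff / sfreq
    sinc <- 2 * fc * ifelse(nn == 0, 1, sin(2 * pi * fc * nn) /
                                (2 * pi * fc * nn))
    win <- signal::kaiser(nTaps, beta)
    h <- sinc * win
    h <- h / sum(h)                      # unit DC gain
    if (type == "highpass") {
        delta <- numeric(nTaps)
        delta[m + 1] <- 1
        h <- delta - h                   # spectral inversion
    }
    h
}

## magnitude response of a kernel at given frequencies (Hz)
kernelGain <- function(kernel, freqsHz, sfreq) {
    m <- (length(kernel) - 1) / 2
    nn <- seq(-m, m)
    vapply(freqsHz, function(f)
        abs(sum(kernel * exp(-2i * pi * f / sfreq * nn))), numeric(1))
}

#' Zero-phase filtering of epoched or continuous data
#'
#' Convolves with a symmetric (linear-phase) kernel and compensates the
#' group delay, so the output is aligned with the input. Edges are padded
#' by reflection before convolution. Accepts a vector, a samples x series
#' matrix, or an \linkS4class{EpochSet} (filtered per epoch and channel).
#'
#' @param x data to filter; for matrices, time runs down the rows.
#' @param kernel filter kernel from \code{\link{designKaiserFir}}.
#' @return The filtered object, same shape as the input.
#' @export
applyZeroPhase <- function(x, kernel) {
    if (is(x, "EpochSet")) {
        d <- dim(x@data)
        flat <- matrix(aperm(x@data, c(3, 1, 2)), nrow = d[3L])
        filt <- applyZeroPhase(flat, kernel)
        x@data <- aperm(array(filt, dim = c(d[3L], d[1L], d[2L])),
                        c(2, 3, 1))
        return(x)
    }
    vec <- is.null(dim(x))
    xm <- if (vec) matrix(x, ncol = 1) else x
    n <- nrow(xm)
    L <- length(kernel)
    if (n <= L)
        stop("data must be longer than the filter kernel (", L, " taps)")
    m <- (L - 1) / 2
    pad <- rbind(xm[(m + 1):2, , drop = FALSE],
                 xm,
                 xm[(n - 1):(n - m), , drop = FALSE])
    nP <- n + 2 * m
    nFft <- stats::nextn(nP + L - 1, 2)
    K <- stats::fft(c(kernel, numeric(nFft - L)))
    P <- rbind(pad, matrix(0, nFft - nP, ncol(pad)))
    Y <- Re(stats::mvfft(stats::mvfft(P) * K, inverse = TRUE)) / nFft
    out <- Y[(2 * m + 1):(2 * m + n), , drop = FALSE]
    if (vec) drop(out) else out
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean voltage over the baseline
#' window (half-open \code{[start, end)} in ms; default the 100 ms
#' pre-stimulus interval).
#'
#' @param epochs An \linkS4class{EpochSet}.
#' @param window baseline window in ms.
#' @return The baseline-corrected \linkS4class{EpochSet}.
#' @export
baselineCorrect <- function(epochs, window = c(-100, 0)) {
    stopifnot(is(epochs, "EpochSet"))
    idx <- windowIndex(epochs@times, window)
    bl <- apply(epochs@data[, , idx, drop = FALSE], c(1, 2), mean)
    epochs@data <- epochs@data - as.vector(bl)   # recycles over samples
    epochs
}

#' Reject epochs by peak-to-peak amplitude
#'
#' An epoch is rejected iff the voltage range (max - min over the whole
#' epoch) exceeds \code{threshold} on at least one channel.
#'
#' @param epochs An \linkS4class{EpochSet}.
#' @param threshold peak-to-peak limit (microvolt).
#' @return List with \code{kept} (the surviving \linkS4class{EpochSet})
#'   and \code{rejected} (logical mask over the input epochs).
#' @export
rejectArtifacts <- function(epochs, threshold = 100) {
    stopifnot(is(epochs, "EpochSet"), threshold > 0)
    ptp <- apply(epochs@data, c(1, 2), function(v) max(v) - min(v))
    rejected <- apply(ptp > threshold, 1L, any)
    kept <- epochs
    kept@data <- epochs@data[!rejected, , , drop = FALSE]
    kept@trialInfo <- epochs@trialInfo[!rejected, , drop = FALSE]
    list(kept = kept, rejected = rejected)
}

#' Average surviving epochs per condition
#'
#' Averages epochs within each of the eight condition labels, by default
#' using only correct-response trials. Conditions named in \code{require}
#' that end up with fewer than \code{minEpochs} epochs raise a
#' \code{"tooFewEpochs"} condition, the per-subject exclusion signal used
#' by cohort-level code.
#'
#' @param epochs An \linkS4class{EpochSet} (baseline-corrected, cleaned).
#' @param correctOnly use only correct trials (default TRUE).
#' @param require condition labels that must be present; defaults to all
#'   labels observed in the data.
#' @param minEpochs minimum epochs per required condition.
#' @return Named list of \linkS4class{Evoked}, one per available condition.
#' @export
averageConditions <- function(epochs, correctOnly = TRUE,
                              require = NULL, minEpochs = 1L) {
    stopifnot(is(epochs, "EpochSet"))
    info <- epochs@trialInfo
    use <- !is.na(info$label)
    if (correctOnly && "correct" %in% names(info))
        use <- use & !is.na(info$correct) & info$correct
    labs <- unique(info$label[use])
    if (is.null(require)) require <- labs
    counts <- table(factor(info$label[use], levels = require))
    if (any(counts < minEpochs)) {
        bad <- names(counts)[counts < minEpochs]
        cond <- structure(
            class = c("tooFewEpochs", "error", "condition"),
            list(message = paste0("subject ", epochs@subjectId,
                                  ": too few epochs in condition(s) ",
                                  paste(bad, collapse = ", ")),
                 call = sys.call()))
        stop(cond)
    }
    out <- lapply(labs, function(lab) {
        sel <- which(use & info$label == lab)
        avg <- apply(epochs@data[sel, , , drop = FALSE], c(2, 3), mean)
        new("Evoked", condition = lab, data = avg,
            nEpochs = length(sel), times = epochs@times,
            channelLabels = epochs@channelLabels,
            subjectId = epochs@subjectId)
    })
    stats::setNames(out, labs)
}
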