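#' @import methods
NULL

#' The eight reference-back condition labels
#'
#' Trials are cross-classified by TRIAL TYPE (reference vs comparison frame),
#' GATE SWITCH (frame differs from the previous trial or not) and the required
#' RESPONSE (same vs different as the letter of the last reference trial),
#' giving the 2 x 2 x 2 cell structure every contrast in the package is
#' defined on. Labels are strings of the form
#' \code{"reference.no_switch.same"}.
#'
#' @return Character vector of the 8 condition labels, in fixed order.
#' @export
#' @examples
#' conditionLabels()
conditionLabels <- function() {
    as.character(outer(
        outer(c("reference", "comparison"), c("no_switch", "switch"),
              paste, sep = "."),
        c("same", "different"), paste, sep = "."))
}

#' SessionDesign: parameters of a reference-back session
#'
#' Holds the block structure and trial-type probabilities of a session:
#' \code{nBlocks} blocks of \code{trialsPerBlock} trials, reference frames
#' with probability \code{pReference}, gate switches with probability
#' \code{pSwitch} among gate-classifiable trials, and required responses
#' balanced at \code{pSame}. \code{balanceTolerance} is the maximal deviation
#' (in trials) of per-block counts from their targets.
#'
#' @slot nBlocks integer, number of blocks.
#' @slot trialsPerBlock integer, trials per block.
#' @slot pReference,pSwitch,pSame probabilities in (0, 1).
#' @slot balanceTolerance numeric, allowed per-block count deviation.
#' @slot seed integer RNG seed.
#' @export
setClass("SessionDesign",
    representation(nBlocks = "integer", trialsPerBlock = "integer",
                   pReference = "numeric", pSwitch = "numeric",
                   pSame = "numeric", balanceTolerance = "numeric",
                   seed = "integer"),
    prototype(nBlocks = 9L, trialsPerBlock = 80L, pReference = 0.5,
              pSwitch = 0.25, pSame = 0.5, balanceTolerance = 1.5,
              seed = 1L))

setValidity("SessionDesign", function(object) {
    msg <- character()
    p <- c(object@pReference, object@pSwitch, object@pSame)
    if (any(p <= 0) || any(p >= 1))
        msg <- c(msg, "pReference, pSwitch, pSame must lie in (0, 1)")
    if (object@nBlocks < 1L)
        msg <- c(msg, "nBlocks must be >= 1")
    if (object@trialsPerBlock < 4L)
        msg <- c(msg, "trialsPerBlock must be >= 4")
    if (object@balanceTolerance <= 0)
        msg <- c(msg, "balanceTolerance must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a SessionDesign
#'
#' @param nBlocks,trialsPerBlock block structure (defaults 9 x 80).
#' @param pReference,pSwitch,pSame trial-type probabilities.
#' @param balanceTolerance allowed per-block count deviation in trials.
#' @param seed integer seed; the generated session is a deterministic
#'   function of the design including this seed.
#' @return A \linkS4class{SessionDesign}.
#' @export
#' @examples
#' sessionDesign(nBlocks = 2, trialsPerBlock = 40, seed = 7)
sessionDesign <- function(nBlocks = 9, trialsPerBlock = 80,
                          pReference = 0.5, pSwitch = 0.25, pSame = 0.5,
                          balanceTolerance = 1.5, seed = 1) {
    new("SessionDesign", nBlocks = as.integer(nBlocks),
        trialsPerBlock = as.integer(trialsPerBlock),
        pReference = pReference, pSwitch = pSwitch, pSame = pSame,
        balanceTolerance = balanceTolerance, seed = as.integer(seed))
}

#' EpochSet: single-subject epoched multichannel voltage data
#'
#' A trials x channels x samples array of voltages (microvolt) with timing
#' metadata and a per-trial information table (condition labels, behavioural
#' outcome). The canonical recording geometry is 1000 Hz sampling with epochs
#' from -100 to 1000 ms (1101 samples), but any strictly increasing time
#' vector consistent with \code{sfreq} is accepted.
#'
#' @slot data numeric array, trials x channels x samples, microvolt.
#' @slot sfreq sampling frequency in Hz.
#' @slot times sample times in ms relative to stimulus onset.
#' @slot channelLabels ordered channel names.
#' @slot trialInfo data.frame with one row per trial (columns include
#'   \code{label}, \code{correct}, \code{rt_ms}).
#' @slot subjectId subject identifier.
#' @export
setClass("EpochSet",
    representation(data = "array", sfreq = "numeric", times = "numeric",
                   channelLabels = "character", trialInfo = "data.frame",
                   subjectId = "character"))

setValidity("EpochSet", function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, "data must be a trials x channels x samples array")
    else {
        if (d[2L] != length(object@channelLabels))
            msg <- c(msg, "channelLabels length must equal dim(data)[2]")
        if (d[3L] != length(object@times))
            msg <- c(msg, "times length must equal dim(data)[3]")
        if (nrow(object@trialInfo) != d[1L])
            msg <- c(msg, "trialInfo must have one row per trial")
    }
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (length(object@sfreq) != 1L || object@sfreq <= 0)
        msg <- c(msg, "sfreq must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param data trials x channels x samples array (microvolt).
#' @param sfreq sampling frequency (Hz).
#' @param times sample times in ms; defaults to a regular grid starting at
#'   \code{tmin}.
#' @param channelLabels channel names.
#' @param trialInfo per-trial data.frame.
#' @param subjectId subject identifier.
#' @param tmin epoch start in ms, used when \code{times} is missing.
#' @return An \linkS4class{EpochSet}.
#' @export
epochSet <- function(data, sfreq = 1000, times = NULL,
                     channelLabels = NULL, trialInfo = NULL,
                     subjectId = "subject", tmin = -100) {
    d <- dim(data)
    if (is.null(times))
        times <- tmin + (seq_len(d[3L]) - 1L) * 1000 / sfreq
    if (is.null(channelLabels))
        channelLabels <- paste0("ch", seq_len(d[2L]))
    if (is.null(trialInfo))
        trialInfo <- data.frame(label = rep(NA_character_, d[1L]),
                                correct = rep(TRUE, d[1L]),
                                rt_ms = rep(NA_real_, d[1L]))
    new("EpochSet", data = data, sfreq = sfreq, times = times,
        channelLabels = channelLabels, trialInfo = trialInfo,
        subjectId = subjectId)
}

#' Evoked: per-condition averaged potentials for one subject
#'
#' @slot condition condition label or named contrast.
#' @slot data channels x samples matrix (microvolt).
#' @slot nEpochs number of epochs entering the average.
#' @slot times sample times (ms).
#' @slot channelLabels channel names.
#' @slot subjectId subject identifier.
#' @export
setClass("Evoked",
    representation(condition = "character", data = "matrix",
                   nEpochs = "integer", times = "numeric",
                   channelLabels = "character", subjectId = "character"))

setValidity("Evoked", function(object) {
    msg <- character()
    if (object@nEpochs < 1L) msg <- c(msg, "nEpochs must be >= 1")
    if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
    if (nrow(object@data) != length(object@channelLabels))
        msg <- c(msg, "rows of data must match channelLabels")
    if (ncol(object@data) != length(object@times))
        msg <- c(msg, "columns of data must match times")
    if (length(msg)) msg else TRUE
})

#' LeadField: synthetic EEG forward gain matrix
#'
#' Gain matrix mapping \code{nSources} dipoles with three free orientations
#' to \code{nChannels} sensors; columns are ordered source-major
#' (x, y, z orientation triplets per source).
#'
#' @slot gain channels x (3 * sources) matrix.
#' @slot sourcePositions sources x 3 coordinates (arbitrary units).
#' @slot channelPositions channels x 3 sensor coordinates.
#' @export
setClass("LeadField",
    representation(gain = "matrix", sourcePositions = "matrix",
                   channelPositions = "matrix"))

setValidity("LeadField", function(object) {
    msg <- character()
    if (!all(is.finite(object@gain))) msg <- c(msg, "gain must be finite")
    if (ncol(object@gain) != 3L * nrow(object@sourcePositions))
        msg <- c(msg, "gain must have 3 columns per source")
    if (nrow(object@gain) != nrow(object@channelPositions))
        msg <- c(msg, "gain rows must match channelPositions")
    m <- nrow(object@gain)
    H <- diag(m) - matrix(1 / m, m, m)
    if (qr(H %*% object@gain)$rank < m - 1L)
        msg <- c(msg, "gain must have full row rank after average-reference")
    if (length(msg)) msg else TRUE
})

#' PermutationResult: tmax permutation test output
#'
#' @slot tObserved observed one-sample t per (channel, sample).
#' @slot tmaxNull permutation null distribution of max |t|.
#' @slot criticalValue |t| threshold at the familywise alpha.
#' @slot pMap familywise-corrected p-values, same shape as tObserved.
#' @slot significantMask logical map, \code{pMap <= alpha}.
#' @slot excluded logical map of zero-variance points dropped from the family.
#' @slot nPermutations number of permutations (or sign patterns).
#' @slot alpha familywise error rate.
#' @slot exhaustive TRUE if all sign patterns were enumerated.
#' @export
setClass("PermutationResult",
    representation(tObserved = "matrix", tmaxNull = "numeric",
                   criticalValue = "numeric", pMap = "matrix",
                   significantMask = "matrix", excluded = "matrix",
                   nPermutations = "integer", alpha = "numeric",
                   exhaustive = "logical"))

setValidity("PermutationResult", function(object) {
    msg <- character()
    p <- object@pMap[!object@excluded]
    if (length(p) && (any(p <= 0) || any(p > 1)))
        msg <- c(msg, "corrected p-values must lie in (0, 1]")
    if (!identical(dim(object@pMap), dim(object@tObserved)))
        msg <- c(msg, "pMap must match tObserved in shape")
    if (!identical(object@significantMask[!object@excluded] <= 1,
                   rep(TRUE, sum(!object@excluded))))
        msg <- c(msg, "significantMask malformed")
    if (length(msg)) msg else TRUE
})

#' SourceEstimate: standardized source power map
#'
#' @slot power sources x samples matrix of non-negative standardized power.
#' @slot label time point or window label.
#' @export
setClass("SourceEstimate",
    representation(power = "matrix", label = "character"))

setValidity("SourceEstimate", function(object) {
    if (any(object@power < -1e-10))
        "standardized power must be non-negative" else TRUE
})
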