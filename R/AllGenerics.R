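#' @rdname EpochSet-accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname sourcePower
#' @export
setGeneric("sourcePower", function(object) standardGeneric("sourcePower"))

#' Accessors for EpochSet and Evoked objects
#'
#' \code{epochData} returns the voltage array (trials x channels x samples
#' for an \linkS4class{EpochSet}; channels x samples for an
#' \linkS4class{Evoked}); \code{epochTimes} the sample times in ms;
#' \code{channelNames} the channel labels; \code{trialInfo} the per-trial
#' table; \code{nEpochs} the number of (contributing) epochs;
#' \code{samplingRate} the sampling frequency in Hz.
#'
#' @param object An \linkS4class{EpochSet} or \linkS4class{Evoked}.
#' @return The slot value described above.
#' @name EpochSet-accessors
NULL

#' @rdname EpochSet-accessors
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)
#' @rdname EpochSet-accessors
#' @export
setMethod("epochData", "Evoked", function(object) object@data)
#' @rdname EpochSet-accessors
#' @export
setMethod("epochTimes", "EpochSet", function(object) object@times)
#' @rdname EpochSet-accessors
#' @export
setMethod("epochTimes", "Evoked", function(object) object@times)
#' @rdname EpochSet-accessors
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channelLabels)
#' @rdname EpochSet-accessors
#' @export
setMethod("channelNames", "Evoked", function(object) object@channelLabels)
#' @rdname EpochSet-accessors
#' @export
setMethod("trialInfo", "EpochSet", function(object) object@trialInfo)
#' @rdname EpochSet-accessors
#' @export
setMethod("subjectId", "EpochSet", function(object) object@subjectId)
#' @rdname EpochSet-accessors
#' @export
setMethod("subjectId", "Evoked", function(object) object@subjectId)
#' @rdname EpochSet-accessors
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@data)[1L])
#' @rdname EpochSet-accessors
#' @export
setMethod("nEpochs", "Evoked", function(object) object@nEpochs)
#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@sfreq)

#' Standardized power of a SourceEstimate
#'
#' @param object A \linkS4class{SourceEstimate}.
#' @return sources x samples matrix of standardized power.
#' @name sourcePower
NULL

#' @rdname sourcePower
#' @export
setMethod("sourcePower", "SourceEstimate", function(object) object@power)

setMethod("show", "SessionDesign", function(object) {
    cat("SessionDesign:", object@nBlocks, "block(s) x",
        object@trialsPerBlock, "trials\n")
    cat("  p(reference) =", object@pReference,
        " p(switch) =", object@pSwitch, " p(same) =", object@pSame, "\n")
    cat("  balance tolerance =", object@balanceTolerance,
        "trials, seed =", object@seed, "\n")
})

setMethod("show", "EpochSet", function(object) {
    d <- dim(object@data)
    cat("EpochSet for subject", object@subjectId, "\n")
    cat(" ", d[1L], "epochs x", d[2L], "channels x", d[3L], "samples @",
        object@sfreq, "Hz\n")
    cat("  time range:", min(object@times), "to", max(object@times), "ms\n")
    if ("label" %in% names(object@trialInfo)) {
        tb <- table(object@trialInfo$label, useNA = "ifany")
        cat("  conditions:", paste(names(tb), tb, sep = "=",
                                   collapse = ", "), "\n")
    }
})

setMethod("show", "Evoked", function(object) {
    cat("Evoked [", object@condition, "] subject ", object@subjectId,
        ": ", nrow(object@data), " channels x ", ncol(object@data),
        " samples, n = ", object@nEpochs, " epochs\n", sep = "")
})

setMethod("show", "LeadField", function(object) {
    cat("LeadField:", nrow(object@gain), "channels,",
        nrow(object@sourcePositions), "sources x 3 orientations\n")
})

setMethod("show", "PermutationResult", function(object) {
    cat("tmax permutation test:", object@nPermutations,
        if (object@exhaustive) "sign patterns (exhaustive)"
        else "random sign-flips", "\n")
    cat("  family:", sum(!object@excluded), "points (",
        sum(object@excluded), "zero-variance excluded )\n")
    cat("  critical |t| =", format(object@criticalValue, digits = 4),
        "at FWER", object@alpha, "\n")
    cat("  significant points:", sum(object@significantMask), "\n")
})

setMethod("show", "SourceEstimate", function(object) {
    cat("SourceEstimate [", object@label, "]: ", nrow(object@power),
        " sources x ", ncol(object@power), " sample(s)\n", sep = "")
})
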