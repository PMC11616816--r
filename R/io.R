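#' Persist or load an EpochSet container
#'
#' Epochs are stored as a directory container mirroring the usual
#' dataset-plus-attributes layout of electrophysiology archives:
#' \code{data.bin} holds the voltage array as little-endian float32 in
#' trials x channels x samples order, \code{meta.json} the dimensions,
#' sampling rate, time vector, channel labels and subject id, and
#' \code{trials.tsv} the per-trial table (see \code{\link{writeEvents}}).
#'
#' @param epochs An \linkS4class{EpochSet}.
#' @param dir container directory (created if needed).
#' @return \code{readEpochSet} returns the \linkS4class{EpochSet};
#'   \code{writeEpochSet} returns \code{dir} invisibly.
#' @export
writeEpochSet <- function(epochs, dir) {
    stopifnot(is(epochs, "EpochSet"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    meta <- list(dims = dim(epochs@data), sfreq = epochs@sfreq,
                 times = epochs@times,
                 channelLabels = epochs@channelLabels,
                 subjectId = epochs@subjectId)
    jsonlite::write_json(meta, file.path(dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    con <- file(file.path(dir, "data.bin"), "wb")
    on.exit(close(con))
    writeBin(as.vector(epochs@data), con, size = 4L, endian = "little")
    writeEvents(epochs@trialInfo, file.path(dir, "trials.tsv"))
    invisible(dir)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                                simplifyVector = TRUE)
    n <- prod(meta$dims)
    con <- file(file.path(dir, "data.bin"), "rb")
    on.exit(close(con))
    x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    info <- readEvents(file.path(dir, "trials.tsv"))
    new("EpochSet", data = array(x, dim = meta$dims),
        sfreq = meta$sfreq, times = meta$times,
        channelLabels = meta$channelLabels, trialInfo = info,
        subjectId = meta$subjectId)
}

#' Read a study configuration from YAML
#'
#' The YAML keys mirror the arguments of \code{\link{studyConfig}}
#' (\code{nYounger}, \code{design: {nBlocks, trialsPerBlock, ...}},
#' \code{paramsYounger: {baseRt, ...}}, \code{filter: {lowpass: {cutoff,
#' kaiserBeta, transitionBandwidth}}}, \code{nPerm}, \code{alpha},
#' \code{priorScale}, \code{seed}, ...). Keys not present keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A \code{StudyConfig} list (see \code{\link{studyConfig}}).
#' @export
readStudyConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- list()
    scalars <- intersect(names(y), c("nYounger", "nOlder", "seed",
                                     "nPerm", "alpha", "priorScale",
                                     "sfreq", "rejectThreshold", "minRt",
                                     "sourceAnalysis", "nSources",
                                     "channels"))
    args[scalars] <- y[scalars]
    if (!is.null(y$design))
        args$design <- do.call(sessionDesign, y$design)
    if (!is.null(y$paramsYounger))
        args$paramsYounger <- do.call(behaviourParams, y$paramsYounger)
    if (!is.null(y$paramsOlder))
        args$paramsOlder <- do.call(behaviourParams, y$paramsOlder)
    if (!is.null(y$filter) && !is.null(y$filter$lowpass))
        args$lowpass <- list(
            cutoff = y$filter$lowpass$cutoff,
            kaiserBeta = y$filter$lowpass$kaiserBeta,
            transitionBandwidth = y$filter$lowpass$transitionBandwidth)
    do.call(studyConfig, args)
}

#' Condition mean reaction times of an example two-cohort study
#'
#' Loads the packaged example table of condition mean RTs (ms) for a
#' younger (n = 24) and an older (n = 23) adult cohort performing the
#' reference-back task, one row per group x condition cell plus the
#' overall means. Used by the worked examples and the acceptance script
#' to exercise the cell-mean cost arithmetic.
#'
#' @return data.frame with columns \code{group}, \code{trial_type},
#'   \code{gate_switch}, \code{response}, \code{mean_rt_ms},
#'   \code{sd_rt_ms}, \code{n}.
#' @export
#' @examples
#' head(exampleGroupRtMeans())
exampleGroupRtMeans <- function() {
    path <- system.file("extdata", "group_rt_means.csv",
                        package = "gatingERP", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Condition cell means as a named vector for one group
#'
#' @param means data.frame in the layout of
#'   \code{\link{exampleGroupRtMeans}}.
#' @param group group label to extract.
#' @return Named numeric vector over \code{\link{conditionLabels}}.
#' @export
cellMeanVector <- function(means, group) {
    m <- means[means$group == group & means$trial_type != "overall", ]
    stats::setNames(m$mean_rt_ms,
                    paste(m$trial_type, m$gate_switch, m$response,
                          sep = "."))
}
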