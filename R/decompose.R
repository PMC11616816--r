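#' Signed condition weights for the four gating subprocesses
#'
#' Returns the contrast table that defines the decomposition on both RTs
#' and ERPs:
#' \itemize{
#'   \item updating: no-switch reference minus no-switch comparison
#'     (same/different sub-cells combined by unweighted average, hence
#'     weights +1/2, +1/2, -1/2, -1/2);
#'   \item substitution: (different minus same within no-switch reference)
#'     minus (different minus same within no-switch comparison);
#'   \item gate opening: switch reference minus no-switch reference;
#'   \item gate closing: switch comparison minus no-switch comparison.
#' }
#' Switch trials never enter updating or substitution, so gate toggling
#' cannot bias those two effects. All four weight vectors sum to zero
#' (asserted on construction).
#'
#' @return Named list of four named numeric vectors over
#'   \code{\link{conditionLabels}}.
#' @export
#' @examples
#' sapply(subprocessContrasts(), sum)  # all zero
subprocessContrasts <- function() {
    zero <- stats::setNames(numeric(8), conditionLabels())
    w <- list(updating = zero, substitution = zero,
              gate_opening = zero, gate_closing = zero)
    w$updating[c("reference.no_switch.same",
                 "reference.no_switch.different")] <- 0.5
    w$updating[c("comparison.no_switch.same",
                 "comparison.no_switch.different")] <- -0.5
    w$substitution["reference.no_switch.different"] <- 1
    w$substitution["reference.no_switch.same"] <- -1
    w$substitution["comparison.no_switch.different"] <- -1
    w$substitution["comparison.no_switch.same"] <- 1
    w$gate_opening[c("reference.switch.same",
                     "reference.switch.different")] <- 0.5
    w$gate_opening[c("reference.no_switch.same",
                     "reference.no_switch.different")] <- -0.5
    w$gate_closing[c("comparison.switch.same",
                     "comparison.switch.different")] <- 0.5
    w$gate_closing[c("comparison.no_switch.same",
                     "comparison.no_switch.different")] <- -0.5
    stopifnot(all(abs(vapply(w, sum, numeric(1))) < 1e-12))
    w
}

## ratio denominators: mean of the two collapsed condition means entering
## each simple difference
costAndRatioFromCellMeans <- function(m) {
    cellMean <- function(labels) mean(m[labels])
    refNs <- cellMean(c("reference.no_switch.same",
                        "reference.no_switch.different"))
    compNs <- cellMean(c("comparison.no_switch.same",
                         "comparison.no_switch.different"))
    refSw <- cellMean(c("reference.switch.same",
                        "reference.switch.different"))
    compSw <- cellMean(c("comparison.switch.same",
                         "comparison.switch.different"))
    refDiff <- m["reference.no_switch.different"] -
        m["reference.no_switch.same"]
    compDiff <- m["comparison.no_switch.different"] -
        m["comparison.no_switch.same"]
    list(
        updating = c(cost = refNs - compNs,
                     ratio = (refNs - compNs) / ((refNs + compNs) / 2)),
        substitution = c(
            cost = unname(refDiff - compDiff),
            ratio = unname(refDiff / refNs - compDiff / compNs)),
        gate_opening = c(cost = refSw - refNs,
                         ratio = (refSw - refNs) / ((refSw + refNs) / 2)),
        gate_closing = c(cost = compSw - compNs,
                         ratio = (compSw - compNs) /
                             ((compSw + compNs) / 2)))
}

#' Subprocess RT costs and ratio indices from condition cell means
#'
#' Computes the four subprocess costs (ms) and the relative RT ratio index
#' (the condition RT difference divided by the mean of the two condition
#' means) from a named vector of the eight condition mean RTs. For
#' substitution, the ratio is the reference-cell ratio minus the
#' comparison-cell ratio.
#'
#' @param means named numeric vector over \code{\link{conditionLabels}}
#'   (switch cells may be omitted if only updating/substitution are
#'   needed).
#' @return data.frame with columns \code{subprocess}, \code{cost_ms},
#'   \code{ratio}.
#' @export
#' @examples
#' m <- setNames(c(477, 592, 509, 625, 451, 511, 526, 620),
#'               conditionLabels())
#' rtCostsFromCellMeans(m)
rtCostsFromCellMeans <- function(means) {
    have <- names(means)
    full <- stats::setNames(rep(NA_real_, 8), conditionLabels())
    full[intersect(have, names(full))] <- means[intersect(have,
                                                          names(full))]
    res <- costAndRatioFromCellMeans(full)
    data.frame(subprocess = names(res),
               cost_ms = vapply(res, `[[`, numeric(1), "cost"),
               ratio = vapply(res, `[[`, numeric(1), "ratio"),
               row.names = NULL)
}

#' Per-subject subprocess RT costs from trial-level behaviour
#'
#' Filters to correct, answered trials with valid RTs (>= 150 ms),
#' averages RT within each of the eight condition cells per subject, and
#' applies the subprocess contrast algebra. Subjects missing a cell
#' required by an effect get \code{NA} for that effect (dropped per
#' effect, not globally).
#'
#' @param behaviour trial table(s) from \code{\link{simulateBehaviour}}
#'   (or equivalent) with columns \code{subject}, \code{label},
#'   \code{rt_ms}, \code{correct}; a list of per-subject tables is also
#'   accepted.
#' @param minRt validity floor in ms (default 150).
#' @return data.frame with one row per subject x subprocess: columns
#'   \code{subject}, \code{subprocess}, \code{cost_ms}, \code{ratio}.
#' @export
rtCosts <- function(behaviour, minRt = 150) {
    if (is.list(behaviour) && !is.data.frame(behaviour))
        behaviour <- do.call(rbind, behaviour)
    need <- c("subject", "label", "rt_ms", "correct")
    if (!all(need %in% names(behaviour)))
        stop("behaviour must contain columns: ",
             paste(need, collapse = ", "))
    ok <- !is.na(behaviour$label) & !is.na(behaviour$correct) &
        behaviour$correct & !is.na(behaviour$rt_ms) &
        behaviour$rt_ms >= minRt
    b <- behaviour[ok, ]
    out <- lapply(split(b, b$subject), function(d) {
        m <- tapply(d$rt_ms, factor(d$label, levels = conditionLabels()),
                    mean)
        cr <- costAndRatioFromCellMeans(m)
        data.frame(subject = d$subject[1L], subprocess = names(cr),
                   cost_ms = vapply(cr, `[[`, numeric(1), "cost"),
                   ratio = vapply(cr, `[[`, numeric(1), "ratio"),
                   row.names = NULL)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Difference potentials for the four subprocesses
#'
#' Sample-wise signed combination of per-condition evoked potentials using
#' the \code{\link{subprocessContrasts}} weights. The operation is linear
#' in the evoked data.
#'
#' @param evoked named list of \linkS4class{Evoked} (names are condition
#'   labels), as returned by \code{\link{averageConditions}}.
#' @param contrasts contrast set (default \code{subprocessContrasts()}).
#' @return Named list of channels x samples matrices, one per subprocess.
#' @export
differencePotentials <- function(evoked,
                                 contrasts = subprocessContrasts()) {
    lapply(contrasts, function(w) {
        used <- names(w)[w != 0]
        missing <- setdiff(used, names(evoked))
        if (length(missing))
            stop("missing condition average(s): ",
                 paste(missing, collapse = ", "))
        Reduce(`+`, lapply(used, function(lab)
            w[lab] * evoked[[lab]]@data))
    })
}

#' Mean amplitude of a difference potential in a time window
#'
#' Arithmetic mean over the samples in the half-open window
#' \code{[start, end)} ms, per requested electrode.
#'
#' @param diff channels x samples matrix (a difference potential).
#' @param times sample times in ms.
#' @param window \code{c(start, end)} in ms.
#' @param channelLabels channel names for the rows of \code{diff}.
#' @param electrodes electrodes to return (default all).
#' @return Named numeric vector of mean amplitudes (microvolt).
#' @export
windowMean <- function(diff, times, window, channelLabels = rownames(diff),
                       electrodes = channelLabels) {
    if (is.null(channelLabels))
        channelLabels <- paste0("ch", seq_len(nrow(diff)))
    idx <- windowIndex(times, window)
    missing <- setdiff(electrodes, channelLabels)
    if (length(missing))
        stop("unknown electrode(s): ", paste(missing, collapse = ", "))
    rows <- match(electrodes, channelLabels)
    stats::setNames(rowMeans(diff[rows, idx, drop = FALSE]), electrodes)
}

#' Analysis time windows per subprocess
#'
#' The default mean-amplitude windows: updating 80-180, 300-400 and
#' 400-1000 ms; substitution 250-600 and 550-750 ms; gate opening 150-250,
#' 300-500 and 500-700 ms; gate closing 150-300 and 300-600 ms.
#'
#' @return Named list (per subprocess) of two-element windows in ms.
#' @export
analysisWindows <- function() {
    list(updating = list(c(80, 180), c(300, 400), c(400, 1000)),
         substitution = list(c(250, 600), c(550, 750)),
         gate_opening = list(c(150, 250), c(300, 500), c(500, 700)),
         gate_closing = list(c(150, 300), c(300, 600)))
}
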