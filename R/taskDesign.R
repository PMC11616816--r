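#' Generate a balanced reference-back trial sequence
#'
#' Builds the full session: \code{nBlocks} blocks of \code{trialsPerBlock}
#' trials, each trial a letter (X or O) inside a red (reference) or blue
#' (comparison) frame. Within every block the reference/comparison counts,
#' the gate-switch proportion among classifiable trials, and the
#' same/different required responses are balanced by constrained resampling
#' to within \code{balanceTolerance} trials of their targets. The first
#' trial of each block is forced to be a reference trial and carries an
#' undefined gate-switch status (it has no within-block predecessor), which
#' also guarantees that a reference letter exists for all later trials.
#'
#' Stimulus duration is jittered around 500 ms (+/- 50 ms) and the
#' pre-stimulus fixation interval around 1400 ms (+/- 100 ms), both on a
#' 16.6 ms display-frame grid. The sequence is a deterministic function of
#' the design, including its seed.
#'
#' @param design A \linkS4class{SessionDesign}.
#' @param maxTries resampling attempts per block before giving up.
#' @return A data.frame with one row per trial: \code{block}, \code{trial},
#'   \code{onset_ms}, \code{frame}, \code{letter}, \code{gate_switch},
#'   \code{required_response}, \code{label}, \code{stim_dur_ms},
#'   \code{isi_ms}. Undefined entries are \code{NA}.
#' @export
#' @examples
#' trials <- generateSession(sessionDesign(nBlocks = 1, trialsPerBlock = 20))
#' table(trials$frame)
generateSession <- function(design, maxTries = 5000L) {
    stopifnot(is(design, "SessionDesign"))
    validObject(design)
    tpb <- design@trialsPerBlock
    tol <- design@balanceTolerance
    nClass <- tpb - 1L

    withSeed(design@seed, {
        blocks <- vector("list", design@nBlocks)
        for (b in seq_len(design@nBlocks)) {
            ## switch count: binomial draw restricted to the tolerance band
            kAll <- 0:nClass
            ok <- abs(kAll / nClass - design@pSwitch) <= tol / tpb
            if (!any(ok))
                stop("infeasible balance constraints: no admissible ",
                     "switch count for pSwitch = ", design@pSwitch)
            kVals <- kAll[ok]
            w <- stats::dbinom(kVals, nClass, design@pSwitch)
            k <- if (length(kVals) == 1L) kVals else
                sample(kVals, 1L, prob = w)

            ## frame sequence: first trial reference, k switches among the
            ## rest; resample switch positions until the reference count
            ## lands inside the tolerance band
            frames <- NULL
            for (i in seq_len(maxTries)) {
                sw <- logical(nClass)
                sw[sample.int(nClass, k)] <- TRUE
                isRef <- logical(tpb)
                isRef[1L] <- TRUE
                for (j in seq_len(nClass))
                    isRef[j + 1L] <- xor(isRef[j], sw[j])
                if (abs(sum(isRef) - design@pReference * tpb) <= tol) {
                    frames <- ifelse(isRef, "reference", "comparison")
                    break
                }
            }
            if (is.null(frames))
                stop("could not satisfy balance constraints in block ", b,
                     " after ", maxTries, " attempts")
            blocks[[b]] <- data.frame(
                block = b, trial = seq_len(tpb), frame = frames,
                gate_switch = c(NA, ifelse(sw, "switch", "no_switch")),
                stringsAsFactors = FALSE)
        }
        trials <- do.call(rbind, blocks)

        ## desired responses: balance same/different inside each
        ## frame x gate-switch cell of each block
        trials$desired <- NA_character_
        for (b in seq_len(design@nBlocks)) {
            inb <- trials$block == b & !is.na(trials$gate_switch)
            for (fr in c("reference", "comparison"))
                for (gs in c("no_switch", "switch")) {
                    cell <- which(inb & trials$frame == fr &
                                      trials$gate_switch == gs)
                    n <- length(cell)
                    if (!n) next
                    frac <- (design@pSame * n) %% 1
                    nSame <- floor(design@pSame * n) +
                        (stats::runif(1) < frac)
                    resp <- sample(c(rep("same", nSame),
                                     rep("different", n - nSame)))
                    trials$desired[cell] <- resp
                }
        }

        ## letters: walk the sequence keeping the current reference letter
        letters2 <- c("X", "O")
        refLetter <- NA_character_
        trials$letter <- NA_character_
        for (i in seq_len(nrow(trials))) {
            des <- trials$desired[i]
            if (is.na(refLetter) || is.na(des))
                trials$letter[i] <- sample(letters2, 1L)
            else if (des == "same")
                trials$letter[i] <- refLetter
            else
                trials$letter[i] <- setdiff(letters2, refLetter)
            if (trials$frame[i] == "reference")
                refLetter <- trials$letter[i]
        }
        trials$desired <- NULL

        ## timing: fixation (isi) precedes each stimulus
        n <- nrow(trials)
        trials$stim_dur_ms <- 500 + 16.6 * sample(-3:3, n, replace = TRUE)
        trials$isi_ms <- 1400 + 16.6 * sample(-6:6, n, replace = TRUE)
        trials$onset_ms <- cumsum(trials$isi_ms) +
            c(0, cumsum(trials$stim_dur_ms)[-n])

        classifyTrials(trials)
    })
}

#' Classify trials into the eight reference-back conditions
#'
#' Walks an ordered trial sequence and derives, for every trial, the
#' gate-switch status (frame differs from the immediately preceding trial
#' in the same block; undefined for the first trial of a block) and the
#' required response (\code{"same"} iff the letter equals the letter of the
#' most recent preceding reference trial; undefined when no reference trial
#' precedes). The working reference letter is updated only at reference
#' trials, after the comparison for that trial is made. Trials with both
#' fields defined receive one of the eight \code{\link{conditionLabels}}.
#'
#' @param trials data.frame with columns \code{block}, \code{frame},
#'   \code{letter}, ordered by onset.
#' @return The input with (re)computed columns \code{gate_switch},
#'   \code{required_response} and \code{label}.
#' @export
#' @examples
#' seqdf <- data.frame(block = 1, frame = c("reference", "comparison",
#'   "comparison", "reference", "reference"),
#'   letter = c("X", "X", "O", "O", "O"))
#' classifyTrials(seqdf)[, c("gate_switch", "required_response")]
classifyTrials <- function(trials) {
    if (!nrow(trials)) {
        trials$gate_switch <- character(0)
        trials$required_response <- character(0)
        trials$label <- character(0)
        return(trials)
    }
    stopifnot(all(c("block", "frame", "letter") %in% names(trials)))
    n <- nrow(trials)
    gs <- rep(NA_character_, n)
    rr <- rep(NA_character_, n)
    refLetter <- NA_character_
    for (i in seq_len(n)) {
        if (i > 1L && trials$block[i] == trials$block[i - 1L])
            gs[i] <- if (trials$frame[i] == trials$frame[i - 1L])
                "no_switch" else "switch"
        if (!is.na(refLetter))
            rr[i] <- if (trials$letter[i] == refLetter) "same" else
                "different"
        if (trials$frame[i] == "reference")
            refLetter <- trials$letter[i]
    }
    trials$gate_switch <- gs
    trials$required_response <- rr
    trials$label <- ifelse(is.na(gs) | is.na(rr), NA_character_,
                           paste(trials$frame, gs, rr, sep = "."))
    trials
}

#' Read or write a trial event table (TSV)
#'
#' Events are exchanged as a BIDS-events-like UTF-8 TSV with a header row
#' and columns \code{block}, \code{trial}, \code{onset_ms}, \code{frame},
#' \code{letter}, \code{gate_switch}, \code{required_response},
#' \code{stim_dur_ms}, \code{isi_ms}; behavioural columns (\code{rt_ms},
#' \code{correct}) are carried through when present. Undefined values are
#' written as \code{"n/a"}.
#'
#' @param trials data.frame of trials (see \code{\link{generateSession}}).
#' @param path file path.
#' @return \code{readEvents} returns the trial data.frame;
#'   \code{writeEvents} returns \code{path} invisibly.
#' @export
writeEvents <- function(trials, path) {
    cols <- c("block", "trial", "onset_ms", "frame", "letter",
              "gate_switch", "required_response", "stim_dur_ms", "isi_ms",
              "label", "rt_ms", "correct")
    out <- trials[, intersect(cols, names(trials)), drop = FALSE]
    for (j in seq_along(out))
        out[[j]] <- ifelse(is.na(out[[j]]), "n/a", as.character(out[[j]]))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            na.strings = "n/a", stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    for (col in c("block", "trial"))
        if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
    for (col in c("onset_ms", "stim_dur_ms", "isi_ms", "rt_ms"))
        if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
    if ("correct" %in% names(df)) df$correct <- as.logical(df$correct)
    df
}
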