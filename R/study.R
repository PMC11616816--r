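#' StudyReport: full pipeline output bundle
#'
#' Returned by \code{\link{runStudy}}; slots hold the report tables and
#' intermediate artifacts of a complete simulate - preprocess - decompose -
#' test run.
#'
#' @slot rtTable condition mean RT table (group x condition, mean and SD).
#' @slot amplitudeTable window mean-amplitude table (group x subprocess x
#'   window x electrode).
#' @slot behaviouralStats subprocess-level behavioural statistics.
#' @slot erpStats window mean-amplitude mixed-ANOVA statistics.
#' @slot costs per-subject subprocess costs and ratios.
#' @slot accuracy per-group accuracy/incorrect/miss summary.
#' @slot tmax named list of \linkS4class{PermutationResult} per group and
#'   subprocess.
#' @slot sources per-source group comparison table (empty if disabled).
#' @slot exclusions subjects dropped with the stage that dropped them.
#' @slot config the configuration the run is a deterministic function of.
#' @export
setClass("StudyReport",
    representation(rtTable = "data.frame", amplitudeTable = "data.frame",
                   behaviouralStats = "data.frame",
                   erpStats = "data.frame", costs = "data.frame",
                   accuracy = "data.frame", tmax = "list",
                   sources = "data.frame", exclusions = "character",
                   config = "list"))

setMethod("show", "StudyReport", function(object) {
    ny <- object@config$nYounger; no <- object@config$nOlder
    cat("StudyReport:", ny, "+", no, "simulated subjects\n")
    if (length(object@exclusions))
        cat("  excluded:", paste(object@exclusions, collapse = ", "),
            "\n")
    cat("  tables: rt", paste(dim(object@rtTable), collapse = "x"),
        "| amplitudes", paste(dim(object@amplitudeTable),
                              collapse = "x"),
        "| behavioural stats", nrow(object@behaviouralStats), "rows",
        "| ERP stats", nrow(object@erpStats), "rows\n")
    cat("  tmax tests:", length(object@tmax), "\n")
})

#' Default 12-electrode analysis montage
#'
#' The lateral-plus-midline grid used for the mass-univariate analysis
#' (F3, Fz, F4, C3, Cz, C4, P3, Pz, P4, O1, Oz, O2); the midline subset
#' (Fz, Cz, Pz, Oz) is the ANTERIORITY factor of the window ANOVAs.
#'
#' @return Character vector of 12 channel names.
#' @export
analysisMontage <- function() {
    c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4",
      "O1", "Oz", "O2")
}

## anterior-posterior scalp weight profiles over a named montage
scalpProfile <- function(channelLabels, focus = c("occipital", "frontal",
                                                  "parietal", "broad")) {
    focus <- match.arg(focus)
    row <- substr(channelLabels, 1L, 1L)
    w <- switch(focus,
        occipital = c(F = 0.05, C = 0.15, P = 0.55, O = 1)[row],
        frontal = c(F = 1, C = 0.55, P = 0.2, O = 0.05)[row],
        parietal = c(F = 0.1, C = 0.5, P = 1, O = 0.7)[row],
        broad = rep(0.8, length(row)))
    w <- unname(w)
    w[is.na(w)] <- 0.3
    w
}

#' Default ERP generating templates per simulated age group
#'
#' Component sets that reproduce the qualitative structure of the four
#' difference potentials: a condition-independent visual response (cancels
#' in every contrast), posterior updating negativities (early and
#' sustained, the sustained one larger in the younger group), a
#' substitution positivity that is frontal and earlier in the younger
#' group but posterior and later in the older group, parieto-occipital
#' gate-opening components (larger in the younger group), and
#' age-invariant gate-closing components (occipital negativity, frontal
#' positivity). Amplitudes are in microvolt at the weight-1 electrode.
#'
#' @param group \code{"younger"} or \code{"older"}.
#' @param channelLabels montage (default \code{\link{analysisMontage}}).
#' @param sfreq sampling rate in Hz.
#' @param noiseSd,artifactRate noise and artifact levels passed through to
#'   \code{\link{erpTemplate}}.
#' @return An \code{\link{erpTemplate}}.
#' @export
defaultErpTemplate <- function(group = c("younger", "older"),
                               channelLabels = analysisMontage(),
                               sfreq = 250, noiseSd = 8,
                               artifactRate = 0.05) {
    group <- match.arg(group)
    young <- group == "younger"
    refNs <- c(reference.no_switch.same = 1,
               reference.no_switch.different = 1)
    compSw <- c(comparison.switch.same = 1,
                comparison.switch.different = 1)
    refSw <- c(reference.switch.same = 1,
               reference.switch.different = 1)
    subst <- c(reference.no_switch.different = 0.25,
               reference.no_switch.same = -0.25,
               comparison.no_switch.different = -0.25,
               comparison.no_switch.same = 0.25)
    all8 <- stats::setNames(rep(1, 8), conditionLabels())
    cmp <- function(label, lat, wid, amp, focus, cw)
        list(label = label, latencyMs = lat, widthMs = wid,
             amplitude = amp,
             channelWeights = scalpProfile(channelLabels, focus),
             conditionWeights = cw)
    components <- list(
        cmp("visual evoked", 110, 35, 5, "occipital", all8),
        cmp("updating early negativity", 130, 35,
            if (young) -1.9 else -1.0, "occipital", refNs),
        cmp("updating sustained negativity", 650, 220,
            if (young) -1.8 else -1.65, "occipital", refNs),
        if (young)
            cmp("substitution positivity", 420, 110, 0.8, "frontal",
                subst)
        else
            cmp("substitution positivity", 650, 90, 1.6, "occipital",
                subst),
        cmp("gate opening negativity", 200, 40,
            if (young) -0.2 else -1.6, "occipital", refSw),
        cmp("gate opening positivity", 420, 120,
            if (young) 1.9 else 0.3, "parietal", refSw),
        cmp("gate closing negativity", 225, 50, -0.9, "occipital",
            compSw),
        cmp("gate closing positivity", 450, 120, 0.7, "frontal",
            compSw))
    erpTemplate(components = components, channelLabels = channelLabels,
                noiseSd = noiseSd, noiseSpectrum = "one_over_f",
                artifactRate = artifactRate, artifactAmplitude = 200,
                sfreq = sfreq, tmin = -100, tmax = 1000)
}

#' Study configuration
#'
#' Bundles every parameter of a full simulated study. Defaults follow the
#' canonical two-cohort design: 24 younger and 23 older subjects, nine
#' 80-trial blocks, reference probability .5, switch probability .25,
#' younger/older behavioural parameters matching the published group cell
#' means, the 12-channel analysis montage at 250 Hz, 30 Hz Kaiser FIR
#' low-pass (beta 12.2653, 10 Hz transition band), 100 microvolt
#' peak-to-peak rejection, 10000-permutation tmax tests at familywise
#' alpha .05, and JZS prior scale 0.707.
#'
#' @param nYounger,nOlder cohort sizes (>= 2).
#' @param design a \linkS4class{SessionDesign}.
#' @param paramsYounger,paramsOlder \code{\link{behaviourParams}} per
#'   group.
#' @param templateYounger,templateOlder \code{\link{erpTemplate}} per
#'   group; built from \code{\link{defaultErpTemplate}} when NULL.
#' @param channels analysis montage.
#' @param sfreq simulation sampling rate (Hz).
#' @param windows per-subprocess analysis windows
#'   (\code{\link{analysisWindows}}).
#' @param lowpass list with \code{cutoff}, \code{kaiserBeta},
#'   \code{transitionBandwidth} (Hz).
#' @param rejectThreshold peak-to-peak rejection threshold (microvolt).
#' @param minRt RT validity floor (ms).
#' @param nPerm,alpha,priorScale inferential settings.
#' @param sourceAnalysis run the group source comparison.
#' @param nSources sources in the synthetic lead field.
#' @param minEpochs minimum surviving epochs per condition per subject.
#' @param seed master seed; the whole run is a deterministic function of
#'   the configuration.
#' @return A \code{StudyConfig} list.
#' @export
studyConfig <- function(nYounger = 24, nOlder = 23,
                        design = sessionDesign(),
                        paramsYounger = NULL, paramsOlder = NULL,
                        templateYounger = NULL, templateOlder = NULL,
                        channels = analysisMontage(), sfreq = 250,
                        windows = analysisWindows(),
                        lowpass = list(cutoff = 30,
                                       kaiserBeta = 12.2653,
                                       transitionBandwidth = 10),
                        rejectThreshold = 100, minRt = 150,
                        nPerm = 10000, alpha = 0.05,
                        priorScale = 0.707, sourceAnalysis = TRUE,
                        nSources = 60, minEpochs = 5, seed = 1) {
    if (nYounger < 2 || nOlder < 2) stop("cohort sizes must be >= 2")
    if (is.null(paramsYounger))
        paramsYounger <- behaviourParams(
            baseRt = 481, ageSlowing = 0, costUpdating = 53,
            costSubstitution = 55, costGateOpening = 33,
            costGateClosing = 92, rtSd = 0.2, pIncorrect = 0.11,
            pMiss = 0.031)
    if (is.null(paramsOlder))
        paramsOlder <- behaviourParams(
            baseRt = 481, ageSlowing = 134, costUpdating = 61,
            costSubstitution = 123, costGateOpening = 55,
            costGateClosing = 63, rtSd = 0.2, pIncorrect = 0.141,
            pMiss = 0.05)
    if (is.null(templateYounger))
        templateYounger <- defaultErpTemplate("younger", channels, sfreq)
    if (is.null(templateOlder))
        templateOlder <- defaultErpTemplate("older", channels, sfreq)
    for (w in unlist(windows, recursive = FALSE))
        if (w[1L] < templateYounger$tmin || w[2L] > templateYounger$tmax +
                1e-9)
            stop("analysis window [", w[1L], ", ", w[2L],
                 ") lies outside the epoch")
    structure(list(nYounger = as.integer(nYounger),
                   nOlder = as.integer(nOlder), design = design,
                   paramsYounger = paramsYounger,
                   paramsOlder = paramsOlder,
                   templateYounger = templateYounger,
                   templateOlder = templateOlder, channels = channels,
                   sfreq = sfreq, windows = windows, lowpass = lowpass,
                   rejectThreshold = rejectThreshold, minRt = minRt,
                   nPerm = as.integer(nPerm), alpha = alpha,
                   priorScale = priorScale,
                   sourceAnalysis = isTRUE(sourceAnalysis),
                   nSources = as.integer(nSources),
                   minEpochs = as.integer(minEpochs),
                   seed = as.integer(seed)),
              class = "StudyConfig")
}

#' Accuracy, incorrect and miss rates per group
#'
#' Rates partition the classifiable trials: accuracy (correct responses),
#' incorrect responses (answered but wrong), and misses (no response
#' within the deadline); the three sum to 100 percent. Trials with no
#' defined required response (the session's first trial) are excluded
#' from the denominator.
#'
#' @param behaviour list of per-subject behaviour tables (or one combined
#'   table) with columns \code{correct}, \code{miss} and \code{group}
#'   (added if absent, from the \code{group} argument).
#' @param group optional group label when \code{behaviour} has no
#'   \code{group} column.
#' @return data.frame with columns \code{group}, \code{accuracy_pct},
#'   \code{incorrect_pct}, \code{miss_pct}, \code{n_trials}.
#' @export
accuracySummary <- function(behaviour, group = "all") {
    if (is.list(behaviour) && !is.data.frame(behaviour))
        behaviour <- do.call(rbind, behaviour)
    if (!"group" %in% names(behaviour)) behaviour$group <- group
    b <- behaviour[!is.na(behaviour$correct), ]
    out <- lapply(split(b, b$group), function(d) {
        n <- nrow(d)
        miss <- sum(d$miss)
        corr <- sum(d$correct)
        data.frame(group = d$group[1L],
                   accuracy_pct = 100 * corr / n,
                   incorrect_pct = 100 * (n - corr - miss) / n,
                   miss_pct = 100 * miss / n, n_trials = n)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## Table-5-shaped statistics from per-subject subprocess scores.
## For a 2-level within contrast with a between factor the split-plot F
## tests reduce to t statistics on the per-subject contrast scores:
## presence = unweighted mean of the group means against zero,
## interaction = group difference of the scores.
contrastStats <- function(scoreA, scoreB, priorScale = 0.707) {
    scoreA <- scoreA[!is.na(scoreA)]
    scoreB <- scoreB[!is.na(scoreB)]
    n1 <- length(scoreA); n2 <- length(scoreB)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * stats::var(scoreA) +
                (n2 - 1) * stats::var(scoreB)) / df
    tPres <- (mean(scoreA) + mean(scoreB)) / 2 /
        sqrt(sp2 * (1 / n1 + 1 / n2) / 4)
    tInt <- (mean(scoreA) - mean(scoreB)) /
        sqrt(sp2 * (1 / n1 + 1 / n2))
    mw <- mannWhitney(scoreA, scoreB)
    bf <- jzsBfTtest(scoreA, scoreB, priorScale = priorScale)
    list(presence = list(F = tPres^2, dfNum = 1, dfDen = df,
                         p = 2 * stats::pt(abs(tPres), df,
                                           lower.tail = FALSE),
                         partialEtaSq = tPres^2 / (tPres^2 + df)),
         interaction = list(F = tInt^2, dfNum = 1, dfDen = df,
                            p = 2 * stats::pt(abs(tInt), df,
                                              lower.tail = FALSE),
                            partialEtaSq = tInt^2 / (tInt^2 + df)),
         size = list(U = mw$U, pU = mw$p, rankBiserial = mw$rankBiserial,
                     bf10 = bf$bf10, t = bf$t))
}

#' Run the full simulated study pipeline
#'
#' Executes simulate, preprocess, decompose and test for both cohorts:
#' per-subject session generation, behaviour and epoch simulation,
#' low-pass filtering, baseline correction, peak-to-peak artifact
#' rejection, correct-trial condition averaging, subprocess difference
#' potentials, RT costs and ratio indices, tmax permutation maps per
#' group and subprocess, window mean-amplitude mixed ANOVAs with
#' Greenhouse-Geisser correction and BIC inclusion Bayes factors,
#' behavioural subprocess statistics (presence, group difference,
#' Mann-Whitney and JZS BF size comparisons), accuracy summaries, and an
#' optional sLORETA group source comparison. Subjects failing the
#' minimum-epochs criterion in any condition are excluded from the ERP
#' branch (logged in the report). The whole run is a deterministic
#' function of the configuration.
#'
#' @param config A \code{\link{studyConfig}}.
#' @param verbose print progress.
#' @return A \linkS4class{StudyReport}.
#' @export
runStudy <- function(config = studyConfig(), verbose = FALSE) {
    stopifnot(inherits(config, "StudyConfig"))
    say <- function(...) if (verbose) message(...)
    kernel <- designKaiserFir(config$lowpass$cutoff, config$sfreq,
                              beta = config$lowpass$kaiserBeta,
                              transitionBandwidth =
                                  config$lowpass$transitionBandwidth)
    midline <- intersect(c("Fz", "Cz", "Pz", "Oz"), config$channels)
    groups <- list(
        younger = list(n = config$nYounger,
                       params = config$paramsYounger,
                       template = config$templateYounger),
        older = list(n = config$nOlder, params = config$paramsOlder,
                     template = config$templateOlder))

    behaviour <- list()
    winRows <- list()
    diffWaves <- list()    # [[group]][[subprocess]] subject x ch x samp
    topo <- list()         # per-subject window topography for sources
    exclusions <- character()
    times <- NULL
    gseed <- c(younger = config$seed, older = config$seed + 500000L)

    for (g in names(groups)) {
        gi <- groups[[g]]
        eff <- withSeed(gseed[[g]], list(
            base = stats::rnorm(gi$n, 0, 60),
            amp = pmax(0.1, stats::rnorm(gi$n, 1, 0.25)),
            seeds = sample.int(2^30, 2L * gi$n)))
        for (i in seq_len(gi$n)) {
            sid <- sprintf("%s_%02d", g, i)
            say("subject ", sid)
            p <- gi$params
            p$baseRt <- max(p$baseRt + eff$base[i],
                            151 + abs(p$costSubstitution) / 2)
            des <- config$design
            des@seed <- eff$seeds[2L * i - 1L]
            trials <- tryCatch(generateSession(des), error = function(e)
                stop("task_design stage failed for ", sid, ": ",
                     conditionMessage(e)))
            beh <- simulateBehaviour(trials, p,
                                     seed = eff$seeds[2L * i])
            beh$subject <- sid
            beh$group <- g
            behaviour[[sid]] <- beh

            epochs <- simulateEpochs(trials, gi$template,
                                     behaviour = beh,
                                     seed = eff$seeds[2L * i],
                                     amplitudeScale = eff$amp[i])
            epochs@subjectId <- sid
            epochs <- applyZeroPhase(epochs, kernel)
            epochs <- baselineCorrect(epochs)
            epochs <- rejectArtifacts(epochs,
                                      config$rejectThreshold)$kept
            evoked <- tryCatch(
                averageConditions(epochs, correctOnly = TRUE,
                                  require = conditionLabels(),
                                  minEpochs = config$minEpochs),
                tooFewEpochs = function(e) e)
            if (inherits(evoked, "tooFewEpochs")) {
                exclusions <- c(exclusions,
                                paste0(sid, " (",
                                       conditionMessage(evoked), ")"))
                next
            }
            if (is.null(times)) times <- epochs@times
            diffs <- differencePotentials(evoked)
            for (sp in names(diffs)) {
                diffWaves[[g]][[sp]] <-
                    c(diffWaves[[g]][[sp]], list(diffs[[sp]]))
                for (wi in seq_along(config$windows[[sp]])) {
                    w <- config$windows[[sp]][[wi]]
                    amps <- windowMean(diffs[[sp]], times, w,
                                       channelLabels = config$channels,
                                       electrodes = midline)
                    winRows[[length(winRows) + 1L]] <- data.frame(
                        subject = sid, group = g, subprocess = sp,
                        window = paste0(w[1L], "-", w[2L]),
                        electrode = names(amps), amplitude = amps,
                        row.names = NULL)
                }
            }
            if (config$sourceAnalysis) {
                w <- config$windows$substitution[[
                    length(config$windows$substitution)]]
                topo[[sid]] <- list(
                    group = g,
                    active = windowMean(diffs$substitution, times, w,
                                        channelLabels =
                                            config$channels),
                    baseline = windowMean(diffs$substitution, times,
                                          c(times[1L], 0),
                                          channelLabels =
                                              config$channels))
            }
        }
    }

    behaviourTab <- do.call(rbind, behaviour)
    rownames(behaviourTab) <- NULL
    costs <- rtCosts(behaviourTab, minRt = config$minRt)
    costs$group <- sub("_.*$", "", costs$subject)
    windowTab <- do.call(rbind, winRows)

    ## Table 3 shape: condition mean RT per group
    ok <- !is.na(behaviourTab$label) & !is.na(behaviourTab$correct) &
        behaviourTab$correct & !is.na(behaviourTab$rt_ms) &
        behaviourTab$rt_ms >= config$minRt
    bOK <- behaviourTab[ok, ]
    subjMeans <- stats::aggregate(
        rt_ms ~ subject + group + label, data = bOK, FUN = mean)
    rtTable <- do.call(rbind, lapply(
        split(subjMeans, subjMeans[c("group", "label")], drop = TRUE),
        function(d) data.frame(group = d$group[1L],
                               condition = d$label[1L],
                               mean_rt_ms = mean(d$rt_ms),
                               sd_rt_ms = stats::sd(d$rt_ms))))
    rownames(rtTable) <- NULL

    ## Table 5 shape: behavioural subprocess statistics
    behRows <- list()
    for (sp in unique(costs$subprocess))
        for (measure in c("cost_ms", "ratio")) {
            a <- costs[costs$subprocess == sp &
                           costs$group == "younger", measure]
            b <- costs[costs$subprocess == sp &
                           costs$group == "older", measure]
            cs <- contrastStats(a, b, config$priorScale)
            behRows[[length(behRows) + 1L]] <- data.frame(
                subprocess = sp, measure = measure,
                mean_younger = mean(a, na.rm = TRUE),
                mean_older = mean(b, na.rm = TRUE),
                F_presence = cs$presence$F, p_presence = cs$presence$p,
                petaSq_presence = cs$presence$partialEtaSq,
                F_interaction = cs$interaction$F,
                p_interaction = cs$interaction$p,
                petaSq_interaction = cs$interaction$partialEtaSq,
                U = cs$size$U, p_U = cs$size$pU,
                rank_biserial = cs$size$rankBiserial,
                bf10 = cs$size$bf10)
        }
    behaviouralStats <- do.call(rbind, behRows)

    ## Table 4 shape: group amplitude means
    amplitudeTable <- do.call(rbind, lapply(
        split(windowTab,
              windowTab[c("group", "subprocess", "window",
                          "electrode")], drop = TRUE),
        function(d) data.frame(
            group = d$group[1L], subprocess = d$subprocess[1L],
            window = d$window[1L], electrode = d$electrode[1L],
            mean_uv = mean(d$amplitude),
            sd_uv = stats::sd(d$amplitude))))
    rownames(amplitudeTable) <- NULL

    ## Table 6 shape: mixed ANOVA + inclusion BF per subprocess x window
    erpRows <- list()
    for (sp in unique(windowTab$subprocess))
        for (w in unique(windowTab$window[windowTab$subprocess == sp])) {
            d <- windowTab[windowTab$subprocess == sp &
                               windowTab$window == w, ]
            an <- mixedAnova(d, dv = "amplitude", within = "electrode",
                             between = "group", subject = "subject")
            bf <- bfInclusion(d, dv = "amplitude",
                              within = "electrode", between = "group",
                              subject = "subject")
            an$bfIncl <- bf$bfIncl[match(an$effect, bf$effect)]
            an$subprocess <- sp
            an$window <- w
            erpRows[[length(erpRows) + 1L]] <- an
        }
    erpStats <- do.call(rbind, erpRows)

    ## tmax permutation maps per group and subprocess (post-stimulus)
    tmaxRes <- list()
    post <- which(times >= 0)
    for (g in names(diffWaves))
        for (sp in names(diffWaves[[g]])) {
            arr <- simplify2array(diffWaves[[g]][[sp]])  # ch x s x subj
            arr <- aperm(arr, c(3, 1, 2))[, , post, drop = FALSE]
            tmaxRes[[paste(g, sp, sep = ".")]] <-
                tmaxTest(arr, nPerm = config$nPerm,
                         alpha = config$alpha,
                         seed = config$seed + 77L)
        }

    ## sLORETA group comparison on the late substitution window
    sources <- data.frame()
    if (config$sourceAnalysis && length(topo)) {
        lf <- makeSyntheticLeadField(length(config$channels),
                                     config$nSources,
                                     seed = config$seed + 99L)
        pw <- t(vapply(topo, function(tp) {
            act <- sourcePower(sloretaInverse(lf, tp$active))[, 1L]
            bl <- sourcePower(sloretaInverse(lf, tp$baseline))[, 1L]
            act / max(mean(bl), 1e-12)
        }, numeric(config$nSources)))
        grp <- vapply(topo, `[[`, character(1), "group")
        sources <- compareGroupSources(
            pw[grp == "younger", , drop = FALSE],
            pw[grp == "older", , drop = FALSE],
            alpha = 0.01, minCluster = 5L,
            seed = config$seed + 123L)
    }

    accuracy <- accuracySummary(behaviourTab)

    new("StudyReport", rtTable = rtTable,
        amplitudeTable = amplitudeTable,
        behaviouralStats = behaviouralStats, erpStats = erpStats,
        costs = costs, accuracy = accuracy, tmax = tmaxRes,
        sources = sources, exclusions = exclusions,
        config = unclass(config))
}
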