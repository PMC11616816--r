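#' Behavioural generating parameters for one simulated group
#'
#' Latent mean reaction time for a trial is an additive combination of a
#' base RT, a group slowing term, and the four subprocess costs the trial's
#' condition triggers: updating on reference trials, gate opening on switch
#' reference trials, gate closing on switch comparison trials, and
#' substitution as a centred +/- cost/2 contrast between different and same
#' responses within reference trials. The centred coding makes every
#' Table-style contrast estimator an unbiased estimate of its cost (the
#' updating contrast averages the same/different sub-cells, so a one-sided
#' substitution surcharge would leak half of itself into updating).
#'
#' RTs are drawn from a shifted lognormal (shift 150 ms, log-scale spread
#' \code{rtSd}) whose mean equals the latent mean. Misses occur with
#' probability \code{pMiss}; responses slower than the trial's deadline
#' (stimulus duration plus the following fixation interval, 1900 +/- 150 ms)
#' also become misses. Responses are incorrect with probability
#' \code{pIncorrect}.
#'
#' @param baseRt mean RT (ms) of the no-switch comparison baseline.
#' @param ageSlowing additive group slowing (ms).
#' @param costUpdating,costSubstitution,costGateOpening,costGateClosing
#'   subprocess costs (ms).
#' @param rtSd log-scale spread of the shifted lognormal.
#' @param pIncorrect,pMiss error probabilities; must sum below 1.
#' @param responseDeadline fallback deadline (ms) when no following trial
#'   exists.
#' @return A validated parameter list of class \code{"BehaviourParams"}.
#' @export
behaviourParams <- function(baseRt = 480, ageSlowing = 0,
                            costUpdating = 49, costSubstitution = 55,
                            costGateOpening = 33, costGateClosing = 92,
                            rtSd = 0.2, pIncorrect = 0.11, pMiss = 0.031,
                            responseDeadline = 1900) {
    if (baseRt <= 150)
        stop("baseRt must exceed 150 ms: faster responses are invalid ",
             "by design")
    costs <- c(costUpdating, costSubstitution, costGateOpening,
               costGateClosing, ageSlowing)
    if (!all(is.finite(costs))) stop("costs must be finite")
    stopifnotScalarProb(pIncorrect, "pIncorrect")
    stopifnotScalarProb(pMiss, "pMiss")
    if (pIncorrect + pMiss >= 1)
        stop("pIncorrect + pMiss must be < 1")
    if (rtSd < 0) stop("rtSd must be >= 0")
    structure(list(baseRt = baseRt, ageSlowing = ageSlowing,
                   costUpdating = costUpdating,
                   costSubstitution = costSubstitution,
                   costGateOpening = costGateOpening,
                   costGateClosing = costGateClosing,
                   rtSd = rtSd, pIncorrect = pIncorrect, pMiss = pMiss,
                   responseDeadline = responseDeadline),
              class = "BehaviourParams")
}

#' Simulate per-trial behaviour for a classified session
#'
#' @param trials classified trial table (see \code{\link{classifyTrials}}).
#' @param params a \code{\link{behaviourParams}} object.
#' @param seed integer seed; output is deterministic given the seed.
#' @return \code{trials} with added columns \code{rt_ms} (NA for misses),
#'   \code{miss} and \code{correct} (NA where no required response is
#'   defined).
#' @export
simulateBehaviour <- function(trials, params, seed = 1) {
    stopifnot(inherits(params, "BehaviourParams"))
    need <- c("frame", "gate_switch", "required_response", "label")
    if (!all(need %in% names(trials)))
        stop("trials must be classified first (missing: ",
             paste(setdiff(need, names(trials)), collapse = ", "), ")")
    n <- nrow(trials)
    isRef <- trials$frame == "reference"
    isSwitch <- !is.na(trials$gate_switch) &
        trials$gate_switch == "switch"
    respSign <- ifelse(is.na(trials$required_response), 0,
                       ifelse(trials$required_response == "different",
                              1, -1))
    mu <- params$baseRt + params$ageSlowing +
        params$costUpdating * isRef +
        params$costSubstitution / 2 * respSign * isRef +
        params$costGateOpening * (isRef & isSwitch) +
        params$costGateClosing * (!isRef & isSwitch)
    if (any(mu <= 150))
        stop("latent mean RT at or below the 150 ms validity floor; ",
             "adjust baseRt or costs")

    deadline <- if (all(c("stim_dur_ms", "isi_ms") %in% names(trials)))
        trials$stim_dur_ms +
            c(trials$isi_ms[-1L], params$responseDeadline - 500)
    else rep(params$responseDeadline, n)

    withSeed(seed, {
        rt <- 150 + stats::rlnorm(n,
            meanlog = log(mu - 150) - params$rtSd^2 / 2,
            sdlog = params$rtSd)
        miss <- stats::runif(n) < params$pMiss | rt >= deadline
        wrong <- stats::runif(n) < params$pIncorrect /
            (1 - params$pMiss)
        trials$rt_ms <- ifelse(miss, NA_real_, rt)
        trials$miss <- miss
        trials$correct <- ifelse(is.na(trials$required_response),
                                 NA, !miss & !wrong)
        trials
    })
}

#' ERP generating template
#'
#' Each component is a Gaussian-in-time voltage bump with a per-channel
#' scalp weighting and signed per-condition coefficients; an epoch is the
#' sum of its components plus noise, with occasional high-amplitude
#' single-channel step artifacts to exercise peak-to-peak rejection.
#'
#' @param components list of components, each a list with fields
#'   \code{label}, \code{latencyMs}, \code{widthMs} (Gaussian SD),
#'   \code{amplitude} (microvolt), \code{channelWeights} (length =
#'   channels) and \code{conditionWeights} (named by
#'   \code{\link{conditionLabels}}; missing labels count as 0).
#' @param channelLabels ordered channel names.
#' @param noiseSd noise standard deviation (microvolt) per sample.
#' @param noiseSpectrum \code{"white"} or \code{"one_over_f"}.
#' @param artifactRate probability an epoch receives an artifact.
#' @param artifactAmplitude artifact step size (microvolt).
#' @param sfreq sampling rate (Hz).
#' @param tmin,tmax epoch limits (ms).
#' @return A validated template list of class \code{"ErpTemplate"}.
#' @export
erpTemplate <- function(components = list(),
                        channelLabels = paste0("ch", 1:12),
                        noiseSd = 8, noiseSpectrum = c("one_over_f",
                                                       "white"),
                        artifactRate = 0.05, artifactAmplitude = 200,
                        sfreq = 1000, tmin = -100, tmax = 1000) {
    noiseSpectrum <- match.arg(noiseSpectrum)
    for (cmp in components) {
        if (length(cmp$channelWeights) != length(channelLabels))
            stop("channelWeights length must equal the channel count in ",
                 "component '", cmp$label, "'")
        if (cmp$widthMs <= 0) stop("component width must be > 0")
    }
    stopifnotScalarProb(artifactRate, "artifactRate")
    structure(list(components = components,
                   channelLabels = channelLabels, noiseSd = noiseSd,
                   noiseSpectrum = noiseSpectrum,
                   artifactRate = artifactRate,
                   artifactAmplitude = artifactAmplitude,
                   sfreq = sfreq, tmin = tmin, tmax = tmax),
              class = "ErpTemplate")
}

## noise with unit SD per sample, channels x samples
epochNoise <- function(nCh, nS, spectrum) {
    if (spectrum == "white")
        return(matrix(stats::rnorm(nCh * nS), nCh, nS))
    ## spectrally shaped noise: amplitude ~ 1/sqrt(f), unit variance
    freqs <- seq_len(nS %/% 2)
    shape <- 1 / sqrt(freqs)
    out <- matrix(0, nCh, nS)
    for (ch in seq_len(nCh)) {
        spec <- complex(real = stats::rnorm(length(freqs)),
                        imaginary = stats::rnorm(length(freqs))) * shape
        full <- complex(length.out = nS)
        full[2:(length(freqs) + 1L)] <- spec
        full[nS - seq_len(length(freqs) - (nS %% 2 == 0)) + 1L] <-
            Conj(spec[seq_len(length(freqs) - (nS %% 2 == 0))])
        x <- Re(stats::fft(full, inverse = TRUE)) / nS
        out[ch, ] <- x / stats::sd(x)
    }
    out
}

#' Simulate multichannel ERP epochs for a classified session
#'
#' Every epoch is generated from its own deterministic sub-seed derived
#' from \code{seed} and the trial index, so simulation commutes with trial
#' reordering.
#'
#' @param trials classified trial table; rows define the epochs.
#' @param template an \code{\link{erpTemplate}}.
#' @param behaviour optional output of \code{\link{simulateBehaviour}} for
#'   the same trials, supplying \code{correct}/\code{rt_ms} metadata.
#' @param seed integer seed.
#' @param amplitudeScale multiplier applied to all component amplitudes
#'   (per-subject random effects enter here).
#' @return An \linkS4class{EpochSet}.
#' @export
simulateEpochs <- function(trials, template, behaviour = NULL, seed = 1,
                           amplitudeScale = 1) {
    stopifnot(inherits(template, "ErpTemplate"))
    if (!"label" %in% names(trials))
        stop("trials must be classified first")
    if (!is.null(behaviour)) {
        if (nrow(behaviour) != nrow(trials))
            stop("behaviour must have one row per trial")
        trials$correct <- behaviour$correct
        trials$rt_ms <- behaviour$rt_ms
    }
    if (!"correct" %in% names(trials)) trials$correct <- TRUE
    if (!"rt_ms" %in% names(trials)) trials$rt_ms <- NA_real_

    nCh <- length(template$channelLabels)
    times <- seq(template$tmin, template$tmax, by = 1000 / template$sfreq)
    nS <- length(times)
    nT <- nrow(trials)

    ## per-component spatiotemporal pattern, reused across trials
    patterns <- lapply(template$components, function(cmp) {
        bump <- cmp$amplitude *
            exp(-(times - cmp$latencyMs)^2 / (2 * cmp$widthMs^2))
        outer(cmp$channelWeights, bump)
    })
    condW <- lapply(template$components, function(cmp) {
        w <- stats::setNames(numeric(8), conditionLabels())
        ok <- intersect(names(cmp$conditionWeights), names(w))
        w[ok] <- cmp$conditionWeights[ok]
        w
    })

    ## per-epoch sub-seeds key on trial identity (block, trial) when
    ## available, so simulation commutes with row reordering
    idx <- if (all(c("block", "trial") %in% names(trials)))
        as.integer(trials$block) * 1000L + as.integer(trials$trial)
    else seq_len(nT)

    data <- array(0, dim = c(nT, nCh, nS))
    for (i in seq_len(nT)) {
        epoch <- matrix(0, nCh, nS)
        lab <- trials$label[i]
        if (!is.na(lab))
            for (k in seq_along(patterns)) {
                w <- condW[[k]][lab]
                if (w != 0)
                    epoch <- epoch + amplitudeScale * w * patterns[[k]]
            }
        withSeed(trialSeed(seed, idx[i]), {
            if (template$noiseSd > 0)
                epoch <- epoch + template$noiseSd *
                    epochNoise(nCh, nS, template$noiseSpectrum)
            if (stats::runif(1) < template$artifactRate) {
                ch <- sample.int(nCh, 1L)
                s0 <- sample.int(nS - 1L, 1L) + 1L
                epoch[ch, s0:nS] <- epoch[ch, s0:nS] +
                    sample(c(-1, 1), 1L) * template$artifactAmplitude
            }
        })
        data[i, , ] <- epoch
    }
    epochSet(data, sfreq = template$sfreq, times = times,
             channelLabels = template$channelLabels,
             trialInfo = trials, subjectId = "simulated")
}

#' Simulate a cohort of subjects
#'
#' Per-subject random effects: the base RT is drawn from a normal with SD
#' \code{subjectRtSd} around the group \code{baseRt}, and ERP component
#' amplitudes are scaled by a normal factor with SD \code{subjectAmpSd}
#' (truncated at 0.1), so between-subject variance exists for group-level
#' statistics.
#'
#' @param n number of subjects.
#' @param design a \linkS4class{SessionDesign}; each subject gets a fresh
#'   session seeded from \code{seed}.
#' @param params group \code{\link{behaviourParams}}.
#' @param template group \code{\link{erpTemplate}}, or \code{NULL} to skip
#'   epoch simulation (behaviour-only cohorts).
#' @param seed integer cohort seed.
#' @param subjectRtSd between-subject SD of base RT (ms).
#' @param subjectAmpSd between-subject SD of the amplitude scale factor.
#' @param groupLabel label stored with each subject.
#' @return List with \code{behaviour} (one classified+simulated trial table
#'   per subject) and, when \code{template} is given, \code{epochs} (one
#'   \linkS4class{EpochSet} per subject).
#' @export
simulateCohort <- function(n, design, params, template = NULL, seed = 1,
                           subjectRtSd = 60, subjectAmpSd = 0.25,
                           groupLabel = "group") {
    stopifnot(n >= 1)
    effects <- withSeed(seed, list(
        base = stats::rnorm(n, 0, subjectRtSd),
        amp = pmax(0.1, stats::rnorm(n, 1, subjectAmpSd)),
        seeds = sample.int(.Machine$integer.max - 1L, 2L * n)))
    behaviour <- vector("list", n)
    epochs <- if (is.null(template)) NULL else vector("list", n)
    for (i in seq_len(n)) {
        p <- params
        p$baseRt <- max(params$baseRt + effects$base[i], 151 +
                        abs(params$costSubstitution) / 2)
        des <- design
        des@seed <- effects$seeds[2L * i - 1L]
        trials <- generateSession(des)
        beh <- simulateBehaviour(trials, p, seed = effects$seeds[2L * i])
        beh$subject <- sprintf("%s_%02d", groupLabel, i)
        behaviour[[i]] <- beh
        if (!is.null(template)) {
            es <- simulateEpochs(trials, template, behaviour = beh,
                                 seed = effects$seeds[2L * i],
                                 amplitudeScale = effects$amp[i])
            es@subjectId <- beh$subject[1L]
            epochs[[i]] <- es
        }
    }
    list(behaviour = behaviour, epochs = epochs)
}
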