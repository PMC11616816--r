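#' Split-plot (mixed) ANOVA with Greenhouse-Geisser correction
#'
#' Classical two-way mixed ANOVA: one within-subject factor (every subject
#' observed at all levels, e.g. ANTERIORITY with Fz/Cz/Pz/Oz) and one
#' between-subject factor (e.g. AGE GROUP), with possibly unequal group
#' sizes. Sums of squares are the classical sequential decomposition
#' (between effect tested against the subject stratum, within effect and
#' interaction against the subject-by-level stratum). Sphericity is
#' addressed with the Greenhouse-Geisser epsilon computed from the pooled
#' within-group covariance of the level scores; corrected p-values scale
#' both degrees of freedom by epsilon. Effect size is partial eta squared,
#' \code{SS_effect / (SS_effect + SS_error)}.
#'
#' @param data long-format data.frame.
#' @param dv,within,between,subject column names.
#' @return data.frame with one row per effect (\code{between},
#'   \code{within}, \code{between:within}): \code{F}, \code{dfNum},
#'   \code{dfDen}, \code{p}, \code{ggEpsilon} (NA for the between effect),
#'   \code{pGG}, \code{partialEtaSq}.
#' @export
#' @examples
#' d <- expand.grid(subject = factor(1:10), electrode = factor(1:4))
#' d$group <- factor(rep(rep(c("a", "b"), each = 5), 4))
#' d$amplitude <- rnorm(nrow(d))
#' mixedAnova(d, "amplitude", "electrode", "group", "subject")
mixedAnova <- function(data, dv = "amplitude", within = "electrode",
                       between = "group", subject = "subject") {
    need <- c(dv, within, between, subject)
    if (!all(need %in% names(data)))
        stop("data must contain columns: ", paste(need, collapse = ", "))
    d <- data.frame(y = data[[dv]], w = factor(data[[within]]),
                    b = factor(data[[between]]),
                    s = factor(data[[subject]]))
    if (anyNA(d)) stop("missing values in the ANOVA table")
    tab <- table(d$s, d$w)
    if (any(tab != 1L))
        stop("every subject must contribute exactly one observation per ",
             "within-factor level")
    k <- nlevels(d$w)

    mod <- stats::aov(y ~ b * w + Error(s / w), data = d)
    sm <- summary(mod)
    pick <- function(stratum, row) {
        tabs <- sm[[stratum]][[1L]]
        rn <- trimws(rownames(tabs))
        i <- match(row, rn)
        if (is.na(i)) stop("effect '", row, "' missing from aov table")
        c(df = tabs$Df[i], ss = tabs$`Sum Sq`[i])
    }
    eB <- pick("Error: s", "b")
    rB <- pick("Error: s", "Residuals")
    eW <- pick("Error: s:w", "w")
    eI <- pick("Error: s:w", "b:w")
    rW <- pick("Error: s:w", "Residuals")

    ## Greenhouse-Geisser epsilon from the pooled within-group covariance
    Y <- matrix(NA_real_, nlevels(d$s), k,
                dimnames = list(levels(d$s), levels(d$w)))
    Y[cbind(as.integer(d$s), as.integer(d$w))] <- d$y
    grp <- d$b[match(levels(d$s), d$s)]
    Spool <- matrix(0, k, k)
    for (g in levels(grp)) {
        Yg <- Y[grp == g, , drop = FALSE]
        Spool <- Spool + stats::cov(Yg) * (nrow(Yg) - 1L)
    }
    Spool <- Spool / (nlevels(d$s) - nlevels(grp))
    C <- stats::contr.helmert(k)
    C <- qr.Q(qr(C))                      # orthonormal contrasts
    M <- t(C) %*% Spool %*% C
    eps <- sum(diag(M))^2 / ((k - 1) * sum(M * M))
    eps <- min(1, max(1 / (k - 1), eps))

    mk <- function(name, eff, err, useEps) {
        Fv <- (eff["ss"] / eff["df"]) / (err["ss"] / err["df"])
        p <- stats::pf(Fv, eff["df"], err["df"], lower.tail = FALSE)
        pG <- if (useEps)
            stats::pf(Fv, eps * eff["df"], eps * err["df"],
                      lower.tail = FALSE) else p
        data.frame(effect = name, F = unname(Fv),
                   dfNum = unname(eff["df"]), dfDen = unname(err["df"]),
                   p = unname(p),
                   ggEpsilon = if (useEps) eps else NA_real_,
                   pGG = unname(pG),
                   partialEtaSq = unname(eff["ss"] /
                                             (eff["ss"] + err["ss"])))
    }
    out <- rbind(mk("between", eB, rB, FALSE),
                 mk("within", eW, rW, TRUE),
                 mk("between:within", eI, rW, TRUE))
    rownames(out) <- NULL
    out
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' All pairwise comparisons between the columns of a subjects x levels
#' score matrix (paired t-tests) or between the elements of a list of
#' group vectors (independent t-tests). Adjusted p-values are
#' \code{min(1, m * p)} with \code{m} the number of pairs in the family.
#'
#' @param values subjects x levels matrix, or list of numeric vectors.
#' @param paired TRUE for within-subject comparisons (matrix input).
#' @return data.frame with columns \code{level1}, \code{level2}, \code{t},
#'   \code{df}, \code{p}, \code{pAdjusted}, \code{m}.
#' @export
bonferroniPosthoc <- function(values, paired = is.matrix(values)) {
    if (is.matrix(values)) {
        labs <- colnames(values)
        if (is.null(labs)) labs <- paste0("level", seq_len(ncol(values)))
        cols <- lapply(seq_len(ncol(values)), function(j) values[, j])
        names(cols) <- labs
    } else cols <- values
    kk <- length(cols)
    if (kk < 2L) stop("need at least 2 cells to compare")
    pairs <- utils::combn(kk, 2L)
    m <- ncol(pairs)
    rows <- lapply(seq_len(m), function(i) {
        a <- cols[[pairs[1L, i]]]
        b <- cols[[pairs[2L, i]]]
        tt <- stats::t.test(a, b, paired = paired)
        data.frame(level1 = names(cols)[pairs[1L, i]],
                   level2 = names(cols)[pairs[2L, i]],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, pAdjusted = min(1, m * tt$p.value),
                   m = m)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' BIC-approximated inclusion Bayes factors for a two-factor mixed design
#'
#' Enumerates the candidate fixed-effect structures respecting marginality
#' (null, between, within, both mains, both mains + interaction), each
#' with a subject random intercept, fits them by maximum likelihood with
#' \code{lme4}, and approximates each model's marginal likelihood by
#' \code{exp(-BIC / 2)}. The inclusion Bayes factor of an effect compares
#' matched models: models containing the effect (but no higher-order
#' interaction involving it) against the same models with the effect
#' removed, under equal prior model probabilities. This is a documented
#' approximation to the default-prior ANOVA Bayes factor, not a
#' reimplementation of it; values track the direction and order of
#' magnitude of the matched-prior quantity.
#'
#' @inheritParams mixedAnova
#' @return data.frame with columns \code{effect} and \code{bfIncl}
#'   (NA when every fit for an effect is singular).
#' @export
bfInclusion <- function(data, dv = "amplitude", within = "electrode",
                        between = "group", subject = "subject") {
    d <- data.frame(y = data[[dv]], w = factor(data[[within]]),
                    b = factor(data[[between]]),
                    s = factor(data[[subject]]))
    forms <- list(null = y ~ 1 + (1 | s),
                  b = y ~ b + (1 | s),
                  w = y ~ w + (1 | s),
                  bw = y ~ b + w + (1 | s),
                  full = y ~ b * w + (1 | s))
    bic <- vapply(forms, function(f) {
        fit <- tryCatch(
            suppressWarnings(suppressMessages(
                lme4::lmer(f, data = d, REML = FALSE))),
            error = function(e) NULL)
        if (is.null(fit)) NA_real_ else stats::BIC(fit)
    }, numeric(1))
    if (anyNA(bic))
        return(data.frame(effect = c("between", "within",
                                     "between:within"),
                          bfIncl = NA_real_))
    w <- exp(-(bic - min(bic)) / 2)
    w <- w / sum(w)
    ratio <- function(withEff, without)
        sum(w[withEff]) / sum(w[without])
    data.frame(
        effect = c("between", "within", "between:within"),
        bfIncl = c(ratio(c("b", "bw"), c("null", "w")),
                   ratio(c("w", "bw"), c("null", "b")),
                   ratio("full", "bw")))
}
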