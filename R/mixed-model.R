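arm_for_factor <- function(factor) {
  switch(factor, art = "art", focus = "focus", position = "position",
         stop("`factor` must be one of 'art', 'focus', 'position'"))
}

factor_column <- function(t, factor) {
  switch(factor,
         art = factor(t$art, levels = sort(unique(t$art))),
         focus = factor(t$focus, levels = sort(unique(t$focus))),
         position = factor(t$position,
                           levels = intersect(c("middle", "bottom"),
                                              unique(t$position))))
}

#' Fit the setting-effect linear mixed model
#'
#' Fits the mean model for one acquisition factor: response (VRI by
#' default, or the vitreous / RPE mean intensity), the factor as a
#' categorical fixed effect, and random intercepts for subject and for
#' raster scan nested in subject (sections are the observations). The
#' reported estimates come from the REML fit; the overall factor p-value
#' is a likelihood-ratio test against the no-factor model, both refit by
#' maximum likelihood.
#'
#' The table is subset internally to the factor's arm (in-focus middle
#' scans for `art`, ART-100 middle scans for `focus`, ART-100 in-focus
#' scans for `position`).
#'
#' If the mixed fit is degenerate (e.g. zero residual variance in
#' synthetic data) the routine falls back to an ordinary least-squares
#' fit with zero random-effect variances and flags non-convergence.
#'
#' @param table A study table.
#' @param factor `"art"`, `"focus"` or `"position"`.
#' @param response Response column: `"vri"` (default), `"vitreous_mean"`
#'   or `"rpe_mean"`.
#' @return An object of class `mean_effect_fit`: `estimates` (data.frame
#'   `level`, `estimate`, `se`), `p_overall`, `varcorr` (subject, scan and
#'   residual variances), `converged`, `method`, plus the underlying
#'   `fit` and model `data`.
#' @export
fit_mean_model <- function(table, factor = c("art", "focus", "position"),
                           response = "vri") {
  factor <- match.arg(factor)
  stopifnot(response %in% names(table))
  t <- protocol_arm(table, arm_for_factor(factor))
  t <- t[!t$failed & !is.na(t[[response]]), , drop = FALSE]
  t$fac <- factor_column(t, factor)
  t$y <- t[[response]]
  t$subject_f <- factor(t$subject)
  t$scan_f <- factor(scan_id(t))
  if (nlevels(t$fac) < 2L) stop("need >= 2 factor levels in the data")
  if (nlevels(t$subject_f) < 2L) stop("need >= 2 subjects")

  warnings_seen <- character(0)
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(y ~ 0 + fac + (1 | subject_f) + (1 | scan_f),
                 data = t, REML = TRUE),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)

  if (inherits(fit, "error")) {
    # degenerate data (e.g. zero residual variance): plain least squares
    fit <- stats::lm(y ~ 0 + fac, data = t)
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    se[!is.finite(se)] <- 0
    varcorr <- c(subject = 0, scan = 0, residual = 0)
    method <- "lm_fallback"
    converged <- FALSE
    a <- tryCatch(anova(stats::lm(y ~ 1, data = t),
                        stats::lm(y ~ fac, data = t)),
                  error = function(e) NULL)
    p <- if (!is.null(a)) a$`Pr(>F)`[2] else NA_real_
    if (is.na(p) || is.nan(p)) p <- 0  # perfect separation of level means
  } else {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcorr <- c(
      subject = vc$vcov[vc$grp == "subject_f"],
      scan = vc$vcov[vc$grp == "scan_f"],
      residual = vc$vcov[vc$grp == "Residual"])
    method <- "lmer_reml"
    converged <- length(warnings_seen) == 0L
    full_ml <- tryCatch(
      suppressMessages(suppressWarnings(lme4::lmer(
        y ~ fac + (1 | subject_f) + (1 | scan_f), data = t,
        REML = FALSE))),
      error = function(e) NULL)
    null_ml <- tryCatch(
      suppressMessages(suppressWarnings(lme4::lmer(
        y ~ 1 + (1 | subject_f) + (1 | scan_f), data = t,
        REML = FALSE))),
      error = function(e) NULL)
    p <- if (!is.null(full_ml) && !is.null(null_ml)) {
      stat <- 2 * (as.numeric(logLik(full_ml)) - as.numeric(logLik(null_ml)))
      pchisq(max(stat, 0), df = nlevels(t$fac) - 1L, lower.tail = FALSE)
    } else NA_real_
  }

  structure(list(
    factor = factor, response = response,
    estimates = data.frame(level = levels(t$fac),
                           estimate = unname(est), se = unname(se),
                           stringsAsFactors = FALSE),
    p_overall = p, varcorr = varcorr, converged = converged,
    method = method, warnings = warnings_seen, fit = fit, data = t
  ), class = "mean_effect_fit")
}

#' @export
print.mean_effect_fit <- function(x, ...) {
  cat(sprintf("<mean_effect_fit> %s ~ %s  (%s%s)\n", x$response, x$factor,
              x$method, if (x$converged) "" else ", non-converged"))
  print(x$estimates, row.names = FALSE)
  cat(sprintf("overall p-value (LRT): %.4g\n", x$p_overall))
  invisible(x)
}

#' Tukey-adjusted pairwise contrasts
#'
#' All pairwise contrasts between factor levels of a fitted mean model or
#' variability model, with family-wise adjusted p-values (Tukey /
#' multivariate-t family over the complete pairwise contrast set). With
#' only two levels the adjusted p-value equals the unadjusted one.
#'
#' @param fit A `mean_effect_fit` or `variability_fit`.
#' @param ... Unused.
#' @return data.frame with `contrast`, `estimate`, `se`, `p_adj`. For
#'   variability fits the estimate is on the log squared-residual scale
#'   (a log variance ratio).
#' @export
pairwise_compare <- function(fit, ...) UseMethod("pairwise_compare")

emmeans_pairs <- function(model, data) {
  emm <- emmeans::emmeans(model, specs = "fac", data = data)
  prs <- summary(emmeans::contrast(emm, method = "pairwise"),
                 adjust = "tukey")
  data.frame(contrast = as.character(prs$contrast),
             estimate = prs$estimate, se = prs$SE,
             p_adj = prs$p.value, stringsAsFactors = FALSE)
}

#' @export
pairwise_compare.mean_effect_fit <- function(fit, ...) {
  emmeans_pairs(fit$fit, fit$data)
}

#' @export
pairwise_compare.variability_fit <- function(fit, ...) {
  emmeans_pairs(fit$fit, fit$data)
}
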