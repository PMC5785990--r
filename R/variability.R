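#' Model variability with a Gamma GLM on squared residuals
#'
#' Under approximate normality of the residuals, squared residuals follow
#' a scaled chi-squared -- a Gamma -- distribution, so the effect of the
#' acquisition setting on the measurement variability is modelled with a
#' Gamma generalized linear model with a logarithmic link on the squared
#' residuals of a [compute_level_residuals()] table. The variability of
#' each factor level is reported as the square root of the fitted mean
#' squared residual; with a single categorical predictor this equals the
#' per-group root-mean-square residual. The overall factor p-value is a
#' likelihood-ratio test against the intercept-only model; the dispersion
#' is estimated by the Pearson method (it does not affect the fitted
#' means).
#'
#' Exact zero squared residuals are undefined under the Gamma likelihood
#' and are dropped with a logged count (they arise only in degenerate,
#' typically synthetic, data). A factor level whose squared residuals are
#' all zero is excluded with a warning.
#'
#' @param resid A `residual_table` from [compute_level_residuals()].
#' @param factor `"art"`, `"focus"` or `"position"`; the table is subset
#'   to that arm.
#' @return An object of class `variability_fit`: `estimates` (data.frame
#'   `level`, `variability`, `fitted_mean_sq`, `n`), `p_overall`,
#'   `n_zero_dropped`, `level` (residual level), plus the underlying
#'   `fit` and `data`.
#' @export
fit_variability <- function(resid, factor = c("art", "focus", "position")) {
  factor <- match.arg(factor)
  stopifnot(inherits(resid, "residual_table"))
  res_level <- attr(resid, "level")
  t <- protocol_arm(as.data.frame(resid), arm_for_factor(factor))
  if (!nrow(t)) stop("no residuals in the requested arm")
  t$fac <- factor_column(t, factor)

  zero <- t$squared_residual == 0
  n_zero <- sum(zero)
  all_levels <- levels(t$fac)
  t <- t[!zero, , drop = FALSE]
  dead <- setdiff(all_levels, unique(as.character(t$fac)))
  if (length(dead)) {
    warning("factor level(s) with all-zero squared residuals excluded: ",
            paste(dead, collapse = ", "))
    t$fac <- droplevels(t$fac)
  }
  if (nlevels(t$fac) < 1L) {
    # fully degenerate input: no dispersion at all at this level
    return(structure(list(
      factor = factor, level = res_level,
      estimates = data.frame(level = all_levels, variability = 0,
                             fitted_mean_sq = 0, n = 0L,
                             stringsAsFactors = FALSE),
      p_overall = NA_real_, n_zero_dropped = n_zero, fit = NULL,
      data = t), class = "variability_fit"))
  }

  form <- if (nlevels(t$fac) >= 2L) squared_residual ~ 0 + fac
  else squared_residual ~ 1
  fit <- glm(form, data = t, family = Gamma(link = "log"),
             control = glm.control(epsilon = 1e-12, maxit = 200))
  mu <- setNames(exp(coef(fit)), paste0("fac", levels(t$fac)))
  n_per <- table(t$fac)

  p <- if (nlevels(t$fac) >= 2L) {
    fit0 <- glm(squared_residual ~ 1, data = t,
                family = Gamma(link = "log"),
                control = glm.control(epsilon = 1e-12, maxit = 200))
    a <- anova(fit0, fit, test = "LRT")
    a$`Pr(>Chi)`[2]
  } else NA_real_

  structure(list(
    factor = factor, level = res_level,
    estimates = data.frame(level = levels(t$fac),
                           variability = unname(sqrt(mu)),
                           fitted_mean_sq = unname(mu),
                           n = as.integer(n_per),
                           stringsAsFactors = FALSE),
    p_overall = p, n_zero_dropped = n_zero, fit = fit, data = t
  ), class = "variability_fit")
}

#' @export
print.variability_fit <- function(x, ...) {
  cat(sprintf("<variability_fit> %s variability ~ %s\n",
              gsub("_", "-", x$level), x$factor))
  print(x$estimates[, c("level", "variability", "n")], row.names = FALSE)
  cat(sprintf("overall p-value (LRT): %.4g", x$p_overall))
  if (x$n_zero_dropped > 0)
    cat(sprintf("  [%d zero squared residuals dropped]", x$n_zero_dropped))
  cat("\n")
  invisible(x)
}

#' Full variability table for one factor
#'
#' Convenience wrapper running [compute_level_residuals()] and
#' [fit_variability()] at all three levels for one acquisition factor.
#'
#' @param table A study table (exclusions applied).
#' @param factor `"art"`, `"focus"` or `"position"`.
#' @return data.frame with one row per factor level x residual level:
#'   `factor`, `level`, `residual_level`, `variability`, `n`, `p_overall`.
#' @export
variability_table <- function(table, factor = c("art", "focus", "position")) {
  factor <- match.arg(factor)
  lv <- c("within_scan", "intra_subject", "inter_subject")
  out <- lapply(lv, function(l) {
    vf <- fit_variability(compute_level_residuals(table, l), factor)
    data.frame(factor = factor, level = vf$estimates$level,
               residual_level = l,
               variability = vf$estimates$variability,
               n = vf$estimates$n, p_overall = vf$p_overall,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Five-number box-plot summary
#'
#' Quartiles by linear interpolation (type-7, the common default);
#' whiskers extend to the most extreme data points within 1.5 times the
#' interquartile range from the box limits; points beyond the whiskers
#' are flagged as outliers.
#'
#' @param values Numeric vector, at least one finite value.
#' @param qtype Quantile type passed to [stats::quantile()] (default 7).
#' @return List with `n`, `q1`, `median`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
boxplot_stats <- function(values, qtype = 7) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values supplied")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = qtype))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(n = length(values), q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}
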