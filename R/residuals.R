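#' Residual decomposition at the three nesting levels
#'
#' Computes the residuals that carry the variability information at each
#' level of the nested design:
#' \describe{
#'   \item{`within_scan`}{each measurement minus the mean of the measured
#'     sections of its raster scan (one residual per section).}
#'   \item{`intra_subject`}{each raster-scan mean minus the mean of the
#'     repeated acquisitions in its subject x setting cell (one residual
#'     per scan).}
#'   \item{`inter_subject`}{each subject's mean of acquisitions minus the
#'     across-subject mean, within setting (one residual per subject x
#'     setting).}
#' }
#' All means are means over available (post-exclusion) members;
#' higher-level means are hierarchical (means of scan means, not of raw
#' sections), so unbalanced scans are not over-weighted. Groups with a
#' single member contribute a zero residual and are flagged.
#'
#' @param table A study table, exclusions already applied.
#' @param level One of `"within_scan"`, `"intra_subject"`,
#'   `"inter_subject"`.
#' @return A `residual_table`: data.frame with the grouping keys, the arm
#'   factor columns (`position`, `art`, `focus`, `setting`), `residual`,
#'   `squared_residual`, `n_group` and `flagged`; attribute `level`.
#' @export
compute_level_residuals <- function(table,
                                    level = c("within_scan",
                                              "intra_subject",
                                              "inter_subject")) {
  level <- match.arg(level)
  t <- table[!table$failed & !is.na(table$vri), , drop = FALSE]
  if (!nrow(t)) stop("no measured rows in table")

  # scan means first: every higher level is built from them
  sid <- scan_id(t)
  scan_mean <- tapply(t$vri, sid, mean)
  scan_n <- tapply(t$vri, sid, length)

  if (level == "within_scan") {
    res <- t$vri - scan_mean[sid]
    out <- data.frame(subject = t$subject, position = t$position,
                      art = t$art, focus = t$focus, setting = t$setting,
                      repetition = t$repetition, section = t$section,
                      residual = unname(res),
                      n_group = unname(scan_n[sid]),
                      stringsAsFactors = FALSE)
  } else {
    scans <- t[!duplicated(sid), c("subject", "position", "art", "focus",
                                   "setting", "repetition")]
    scans$scan_mean <- unname(scan_mean[sid[!duplicated(sid)]])
    cid <- cell_id(scans)
    cell_mean <- tapply(scans$scan_mean, cid, mean)
    cell_n <- tapply(scans$scan_mean, cid, length)
    if (level == "intra_subject") {
      out <- scans
      out$residual <- scans$scan_mean - unname(cell_mean[cid])
      out$n_group <- unname(cell_n[cid])
      out$scan_mean <- NULL
    } else {
      cells <- scans[!duplicated(cid), c("subject", "position", "art",
                                         "focus", "setting")]
      cells$cell_mean <- unname(cell_mean[cid[!duplicated(cid)]])
      set_mean <- tapply(cells$cell_mean, cells$setting, mean)
      set_n <- tapply(cells$cell_mean, cells$setting, length)
      out <- cells
      out$residual <- cells$cell_mean - unname(set_mean[cells$setting])
      out$n_group <- unname(set_n[cells$setting])
      out$cell_mean <- NULL
    }
  }
  out$squared_residual <- out$residual^2
  out$flagged <- out$n_group == 1L
  rownames(out) <- NULL
  structure(out, level = level,
            class = c("residual_table", "data.frame"))
}

#' Recover the generating variance components from a study table
#'
#' Bias-corrected method-of-moments estimates of the three nested standard
#' deviations from the three residual levels. Within each level the raw
#' mean squared residual is corrected for mean-centering shrinkage
#' (a group of n members yields n - 1 degrees of freedom) and, at the scan
#' and subject levels, for the variance leaked upward from the levels
#' below (a scan mean of n sections carries sigma_section^2 / n, etc.).
#' Negative corrected variances are truncated at zero.
#'
#' @param table A study table (exclusions applied for unbalanced data).
#' @return A [variance_components()] vector
#'   (`sigma_subject`, `sigma_scan`, `sigma_section`).
#' @export
recover_variance_components <- function(table) {
  r1 <- compute_level_residuals(table, "within_scan")
  r2 <- compute_level_residuals(table, "intra_subject")
  r3 <- compute_level_residuals(table, "inter_subject")

  # section level: sum of squares per scan has expectation (n-1) sigma_e^2
  scans1 <- !duplicated(sprintf("sub%02d|%s|rep%d", r1$subject, r1$setting,
                                r1$repetition))
  df1 <- sum(r1$n_group[scans1] - 1L)
  if (df1 <= 0) stop("no within-scan degrees of freedom")
  sig_e2 <- sum(r1$squared_residual) / df1
  mean_inv_nsec <- mean(1 / r1$n_group[scans1])

  df2 <- sum(r2$n_group[!duplicated(cell_id(r2))] - 1L)
  sig_c2 <- if (df2 > 0)
    max(sum(r2$squared_residual) / df2 - sig_e2 * mean_inv_nsec, 0)
  else NA_real_
  mean_inv_nrep <- mean(1 / r2$n_group[!duplicated(cell_id(r2))])

  df3 <- sum(r3$n_group[!duplicated(r3$setting)] - 1L)
  sig_b2 <- if (df3 > 0)
    max(sum(r3$squared_residual) / df3 - sig_c2 * mean_inv_nrep -
          sig_e2 * mean_inv_nrep * mean_inv_nsec, 0)
  else NA_real_

  variance_components(sigma_subject = sqrt(sig_b2),
                      sigma_scan = sqrt(sig_c2),
                      sigma_section = sqrt(sig_e2))
}
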