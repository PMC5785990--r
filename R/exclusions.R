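scan_id <- function(t)
  sprintf("sub%02d|%s|rep%d", t$subject, t$setting, t$repetition)

cell_id <- function(t) sprintf("sub%02d|%s", t$subject, t$setting)

#' Apply the measurement-failure exclusion rules
#'
#' Raster scans from which fewer than 3 of the 7 sections could be
#' measured are discarded entirely; subject x setting cells left with
#' fewer than 2 measured repetitions are then discarded entirely. The
#' returned table contains only the surviving measured rows; an exclusion
#' log is attached as attribute `"exclusion_log"`.
#'
#' The operation is idempotent: re-applying it to its own output changes
#' nothing.
#'
#' @param table A study table (columns `subject`, `setting`, `repetition`,
#'   `section`, `vri`, `failed`).
#' @param min_sections Minimum measured sections per raster scan (default 3).
#' @param min_repetitions Minimum surviving repetitions per subject x
#'   setting cell (default 2).
#' @return The filtered study table with attribute `exclusion_log`
#'   (data.frame of `unit`, `id`, `reason`).
#' @export
apply_exclusions <- function(table, min_sections = 3L,
                             min_repetitions = 2L) {
  stopifnot(is.data.frame(table),
            all(c("subject", "setting", "repetition", "vri", "failed") %in%
                  names(table)))
  measured <- !table$failed & !is.na(table$vri)
  t <- table[measured, , drop = FALSE]
  log <- data.frame(unit = character(0), id = character(0),
                    reason = character(0), stringsAsFactors = FALSE)

  sid <- scan_id(t)
  n_sec <- table(sid)
  bad_scans <- names(n_sec)[n_sec < min_sections]
  # scans that failed entirely never appear in t; count them too
  all_sid <- unique(scan_id(table))
  bad_scans <- union(bad_scans, setdiff(all_sid, unique(sid)))
  if (length(bad_scans)) {
    log <- rbind(log, data.frame(
      unit = "raster_scan", id = sort(bad_scans),
      reason = sprintf("fewer than %d measured sections", min_sections),
      stringsAsFactors = FALSE))
    t <- t[!sid %in% bad_scans, , drop = FALSE]
    sid <- scan_id(t)
  }

  cid <- cell_id(t)
  reps_per_cell <- tapply(t$repetition, cid,
                          function(r) length(unique(r)))
  bad_cells <- names(reps_per_cell)[reps_per_cell < min_repetitions]
  all_cid <- unique(cell_id(table))
  bad_cells <- union(bad_cells, setdiff(all_cid, unique(cid)))
  if (length(bad_cells)) {
    log <- rbind(log, data.frame(
      unit = "subject_setting_cell", id = sort(bad_cells),
      reason = sprintf("fewer than %d surviving repetitions",
                       min_repetitions),
      stringsAsFactors = FALSE))
    t <- t[!cid %in% bad_cells, , drop = FALSE]
  }

  rownames(t) <- NULL
  attr(t, "exclusion_log") <- log
  t
}

#' Failure counts and rates per study arm
#'
#' Compares the theoretical slots of each arm (ART, focus, position)
#' against the measured table: a slot counts as failed when its row is
#' flagged failed or is absent from the table. Percentages are rounded to
#' the nearest integer percent.
#'
#' @param slots Protocol slots from [enumerate_protocol()].
#' @param table A study table whose keys are a subset of `slots`.
#' @return data.frame with `arm`, `theoretical`, `failed`, `pct`.
#' @examples
#' slots <- enumerate_protocol(15, 3, 7)
#' study <- generate_study(slots, seed = 1)
#' failure_summary(slots, study)
#' @export
failure_summary <- function(slots, table) {
  key <- function(t) sprintf("%s|sec%d", scan_id(t), t$section)
  ok_keys <- key(table[!table$failed & !is.na(table$vri), , drop = FALSE])
  out <- lapply(c("art", "focus", "position"), function(a) {
    arm_slots <- protocol_arm(slots, a)
    n <- nrow(arm_slots)
    failed <- sum(!key(arm_slots) %in% ok_keys)
    data.frame(arm = a, theoretical = n, failed = failed,
               pct = round(100 * failed / n), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
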