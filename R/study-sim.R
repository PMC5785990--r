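#' Variance components of the nested design
#'
#' Standard deviations (VRI units) of the three nested random levels the
#' simulator draws from and the analysis estimates: between subjects,
#' between raster scans within a subject x setting cell, and between
#' sections within a raster scan. Defaults are realistic magnitudes for an
#' in-focus macular protocol in healthy eyes.
#'
#' @param sigma_subject,sigma_scan,sigma_section Non-negative standard
#'   deviations.
#' @return An object of class `variance_components` (named numeric).
#' @export
variance_components <- function(sigma_subject = 0.012, sigma_scan = 0.007,
                                sigma_section = 0.010) {
  vc <- c(sigma_subject = sigma_subject, sigma_scan = sigma_scan,
          sigma_section = sigma_section)
  if (any(!is.finite(vc)) || any(vc < 0))
    stop("variance components must be finite and >= 0")
  structure(vc, class = c("variance_components", "numeric"))
}

#' Enumerate the scan slots of a study design
#'
#' Full factorial of subjects x the ten canonical settings x repetitions x
#' sections. Each row ("slot") is one theoretical section measurement,
#' uniquely keyed by (subject, setting, repetition, section). Use
#' [protocol_arm()] to select the ART, focus or position arm.
#'
#' @param n_subjects,repetitions,sections Counts, all >= 1. The canonical
#'   study uses 15 subjects, 3 repetitions and 7 sections per raster scan
#'   (30 raster scans per subject).
#' @return A data.frame with columns `subject`, `position`, `art`,
#'   `focus`, `setting`, `repetition`, `section`, `slot`.
#' @examples
#' d <- enumerate_protocol(15, 3, 7)
#' nrow(protocol_arm(d, "art"))   # 1575 theoretical section measurements
#' @export
enumerate_protocol <- function(n_subjects = 15L, repetitions = 3L,
                               sections = 7L) {
  if (any(c(n_subjects, repetitions, sections) < 1))
    stop("all design counts must be >= 1")
  proto <- canonical_protocol()
  d <- expand.grid(section = seq_len(sections),
                   repetition = seq_len(repetitions),
                   row = seq_len(nrow(proto)),
                   subject = seq_len(n_subjects),
                   KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(subject = d$subject,
                    position = proto$position[d$row],
                    art = proto$art[d$row],
                    focus = proto$focus[d$row],
                    setting = proto$setting[d$row],
                    repetition = d$repetition,
                    section = d$section,
                    stringsAsFactors = FALSE)
  out$slot <- sprintf("sub%02d|%s|rep%d|sec%d", out$subject, out$setting,
                      out$repetition, out$section)
  out
}

# Deterministic per-key seed stream: a stable string hash folded into the
# root seed, so subsetting a design never changes another slot's draws.
hash_key <- function(key) {
  vapply(key, function(k) {
    h <- 0
    for (code in utf8ToInt(k)) h <- (h * 31 + code) %% 2147480009
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# the root seed is folded into the hashed string (not added to the hash)
# so nearby keys and nearby root seeds both map to unrelated streams
keyed_seed <- function(root_seed, keys)
  hash_key(sprintf("%s#%d", keys, as.integer(root_seed)))

keyed_normal <- function(root_seed, keys, sd) {
  if (sd == 0) return(numeric(length(keys)))
  vapply(keyed_seed(root_seed, keys),
         function(s) { set.seed(as.integer(s)); rnorm(1, 0, sd) },
         numeric(1))
}

keyed_uniform <- function(root_seed, keys) {
  vapply(keyed_seed(root_seed, keys),
         function(s) { set.seed(as.integer(s)); runif(1) },
         numeric(1))
}

#' Reference mean VRI per canonical setting
#'
#' Published reference estimates of the global mean VRI under each of the
#' ten canonical acquisition settings in healthy eyes: about 0.039-0.048
#' for the in-focus ART series, strongly elevated for defocused
#' acquisitions (up to 0.200 at +10 D) and for bottom positioning. These
#' are the simulator's default setting means, so a default simulated study
#' reproduces the reported ordering of setting effects.
#'
#' @return Named numeric vector keyed by setting label.
#' @export
reference_setting_means <- function() {
  c("middle_art100_f0"   = 0.048,
    "middle_art50_f0"    = 0.039,
    "middle_art25_f0"    = 0.043,
    "middle_art12_f0"    = 0.043,
    "middle_art6_f0"     = 0.043,
    "middle_art100_f+5"  = 0.192,
    "middle_art100_f+10" = 0.200,
    "middle_art100_f-5"  = 0.088,
    "middle_art100_f-10" = 0.162,
    "bottom_art100_f0"   = 0.162)
}

#' Reference mean VRI by focus offset
#'
#' The focus-arm slice of [reference_setting_means()] as a data.frame,
#' convenient for level-vs-reference difference reporting.
#'
#' @return data.frame with columns `focus` (dioptres) and `mean_vri`.
#' @export
reference_focus_means <- function() {
  m <- reference_setting_means()
  data.frame(focus = c(-10, -5, 0, 5, 10),
             mean_vri = unname(m[c("middle_art100_f-10", "middle_art100_f-5",
                                   "middle_art100_f0", "middle_art100_f+5",
                                   "middle_art100_f+10")]))
}

#' Default per-setting VITAN failure probabilities
#'
#' Defaults calibrated so a full simulated study reproduces the reported
#' arm-level failure rates: ~3% over the in-focus ART arm and ~32% over
#' the focus arm, with failures concentrated at large focus offsets
#' (defocused scans are hard to acquire and to segment).
#'
#' @return Named numeric vector of probabilities keyed by setting label.
#' @export
default_failure_probs <- function() {
  c("middle_art100_f0"   = 0.03,
    "middle_art50_f0"    = 0.03,
    "middle_art25_f0"    = 0.03,
    "middle_art12_f0"    = 0.03,
    "middle_art6_f0"     = 0.03,
    "middle_art100_f+5"  = 0.35,
    "middle_art100_f+10" = 0.45,
    "middle_art100_f-5"  = 0.35,
    "middle_art100_f-10" = 0.45,
    "bottom_art100_f0"   = 0.05)
}

#' Simulate VRI values for a study design
#'
#' Draws the VRI of slot (subject i, repetition j, section k) under setting
#' s as `mu[s] + b_i + c_ijs + e_ijks`, with independent normal random
#' effects: `b_i ~ N(0, sigma_subject^2)` per subject, `c ~ N(0,
#' sigma_scan^2)` per raster scan (one per subject x setting x repetition
#' acquisition) and `e ~ N(0, sigma_section^2)` per section. Draws come
#' from per-key seeded streams derived from `seed`, so the table is
#' bit-reproducible and independent of design subsetting.
#'
#' @param design Protocol slots from [enumerate_protocol()] (or any subset).
#' @param mu_by_setting Named numeric vector mapping setting label to mean
#'   VRI; every setting present in `design` must have an entry.
#' @param vc A [variance_components()].
#' @param seed Integer root seed.
#' @param rpe_mean Nominal RPE intensity used to back-fill the
#'   `vitreous_mean` / `rpe_mean` columns consistently with the simulated
#'   ratio.
#' @return A study table: the design columns plus `vri`, `vitreous_mean`,
#'   `rpe_mean`, `failed` (all `FALSE`).
#' @export
generate_study <- function(design, mu_by_setting = reference_setting_means(),
                           vc = variance_components(), seed = 1L,
                           rpe_mean = 0.85) {
  stopifnot(is.data.frame(design),
            all(c("subject", "setting", "repetition", "section") %in%
                  names(design)))
  missing_mu <- setdiff(unique(design$setting), names(mu_by_setting))
  if (length(missing_mu))
    stop("no mean VRI supplied for setting(s): ",
         paste(missing_mu, collapse = ", "))

  sub_key  <- sprintf("sub%02d", design$subject)
  scan_key <- sprintf("sub%02d|%s|rep%d", design$subject, design$setting,
                      design$repetition)
  sec_key  <- sprintf("%s|sec%d", scan_key, design$section)

  b <- keyed_normal(seed, unique(sub_key), vc["sigma_subject"])
  names(b) <- unique(sub_key)
  cc <- keyed_normal(seed, unique(scan_key), vc["sigma_scan"])
  names(cc) <- unique(scan_key)
  e <- keyed_normal(seed, sec_key, vc["sigma_section"])

  out <- design
  out$vri <- unname(mu_by_setting[design$setting] + b[sub_key] +
                      cc[scan_key] + e)
  out$rpe_mean <- rpe_mean
  out$vitreous_mean <- out$vri * rpe_mean
  out$failed <- FALSE
  out
}

#' Mark slots as failed measurements
#'
#' Independently marks each slot failed with its setting's probability
#' (seeded, via per-slot streams). Failed rows lose their measurement
#' columns (`vri`, `vitreous_mean`, `rpe_mean` become `NA`), emulating an
#' automated measurement that could not be obtained.
#'
#' @param table A study table.
#' @param prob_by_setting Named probability vector keyed by setting label;
#'   settings without an entry get probability 0.
#' @param seed Integer root seed (independent of the value-generating
#'   stream).
#' @return The table with `failed` updated and failed measurements blanked.
#' @export
inject_failures <- function(table, prob_by_setting = default_failure_probs(),
                            seed = 1L) {
  stopifnot(is.data.frame(table), "setting" %in% names(table))
  if (any(prob_by_setting < 0 | prob_by_setting > 1))
    stop("failure probabilities must be in [0, 1]")
  p <- prob_by_setting[table$setting]
  p[is.na(p)] <- 0
  if (all(p == 0)) return(table)
  key <- sprintf("fail|%s", if ("slot" %in% names(table)) table$slot else
    sprintf("sub%02d|%s|rep%d|sec%d", table$subject, table$setting,
            table$repetition, table$section))
  u <- keyed_uniform(seed, key)
  fail <- u < p
  table$failed <- table$failed | fail
  for (col in intersect(c("vri", "vitreous_mean", "rpe_mean"), names(table)))
    table[[col]][table$failed] <- NA_real_
  table
}
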