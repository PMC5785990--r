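#' Compute the vitreous/RPE-relative intensity (VRI)
#'
#' The VRI is the mean intensity of the vitreous patch divided by the mean
#' intensity of the segmented RPE. Because the RPE mean acts as a
#' normalisation term, the ratio is invariant to a global rescaling of the
#' image intensities (e.g. overall signal loss from media opacities).
#'
#' @param image A `bscan` or pixel matrix.
#' @param rpe_mask,patch_mask Logical matrices from [locate_rpe()] and
#'   [build_vitreous_patch()].
#' @param meta Optional slot metadata carried onto the measurement.
#' @return An object of class `vri_measurement`: `vitreous_mean`,
#'   `rpe_mean`, `vri`, `status` (`"ok"` / `"failed"`), `reason`, `meta`.
#' @export
compute_vri <- function(image, rpe_mask, patch_mask, meta = NULL) {
  px <- as_pixels(image)
  if (!any(patch_mask)) return(vri_failure("empty vitreous patch", meta))
  if (!any(rpe_mask)) return(vri_failure("empty RPE mask", meta))
  vit <- mean(px[patch_mask])
  rpe <- mean(px[rpe_mask])
  if (rpe == 0) return(vri_failure("zero RPE signal", meta))
  structure(list(vitreous_mean = vit, rpe_mean = rpe, vri = vit / rpe,
                 status = "ok", reason = NA_character_, meta = meta),
            class = "vri_measurement")
}

vri_failure <- function(reason, meta = NULL) {
  structure(list(vitreous_mean = NA_real_, rpe_mean = NA_real_,
                 vri = NA_real_, status = "failed", reason = reason,
                 meta = meta),
            class = "vri_measurement")
}

#' @export
print.vri_measurement <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<vri_measurement> VRI %.4f (vitreous %.4f / RPE %.4f)\n",
                x$vri, x$vitreous_mean, x$rpe_mean))
  else
    cat(sprintf("<vri_measurement> failed: %s\n", x$reason))
  invisible(x)
}

#' Measure the VRI of one B-scan
#'
#' Full measurement composition: segment the retina/RPE complex, extract
#' the RPE band, build the vitreous patch, and compute the VRI. Any stage
#' failure (insufficient tissue coverage, empty RPE, undersized patch,
#' zero RPE signal) yields a failed measurement carrying that stage's
#' reason; the function never raises on a valid image.
#'
#' @param image A `bscan` or numeric pixel matrix in \[0, 1\].
#' @param cfg A [seg_config()].
#' @param keep_masks Keep the segmentation masks on the result (for
#'   overlays and tests)?
#' @return A `vri_measurement`; with `keep_masks = TRUE` it also carries
#'   `segmentation`, `rpe_mask` and `patch_mask`.
#' @examples
#' b <- make_phantom(phantom_geometry(), phantom_optics(),
#'                   acquisition_setting("middle", 100, 0), seed = 1)
#' analyse_bscan(b)
#' @export
analyse_bscan <- function(image, cfg = seg_config(), keep_masks = FALSE) {
  meta <- if (inherits(image, "bscan")) image$meta else NULL
  px <- as_pixels(image)
  seg <- segment_retina(px, cfg)
  if (!seg$success) return(vri_failure(seg$failure_reason, meta))
  rpe <- locate_rpe(seg, cfg)
  if (!any(rpe)) return(vri_failure("empty RPE mask", meta))
  patch <- build_vitreous_patch(px, seg, cfg)
  if (!patch$success) return(vri_failure(patch$failure_reason, meta))
  res <- compute_vri(px, rpe, patch$mask, meta)
  if (keep_masks) {
    res$segmentation <- seg
    res$rpe_mask <- rpe
    res$patch_mask <- patch$mask
  }
  res
}

#' Measure a batch of B-scans into a study table
#'
#' @param bscans List of `bscan` objects (e.g. rendered phantoms).
#' @param cfg A [seg_config()].
#' @return A study table with one row per input scan (failures included,
#'   with `failed = TRUE` and `NA` measurements).
#' @export
analyse_batch <- function(bscans, cfg = seg_config()) {
  rows <- lapply(bscans, function(b) {
    m <- analyse_bscan(b, cfg)
    meta <- b$meta
    s <- meta$setting
    data.frame(subject = meta$subject,
               position = s$position, art = s$art_level,
               focus = s$focus_offset,
               setting = setting_label(s$position, s$art_level,
                                       s$focus_offset),
               repetition = meta$repetition, section = meta$section,
               vri = m$vri, vitreous_mean = m$vitreous_mean,
               rpe_mean = m$rpe_mean,
               failed = m$status != "ok",
               reason = m$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

parse_scan_filename <- function(path) {
  b <- basename(path)
  m <- regmatches(b, regexec("sub(\\d+)_set(\\d+)_rep(\\d+)_sec(\\d+)", b))[[1]]
  if (length(m) != 5L)
    stop("cannot parse scan metadata from filename: ", b,
         " (expected sub<ID>_set<ROW>_rep<R>_sec<K>)")
  proto <- canonical_protocol()
  row <- as.integer(m[3])
  if (row < 1L || row > nrow(proto))
    stop("setting row out of range in filename: ", b)
  list(subject = as.integer(m[2]),
       setting = acquisition_setting(proto$position[row], proto$art[row],
                                     proto$focus[row]),
       repetition = as.integer(m[4]), section = as.integer(m[5]))
}

#' Measure every scan image in a directory or manifest
#'
#' Reads 8-bit grayscale PNG (or TIFF) B-scans and measures each with
#' [analyse_bscan()]. Scans are located either by listing `dir` (file
#' names must follow `sub<ID>_set<ROW>_rep<R>_sec<K>`, where ROW indexes
#' the canonical protocol) or through a manifest CSV with columns `path`,
#' `subject`, `position`, `art`, `focus`, `repetition`, `section`.
#'
#' @param dir Directory of images, or `NULL` when `manifest` is given.
#' @param cfg A [seg_config()].
#' @param manifest Path to a manifest CSV.
#' @param pattern Filename pattern for directory listing.
#' @return A study table with one row per image.
#' @export
measure_directory <- function(dir = NULL, cfg = seg_config(),
                              manifest = NULL,
                              pattern = "\\.(png|tif|tiff)$") {
  if (is.null(dir) == is.null(manifest))
    stop("supply exactly one of `dir` or `manifest`")
  if (!is.null(manifest)) {
    mf <- read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("path", "subject", "position", "art", "focus", "repetition",
              "section")
    miss <- setdiff(need, names(mf))
    if (length(miss))
      stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
    base <- dirname(manifest)
    scans <- lapply(seq_len(nrow(mf)), function(i) {
      p <- mf$path[i]
      if (!file.exists(p)) p <- file.path(base, mf$path[i])
      if (!file.exists(p))
        stop("image file not found: ", mf$path[i])
      read_bscan(p, subject = mf$subject[i],
                 setting = acquisition_setting(mf$position[i], mf$art[i],
                                               mf$focus[i]),
                 repetition = mf$repetition[i], section = mf$section[i])
    })
  } else {
    files <- list.files(dir, pattern = pattern, full.names = TRUE)
    if (!length(files)) stop("no scan images found in ", dir)
    scans <- lapply(files, function(p) {
      meta <- parse_scan_filename(p)
      read_bscan(p, subject = meta$subject, setting = meta$setting,
                 repetition = meta$repetition, section = meta$section)
    })
  }
  analyse_batch(scans, cfg)
}
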