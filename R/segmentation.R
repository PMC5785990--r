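#' Segmentation configuration
#'
#' Free parameters of the retina/RPE segmentation and vitreous-patch
#' construction. Defaults: Otsu threshold, a disc structuring element of
#' radius 5 px (removes speckle islands smaller than retinal structures at
#' typical B-scan resolution), a 6 px RPE band taken from the lower edge of
#' the tissue mask per column, a 10 px clearance above the inner retinal
#' boundary, and the central 60% of columns.
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value Threshold in \[0, 1\] when
#'   `threshold_method = "fixed"`.
#' @param opening_radius Radius in pixels of the disc structuring element
#'   for the morphological opening.
#' @param min_column_coverage Minimum fraction of image columns the
#'   segmented tissue must span for the segmentation to count as
#'   successful.
#' @param rpe_band_thickness Pixels taken from the lower edge of the
#'   tissue mask per column to form the RPE band.
#' @param patch_margin Pixels kept clear between the vitreous patch and
#'   the inner retinal boundary.
#' @param lateral_crop_fraction Central fraction of columns retained for
#'   the patch.
#' @param min_patch_pixels Minimum vitreous patch size.
#' @param inverse_gamma Optional gamma exponent; when not `NULL`, pixel
#'   values are raised to this power before analysis (to undo display
#'   gamma on exported imagery). Default `NULL`: values used as provided.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(threshold_method = c("otsu", "fixed"),
                       threshold_value = NULL, opening_radius = 5L,
                       min_column_coverage = 0.6, rpe_band_thickness = 6L,
                       patch_margin = 10L, lateral_crop_fraction = 0.6,
                       min_patch_pixels = 500L, inverse_gamma = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" &&
      (is.null(threshold_value) || threshold_value <= 0 ||
         threshold_value >= 1))
    stop("`threshold_value` in (0, 1) is required for the fixed method")
  if (opening_radius < 1) stop("`opening_radius` must be >= 1")
  if (min_column_coverage <= 0 || min_column_coverage > 1)
    stop("`min_column_coverage` must be in (0, 1]")
  if (lateral_crop_fraction <= 0 || lateral_crop_fraction > 1)
    stop("`lateral_crop_fraction` must be in (0, 1]")
  if (rpe_band_thickness < 1) stop("`rpe_band_thickness` must be >= 1")
  structure(list(threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 opening_radius = as.integer(opening_radius),
                 min_column_coverage = min_column_coverage,
                 rpe_band_thickness = as.integer(rpe_band_thickness),
                 patch_margin = as.integer(patch_margin),
                 lateral_crop_fraction = lateral_crop_fraction,
                 min_patch_pixels = as.integer(min_patch_pixels),
                 inverse_gamma = inverse_gamma),
            class = "seg_config")
}

as_pixels <- function(image) {
  px <- if (inherits(image, "bscan")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px) || any(dim(px) == 0L))
    stop("image must be a non-empty numeric matrix (or a bscan)")
  px
}

failed_segmentation <- function(reason, dims) {
  structure(list(tissue_mask = matrix(FALSE, dims[1], dims[2]),
                 rpe_mask = NULL, vitreous_patch_mask = NULL,
                 inner_boundary = rep(NA_integer_, dims[2]),
                 threshold = NA_real_, success = FALSE,
                 failure_reason = reason),
            class = "vitan_segmentation")
}

#' Segment the retina/RPE complex of a B-scan
#'
#' Binarises the image (Otsu or fixed threshold), applies a morphological
#' opening with a disc structuring element, and keeps the largest
#' connected component as the retina/RPE tissue mask. Segmentation
#' succeeds only if that component spans at least
#' `min_column_coverage` of the image columns. The per-column topmost
#' tissue row is recorded as the inner (anterior) retinal boundary.
#'
#' @param image A `bscan` or numeric matrix with values in \[0, 1\],
#'   row 1 = top.
#' @param cfg A [seg_config()].
#' @return An object of class `vitan_segmentation`: `tissue_mask` (logical
#'   matrix), `inner_boundary` (per-column 1-based row index, `NA` where no
#'   tissue), `threshold`, `success`, `failure_reason`.
#' @export
segment_retina <- function(image, cfg = seg_config()) {
  px <- as_pixels(image)
  if (!is.null(cfg$inverse_gamma)) px <- px^cfg$inverse_gamma
  dims <- dim(px)
  rng <- range(px)
  if (diff(rng) == 0)
    return(failed_segmentation("no tissue detected", dims))

  thr <- if (cfg$threshold_method == "otsu")
    EBImage::otsu(EBImage::Image(px), range = c(0, 1))
  else cfg$threshold_value

  bw <- (px > thr) * 1
  if (!any(bw == 1))
    return(failed_segmentation("no tissue detected", dims))

  brush <- EBImage::makeBrush(2L * cfg$opening_radius + 1L, shape = "disc")
  opened <- EBImage::opening(bw, brush)
  lab <- EBImage::bwlabel(opened)
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0)
    return(failed_segmentation("no tissue detected", dims))

  sizes <- tabulate(lab[lab > 0L])
  tissue <- lab == which.max(sizes)

  coverage <- mean(colSums(tissue) > 0L)
  inner <- apply(tissue, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })

  structure(list(tissue_mask = tissue, rpe_mask = NULL,
                 vitreous_patch_mask = NULL, inner_boundary = inner,
                 threshold = as.numeric(thr),
                 success = coverage >= cfg$min_column_coverage,
                 failure_reason = if (coverage >= cfg$min_column_coverage)
                   NA_character_
                 else sprintf("tissue spans %.0f%% of columns (< %.0f%%)",
                              100 * coverage,
                              100 * cfg$min_column_coverage)),
            class = "vitan_segmentation")
}

#' Extract the RPE band from a segmentation
#'
#' For each column intersecting the tissue mask, the lowest
#' `rpe_band_thickness` tissue rows form the RPE band (the RPE is the
#' bright outermost band of the segmented complex). Columns without tissue
#' contribute no RPE pixels.
#'
#' @param seg A successful [segment_retina()] result.
#' @param cfg A [seg_config()].
#' @return Logical matrix, a subset of `seg$tissue_mask`.
#' @export
locate_rpe <- function(seg, cfg = seg_config()) {
  stopifnot(inherits(seg, "vitan_segmentation"))
  if (!isTRUE(seg$success)) stop("segmentation was not successful")
  tissue <- seg$tissue_mask
  if (!any(tissue)) stop("empty tissue mask")
  rpe <- matrix(FALSE, nrow(tissue), ncol(tissue))
  for (j in seq_len(ncol(tissue))) {
    rows <- which(tissue[, j])
    if (!length(rows)) next
    take <- utils::tail(rows, cfg$rpe_band_thickness)
    rpe[take, j] <- TRUE
  }
  rpe
}

#' Build the vitreous patch
#'
#' The patch is every pixel strictly more than `patch_margin` rows above
#' the inner retinal boundary of its column, restricted to the central
#' `lateral_crop_fraction` of columns, minus any tissue pixels. Columns
#' without segmented tissue contribute nothing. The patch must contain at
#' least `min_patch_pixels` pixels to be usable.
#'
#' @param image A `bscan` or pixel matrix (used for its dimensions).
#' @param seg A successful [segment_retina()] result.
#' @param cfg A [seg_config()].
#' @return List with `mask` (logical matrix), `n_pixels`, `success`,
#'   `failure_reason`.
#' @export
build_vitreous_patch <- function(image, seg, cfg = seg_config()) {
  px <- as_pixels(image)
  stopifnot(inherits(seg, "vitan_segmentation"))
  if (!isTRUE(seg$success)) stop("segmentation was not successful")
  h <- nrow(px); w <- ncol(px)
  side <- floor(w * (1 - cfg$lateral_crop_fraction) / 2)
  keep_cols <- seq.int(side + 1L, w - side)
  mask <- matrix(FALSE, h, w)
  for (j in keep_cols) {
    b <- seg$inner_boundary[j]
    if (is.na(b)) next
    top_rows <- b - 1L - cfg$patch_margin   # last patch row (1-based)
    if (top_rows >= 1L) mask[seq_len(top_rows), j] <- TRUE
  }
  mask <- mask & !seg$tissue_mask
  n <- sum(mask)
  list(mask = mask, n_pixels = n,
       success = n >= cfg$min_patch_pixels,
       failure_reason = if (n >= cfg$min_patch_pixels) NA_character_
       else sprintf("vitreous patch has %d px (< %d)", n,
                    cfg$min_patch_pixels))
}
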