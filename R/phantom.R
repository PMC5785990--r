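#' Phantom geometry
#'
#' Pixel-level geometry of a synthetic macular B-scan: a horizontal retina
#' band with a brighter RPE sub-band at its lower edge and a central foveal
#' dip, over a dark vitreous. Row 0 of the rendered image is the top
#' (anterior / vitreous side); rows increase toward the choroid.
#'
#' @param height,width Image dimensions in pixels.
#' @param retina_top_row 0-based row index of the anterior retinal surface
#'   away from the fovea.
#' @param retina_thickness,rpe_thickness Thickness in pixels of the neural
#'   retina band and of the RPE band at its lower edge.
#' @param fovea_depth Depth in pixels of the central dip of the inner
#'   surface (the foveal pit); must be smaller than `retina_thickness`.
#' @param lateral_crop_fraction Central fraction of columns considered the
#'   usable capture area (carried as metadata; the analysis applies its own
#'   crop).
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(height = 192L, width = 256L,
                             retina_top_row = 110L, retina_thickness = 40L,
                             rpe_thickness = 8L, fovea_depth = 12L,
                             lateral_crop_fraction = 0.6) {
  g <- list(height = as.integer(height), width = as.integer(width),
            retina_top_row = as.integer(retina_top_row),
            retina_thickness = as.integer(retina_thickness),
            rpe_thickness = as.integer(rpe_thickness),
            fovea_depth = as.integer(fovea_depth),
            lateral_crop_fraction = lateral_crop_fraction)
  if (any(unlist(g[c("height", "width", "retina_thickness",
                     "rpe_thickness")]) <= 0L))
    stop("all pixel dimensions must be positive")
  if (g$retina_top_row < 0L)
    stop("`retina_top_row` must be >= 0")
  if (g$fovea_depth < 0L || g$fovea_depth >= g$retina_thickness)
    stop("`fovea_depth` must be in [0, retina_thickness)")
  if (g$retina_top_row + g$retina_thickness + g$rpe_thickness > g$height)
    stop("retina band extends beyond the image: retina_top_row + ",
         "retina_thickness + rpe_thickness must be <= height")
  if (lateral_crop_fraction <= 0 || lateral_crop_fraction > 1)
    stop("`lateral_crop_fraction` must be in (0, 1]")
  structure(g, class = "phantom_geometry")
}

#' Phantom optics
#'
#' Intensity model of the phantom. Intensities live in \[0, 1\] (8-bit on
#' disk). Additive Gaussian noise at standard deviation
#' `base_noise_sd / sqrt(art_level)` emulates frame averaging. Focus is
#' modelled as a separable (gain, blur) pair per offset: the gain scales
#' the vitreous signal (defocused acquisitions image the vitreous more
#' brightly, positive offsets most of all) and the blur is a Gaussian PSF
#' applied to the noise-free scene. Bottom positioning translates the band
#' downward into an intensity roll-off at the lower edge of the acquisition
#' window (edge fading), dimming the RPE, and raises the vitreous signal.
#'
#' The default gain map is calibrated so in-focus scans give the smallest
#' vitreous/RPE ratio and positive offsets the largest, with the ratio near
#' 0.05 in focus; the optical model itself is a package design choice.
#'
#' @param vitreous_mean,retina_mean,rpe_mean,background_mean Noise-free
#'   region intensities in \[0, 1\]; must satisfy
#'   `background_mean < vitreous_mean < rpe_mean`.
#' @param base_noise_sd Additive noise standard deviation at ART = 1.
#' @param focus_gain_map Named numeric vector mapping focus offset
#'   (dioptres, as character names) to a vitreous intensity multiplier;
#'   must map 0 to 1, all gains >= 1, and positive offsets >= negative
#'   offsets of equal magnitude.
#' @param focus_blur_map Named numeric vector mapping focus offset to a
#'   Gaussian PSF sigma in pixels; must map 0 to 0.
#' @param bottom_fade_depth Pixels over which intensity rolls off at the
#'   lower image edge for bottom-positioned scans.
#' @param bottom_fade_floor Multiplier reached at the very bottom row of
#'   the fade ramp (1 = no fade).
#' @param bottom_vitreous_gain Vitreous intensity multiplier applied for
#'   bottom-positioned scans (noise pickup in the displaced patch).
#' @return An object of class `phantom_optics`.
#' @export
phantom_optics <- function(vitreous_mean = 0.041, retina_mean = 0.45,
                           rpe_mean = 0.85, background_mean = 0.01,
                           base_noise_sd = 0.03,
                           focus_gain_map = c("-10" = 3.4, "-5" = 1.8,
                                              "0" = 1, "5" = 4.0,
                                              "10" = 4.2),
                           focus_blur_map = c("-10" = 2, "-5" = 1,
                                              "0" = 0, "5" = 1.5,
                                              "10" = 2.5),
                           bottom_fade_depth = 30L,
                           bottom_fade_floor = 0.8,
                           bottom_vitreous_gain = 1.2) {
  # equality of background and vitreous is the zero-haze phantom
  if (!(background_mean >= 0 && background_mean <= vitreous_mean &&
        vitreous_mean < rpe_mean && rpe_mean <= 1))
    stop("need 0 <= background_mean <= vitreous_mean < rpe_mean <= 1")
  if (base_noise_sd < 0) stop("`base_noise_sd` must be >= 0")
  if (is.null(names(focus_gain_map)) || is.null(names(focus_blur_map)))
    stop("focus maps must be named by offset (dioptres)")
  if (!isTRUE(all.equal(unname(focus_gain_map["0"]), 1)))
    stop("focus_gain_map must map offset 0 to gain 1")
  if (!isTRUE(all.equal(unname(focus_blur_map["0"]), 0)))
    stop("focus_blur_map must map offset 0 to blur 0")
  if (any(focus_gain_map < 1))
    stop("focus gains must be >= 1")
  offs <- as.numeric(names(focus_gain_map))
  for (o in offs[offs > 0]) {
    neg <- as.character(-o)
    if (neg %in% names(focus_gain_map) &&
        focus_gain_map[as.character(o)] < focus_gain_map[neg])
      stop("positive focus offsets must have gain >= the matching ",
           "negative offset")
  }
  structure(list(vitreous_mean = vitreous_mean, retina_mean = retina_mean,
                 rpe_mean = rpe_mean, background_mean = background_mean,
                 base_noise_sd = base_noise_sd,
                 focus_gain_map = focus_gain_map,
                 focus_blur_map = focus_blur_map,
                 bottom_fade_depth = as.integer(bottom_fade_depth),
                 bottom_fade_floor = bottom_fade_floor,
                 bottom_vitreous_gain = bottom_vitreous_gain),
            class = "phantom_optics")
}

lookup_focus <- function(map, offset, what) {
  key <- as.character(offset)
  if (!key %in% names(map))
    stop(sprintf("no %s entry for focus offset %s D", what, key))
  unname(map[key])
}

#' Render a synthetic B-scan phantom
#'
#' Builds a noise-free scene from the geometry and optics, applies the
#' focus gain and blur for the setting, the bottom translation and edge
#' fade when `setting$position == "bottom"`, then adds seeded Gaussian
#' noise at sd `base_noise_sd / sqrt(art_level)` and clips to \[0, 1\].
#' Ground truth (region masks and the noise-free region means measured on
#' the rendered scene) is recorded alongside the pixels.
#'
#' @param geometry A [phantom_geometry()].
#' @param optics A [phantom_optics()].
#' @param setting An [acquisition_setting()].
#' @param seed Integer seed for the noise stream.
#' @param subject,repetition,section Metadata carried on the scan.
#' @return An object of class `bscan`: list with `pixels` (height x width
#'   matrix in \[0, 1\], row 1 = top), `meta` and `truth` (masks
#'   `vitreous`, `tissue`, `rpe`; means `vitreous_mean`, `rpe_mean`;
#'   `vri`).
#' @examples
#' b <- make_phantom(phantom_geometry(), phantom_optics(),
#'                   acquisition_setting("middle", 100, 0), seed = 1)
#' b$truth$vri
#' @export
make_phantom <- function(geometry, optics, setting, seed = 1L,
                         subject = 1L, repetition = 1L, section = 1L) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(optics, "phantom_optics"),
            inherits(setting, "oct_setting"))
  g <- geometry; o <- optics
  h <- g$height; w <- g$width

  shift <- 0L
  if (setting$position == "bottom") {
    # push the band so its lower edge sits just above the bottom row,
    # inside the fade ramp
    band_bottom <- g$retina_top_row + g$retina_thickness + g$rpe_thickness
    shift <- (h - 6L) - band_bottom
    if (shift < 0L) shift <- 0L
  }
  top <- g$retina_top_row + shift
  if (top + g$retina_thickness + g$rpe_thickness > h)
    stop("retina band extends beyond the image for this positioning")

  gain <- lookup_focus(o$focus_gain_map, setting$focus_offset, "gain")
  blur <- lookup_focus(o$focus_blur_map, setting$focus_offset, "blur")
  vit_gain <- gain *
    if (setting$position == "bottom") o$bottom_vitreous_gain else 1

  # inner (anterior) boundary per column: foveal pit as a Gaussian dip
  cols <- seq_len(w)
  centre <- (w + 1) / 2
  dip <- round(g$fovea_depth * exp(-((cols - centre) / (w / 8))^2))
  inner <- top + dip                      # 0-based row of first tissue pixel
  rpe_top <- top + g$retina_thickness     # flat RPE band
  rpe_bot <- rpe_top + g$rpe_thickness    # exclusive

  img <- matrix(o$background_mean, nrow = h, ncol = w)
  vit_mask <- tis_mask <- rpe_mask <- matrix(FALSE, h, w)
  vit_value <- min(o$vitreous_mean * vit_gain, 1)
  for (j in cols) {
    ib <- inner[j]                        # 0-based
    if (ib > 0L) {
      img[seq_len(ib), j] <- vit_value
      vit_mask[seq_len(ib), j] <- TRUE
    }
    rows_ret <- seq.int(ib + 1L, rpe_top)         # 1-based retina rows
    img[rows_ret, j] <- o$retina_mean
    rows_rpe <- seq.int(rpe_top + 1L, rpe_bot)    # 1-based RPE rows
    img[rows_rpe, j] <- o$rpe_mean
    tis_mask[c(rows_ret, rows_rpe), j] <- TRUE
    rpe_mask[rows_rpe, j] <- TRUE
  }

  if (blur > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur))

  if (setting$position == "bottom" && o$bottom_fade_depth > 0L &&
      o$bottom_fade_floor < 1) {
    d <- min(o$bottom_fade_depth, h)
    ramp_rows <- seq.int(h - d + 1L, h)
    fac <- 1 - (1 - o$bottom_fade_floor) * (seq_len(d) / d)
    img[ramp_rows, ] <- img[ramp_rows, ] * fac
  }

  truth <- list(
    vitreous = vit_mask, tissue = tis_mask, rpe = rpe_mask,
    vitreous_mean = mean(img[vit_mask]),
    rpe_mean = mean(img[rpe_mask])
  )
  truth$vri <- truth$vitreous_mean / truth$rpe_mean

  noise_sd <- o$base_noise_sd / sqrt(setting$art_level)
  if (noise_sd > 0) {
    old <- .Random.seed_exists()
    set.seed(seed)
    img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
    restore_rng(old)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  structure(list(
    pixels = img,
    meta = list(subject = as.integer(subject), setting = setting,
                repetition = as.integer(repetition),
                section = as.integer(section)),
    truth = truth
  ), class = "bscan")
}

# save/restore the global RNG state so seeded phantom noise does not
# perturb an enclosing simulation's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @export
print.bscan <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<bscan> %dx%d  subject %d, %s, rep %d, section %d  truth VRI %.4f\n",
    nrow(x$pixels), ncol(x$pixels), m$subject,
    setting_label(m$setting$position, m$setting$art_level,
                  m$setting$focus_offset),
    m$repetition, m$section, x$truth$vri))
  invisible(x)
}

#' Write / read a B-scan as an 8-bit grayscale image
#'
#' `write_bscan()` writes `pixels` as 8-bit grayscale PNG.
#' `read_bscan()` reads a PNG (or TIFF when the `tiff` package is
#' available), averaging channels if the file is not single-channel, and
#' attaches the supplied metadata.
#'
#' @param bscan A `bscan` object (or a plain matrix in \[0, 1\]).
#' @param path File path; directories are created as needed.
#' @param subject,setting,repetition,section Metadata for `read_bscan()`.
#' @return `write_bscan()` returns `path` invisibly; `read_bscan()` a
#'   `bscan` (without ground truth).
#' @export
write_bscan <- function(bscan, path) {
  px <- if (inherits(bscan, "bscan")) bscan$pixels else bscan
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # quantise to 8 bit explicitly so the on-disk image is bit-stable
  q <- round(px * 255) / 255
  png::writePNG(q, target = path)
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path, subject = NA_integer_, setting = NULL,
                       repetition = NA_integer_, section = NA_integer_) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  structure(list(pixels = px,
                 meta = list(subject = subject, setting = setting,
                             repetition = repetition, section = section),
                 truth = NULL),
            class = "bscan")
}
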