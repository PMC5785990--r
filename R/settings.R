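#' Acquisition setting
#'
#' One combination of vertical retina positioning, frame-averaging (ART)
#' level and focus offset, as set on the device at acquisition time. The
#' canonical study protocol uses ten such combinations (see
#' [canonical_protocol()]); arbitrary valid combinations can be constructed
#' for phantom experiments.
#'
#' @param position Vertical position of the retina within the scan window,
#'   `"middle"` or `"bottom"`.
#' @param art_level Number of B-scan frames averaged per section (ART,
#'   Automated Real Time). Any integer >= 1; the protocol uses
#'   6, 12, 25, 50 or 100.
#' @param focus_offset Focus offset in dioptres relative to optimal retinal
#'   focus; the protocol uses -10, -5, 0, +5 or +10.
#' @return An object of class `oct_setting`.
#' @examples
#' acquisition_setting("middle", 100, 0)
#' @export
acquisition_setting <- function(position = c("middle", "bottom"),
                                art_level = 100, focus_offset = 0) {
  position <- match.arg(position)
  if (!is.numeric(art_level) || length(art_level) != 1L ||
      art_level < 1 || art_level != round(art_level))
    stop("`art_level` must be a single integer >= 1")
  if (!is.numeric(focus_offset) || length(focus_offset) != 1L)
    stop("`focus_offset` must be a single number (dioptres)")
  structure(list(position = position,
                 art_level = as.integer(art_level),
                 focus_offset = as.numeric(focus_offset)),
            class = "oct_setting")
}

#' @export
print.oct_setting <- function(x, ...) {
  cat(sprintf("<oct_setting> position=%s, ART=%d, focus=%+g D\n",
              x$position, x$art_level, x$focus_offset))
  invisible(x)
}

#' Label identifying a setting combination
#'
#' Stable text key used throughout study tables, e.g. `"middle_art100_f0"`
#' or `"middle_art100_f+5"`.
#'
#' @param position,art,focus Vectors of position, ART level and focus
#'   offset (recycled to a common length).
#' @return Character vector of labels.
#' @export
setting_label <- function(position, art, focus) {
  f <- ifelse(focus > 0, paste0("+", focus), as.character(focus))
  sprintf("%s_art%d_f%s", position, as.integer(art), f)
}

#' The canonical ten-setting scanning protocol
#'
#' The ten position/ART/focus combinations of the study protocol: five
#' in-focus middle-positioned rows with varying ART (100, 50, 25, 12, 6),
#' four ART-100 middle rows with non-zero focus offsets (+5, +10, -5, -10
#' dioptres) and one bottom-positioned ART-100 in-focus row. The ART-100
#' in-focus middle row is shared between the ART and focus arms.
#'
#' @return A data.frame with columns `position`, `art`, `focus`, `setting`.
#' @export
canonical_protocol <- function() {
  p <- data.frame(
    position = c(rep("middle", 9L), "bottom"),
    art      = c(100L, 50L, 25L, 12L, 6L, rep(100L, 5L)),
    focus    = c(rep(0, 5L), 5, 10, -5, -10, 0),
    stringsAsFactors = FALSE
  )
  p$setting <- setting_label(p$position, p$art, p$focus)
  p
}

#' Select a study arm from protocol slots or a study table
#'
#' The "ART arm" is the five in-focus middle rows with varying ART level;
#' the "focus arm" the five ART-100 middle rows with varying focus (the
#' in-focus row belongs to both); the "position arm" the two ART-100
#' in-focus rows (middle vs bottom).
#'
#' @param x A data.frame with `position`, `art`, `focus` columns
#'   (protocol slots from [enumerate_protocol()] or a study table).
#' @param arm `"art"`, `"focus"` or `"position"`.
#' @return The subset of rows belonging to the arm.
#' @export
protocol_arm <- function(x, arm = c("art", "focus", "position")) {
  arm <- match.arg(arm)
  stopifnot(all(c("position", "art", "focus") %in% names(x)))
  keep <- switch(arm,
    art      = x$position == "middle" & x$focus == 0,
    focus    = x$position == "middle" & x$art == 100L,
    position = x$art == 100L & x$focus == 0
  )
  x[keep, , drop = FALSE]
}
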