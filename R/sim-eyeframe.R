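#' Render a synthetic eye frame
#'
#' Draws a bright elliptical eye region on a darker background, emulating
#' the pre-cropped monochrome eye video that eyelid extraction consumes.
#' The ellipse's horizontal (major) extent is fixed by the geometry; its
#' vertical (minor) extent interpolates linearly between the closed and
#' open extents with `openness`, so the eyelid distance reported by
#' [extract_eyelid_distance()] should recover
#' `closed_minor_px + openness * (open_minor_px - closed_minor_px)`.
#'
#' @param openness Eye openness in \[0, 1\] (1 = fully open).
#' @param geometry List with `width`, `height` (frame size, px), `center`
#'   (c(row, col)), `major_px` (full horizontal extent), `open_minor_px`
#'   and `closed_minor_px` (full vertical eyelid distances at openness 1
#'   and 0).
#' @param fg,bg Foreground/background intensities in \[0, 1\].
#' @param noise_sd Additive Gaussian intensity noise SD.
#' @param seed Integer seed (noise only).
#' @return A `height x width` numeric matrix with values in \[0, 1\].
#' @examples
#' fr <- gen_eye_frame(1, noise_sd = 0)
#' extract_eyelid_distance(fr)$distance_px   # ~ 40
#' @export
gen_eye_frame <- function(openness,
                          geometry = list(width = 172, height = 160,
                                          center = c(80, 86),
                                          major_px = 80,
                                          open_minor_px = 40,
                                          closed_minor_px = 0),
                          fg = 0.9, bg = 0.15, noise_sd = 0.02,
                          seed = 1L) {
  if (!is.numeric(openness) || length(openness) != 1L ||
      !is.finite(openness) || openness < 0 || openness > 1)
    stopf("`openness` must be in [0, 1]")
  w <- assert_count(geometry$width, "width")
  h <- assert_count(geometry$height, "height")
  minor <- geometry$closed_minor_px +
    openness * (geometry$open_minor_px - geometry$closed_minor_px)
  a <- geometry$major_px / 2   # horizontal semi-axis (columns)
  b <- minor / 2               # vertical semi-axis (rows)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  frame <- matrix(bg, h, w)
  if (b > 0) {
    inside <- ((rows - geometry$center[1]) / b)^2 +
      ((cols - geometry$center[2]) / a)^2 <= 1
    frame[inside] <- fg
  }
  if (noise_sd > 0) {
    set.seed(assert_seed(seed))
    frame <- frame + matrix(rnorm(h * w, 0, noise_sd), h, w)
  }
  clip01(frame)
}
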