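#' Pixel-to-metric calibration from a ruler of known length
#'
#' Each camera is calibrated independently with a ruler photographed in
#' its own view: the scale parameter is the ruler's true length divided
#' by its apparent pixel length, giving cm per pixel. Every downstream
#' formula multiplies a pixel distance by the scale to obtain
#' centimetres, which is what fixes the direction of the ratio.
#'
#' @param ruler_pixel_length apparent ruler length in pixels (> 0).
#' @param ruler_true_length true ruler length in cm (> 0).
#' @return cm-per-pixel conversion factor.
#' @examples
#' compute_scale(100, 10) # 0.1 cm per pixel
#' @export
compute_scale <- function(ruler_pixel_length, ruler_true_length) {
  if (!is.numeric(ruler_pixel_length) || !is.numeric(ruler_true_length) ||
      length(ruler_pixel_length) != 1L || length(ruler_true_length) != 1L ||
      !is.finite(ruler_pixel_length) || !is.finite(ruler_true_length) ||
      ruler_pixel_length <= 0 || ruler_true_length <= 0)
    stop("calibration error: ruler readings must be finite and > 0", call. = FALSE)
  ruler_true_length / ruler_pixel_length
}

#' Scale parameters for the two views
#'
#' @param side_cm_per_px,top_cm_per_px cm-per-pixel factors, both > 0.
#' @return Named numeric vector `c(side = ..., top = ...)` of class
#'   `scale_params`.
#' @export
scale_params <- function(side_cm_per_px, top_cm_per_px) {
  s <- c(side = as.numeric(side_cm_per_px), top = as.numeric(top_cm_per_px))
  if (!all(is.finite(s)) || any(s <= 0))
    stop("calibration error: scales must be finite and > 0", call. = FALSE)
  class(s) <- "scale_params"
  s
}

as_scale_params <- function(x) {
  if (inherits(x, "scale_params")) return(x)
  if (is.numeric(x) && length(x) == 2L) {
    if (!is.null(names(x)) && all(c("side", "top") %in% names(x)))
      return(scale_params(x[["side"]], x[["top"]]))
    return(scale_params(x[1], x[2]))
  }
  if (is.list(x) && all(c("side", "top") %in% names(x)))
    return(scale_params(x$side, x$top))
  stop("cannot interpret scales; use scale_params(side, top)", call. = FALSE)
}

#' Calibrate both views from ruler readings
#'
#' @param side_ruler,top_ruler length-2 numerics
#'   `c(pixel_length, true_length_cm)` for the ruler as seen in the
#'   side and top view respectively.
#' @return A [scale_params()] object (cm per pixel for each view).
#' @examples
#' calibrate_views(c(200, 20), c(400, 20)) # side 0.1, top 0.05
#' @export
calibrate_views <- function(side_ruler, top_ruler) {
  stopifnot(length(side_ruler) == 2L, length(top_ruler) == 2L)
  scale_params(compute_scale(side_ruler[1], side_ruler[2]),
               compute_scale(top_ruler[1], top_ruler[2]))
}
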