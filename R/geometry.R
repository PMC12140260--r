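#' Planar geometry primitives for dual-view morphometry
#'
#' These are the vector operations every measurement is assembled from:
#' Euclidean distances and vectors between labelled image points, the
#' cosine of a vector against the horizontal image axis, scalar
#' projections onto a body-axis vector, and the dual-view 3D length
#' reconstruction that corrects an in-plane measurement for body
#' curvature seen in the orthogonal view.
#'
#' Points are numeric length-2 vectors `c(x, y)` in pixel coordinates
#' (origin top-left, y downward); sub-pixel values are allowed and no
#' rounding is performed anywhere.
#'
#' @name geometry
#' @keywords internal
NULL

# tolerance below which a top-view direction cosine makes the 3D
# reconstruction numerically unbounded
.COS_EPS <- 1e-6

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p)))
    stop(what, " must be a finite length-2 numeric (x, y)", call. = FALSE)
  p
}

#' Euclidean distance between two image points
#'
#' @param a,b numeric length-2 points `c(x, y)` in pixels.
#' @return Distance in pixels (non-negative scalar).
#' @examples
#' pt_dist(c(0, 0), c(3, 4)) # 5
#' @export
pt_dist <- function(a, b) {
  a <- as_point(a); b <- as_point(b)
  sqrt(sum((b - a)^2))
}

#' Vector from point a to point b
#'
#' @inheritParams pt_dist
#' @return Numeric length-2 vector `c(dx, dy)` in pixels.
#' @export
pt_vec <- function(a, b) {
  as_point(b) - as_point(a)
}

#' Absolute cosine of a vector against the horizontal image axis
#'
#' Returns `|dx| / |v|`, in `[0, 1]`. The absolute value makes the
#' result independent of whether the vector points left or right: every
#' consumer feeds the cosine into [reconstruct_3d_length()], where only
#' its square (and the complementary sine squared) survive, so the sign
#' carries no information and dropping it avoids orientation ambiguity
#' for tail-ward versus head-ward vectors.
#'
#' @param v numeric length-2 vector `c(dx, dy)`.
#' @return Dimensionless scalar in `[0, 1]`.
#' @export
axis_cosine <- function(v) {
  v <- as_point(v, "vector")
  n <- sqrt(sum(v^2))
  if (n == 0)
    stop("degenerate geometry: axis cosine of a zero-length vector", call. = FALSE)
  abs(v[1]) / n
}

#' Magnitude of the scalar projection of one vector onto another
#'
#' `|u . onto| / |onto|`, in pixels. The magnitude (not the signed
#' projection) is returned because projected lengths are compared as
#' lengths when choosing the shorter tail lobe; a signed value would
#' corrupt that comparison for a backward-pointing tail point.
#'
#' @param u numeric length-2 vector to project.
#' @param onto numeric length-2 reference vector (non-zero).
#' @return Projected length in pixels, `<= |u|`.
#' @export
scalar_projection <- function(u, onto) {
  u <- as_point(u, "vector"); onto <- as_point(onto, "vector")
  n <- sqrt(sum(onto^2))
  if (n == 0)
    stop("degenerate geometry: projection onto a zero-length vector", call. = FALSE)
  abs(sum(u * onto)) / n
}

#' Reconstruct the 3D length of a segment from one view plus two angles
#'
#' A segment of true length `|OA|` in 3D projects into the side-view
#' plane with length `proj_len` and direction cosine `cos_side`
#' (against the shared horizontal body axis); its projection into the
#' orthogonal top-view plane has direction cosine `cos_top` against the
#' same axis. The true length is then
#'
#' \deqn{|OA| = \sqrt{(L \cos\alpha / \cos\beta)^2 + (L \sin\alpha)^2}}
#'
#' with \eqn{L} the projected length, \eqn{\cos\alpha} = `cos_side`,
#' \eqn{\cos\beta} = `cos_top` and \eqn{\sin\alpha =
#' \sqrt{1-\cos^2\alpha}}. The horizontal run recovered in the side view
#' (`L cos_side`) is stretched by the top-view inclination (division by
#' `cos_top`), while the vertical rise (`L sin_side`) is already seen at
#' true length. The result never falls below `proj_len` and equals it
#' when `cos_top = 1` (segment parallel to the side-view plane).
#'
#' @param proj_len projected length in the side view; any length unit
#'   (the result is in the same unit). Must be `>= 0`.
#' @param cos_side side-view direction cosine, in `[0, 1]`.
#' @param cos_top top-view direction cosine; `|cos_top|` must exceed
#'   `1e-6`, below which the segment is nearly perpendicular to the
#'   horizontal axis in the top view and its length is unrecoverable.
#' @return Reconstructed 3D length, same unit as `proj_len`.
#' @export
reconstruct_3d_length <- function(proj_len, cos_side, cos_top) {
  stopifnot(is.numeric(proj_len), length(proj_len) == 1L, is.finite(proj_len))
  if (proj_len < 0)
    stop("projected length must be non-negative", call. = FALSE)
  if (abs(cos_side) > 1 + 1e-12 || abs(cos_top) > 1 + 1e-12)
    stop("direction cosines must lie in [-1, 1]", call. = FALSE)
  if (abs(cos_top) < .COS_EPS)
    stop("near-perpendicular top view: |cos_top| < 1e-6, length unrecoverable",
         call. = FALSE)
  cos_a <- min(abs(cos_side), 1)
  sin_a <- sqrt(max(0, 1 - cos_a^2))
  sqrt((proj_len * cos_a / abs(cos_top))^2 + (proj_len * sin_a)^2)
}

#' Length fractions of the segments of an open polyline
#'
#' Used to distribute the side-view mid-body length over the three
#' top-view body segments in proportion to their apparent lengths.
#'
#' @param vertices numeric matrix with one vertex per row (columns x, y),
#'   at least two rows; for the body polyline the rows are the derived
#'   fin-middle point, the middle-middle point, the middle point and the
#'   small-tail point, in that order.
#' @return Numeric vector of per-segment fractions summing to 1.
#' @export
polyline_proportions <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L)
    stop("polyline needs at least two vertices", call. = FALSE)
  seg <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                       vertices[-nrow(vertices), , drop = FALSE])^2))
  total <- sum(seg)
  if (total == 0)
    stop("degenerate geometry: polyline has zero total length", call. = FALSE)
  seg / total
}
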