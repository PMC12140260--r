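#' Seven phenotypic measurements from a dual-view keypoint skeleton
#'
#' Three traits are purely planar (body height, body thickness and
#' tail-handle height: a single landmark pair in one view times that
#' view's scale). The remaining four (head length, body length, full
#' length, tail-handle width) combine a side-view pixel length with
#' direction cosines from both views through the 3D length
#' reconstruction, so that a fish curving in the horizontal plane is
#' still measured along its body.
#'
#' The body length decomposes the side-view mid-body length (head-middle
#' to small-middle to caudal-fin base) over the three top-view body
#' segments (fin-middle to middle-middle to middle to small-tail) in
#' proportion to their apparent top-view lengths, reconstructing each
#' share with the shared side-view chord cosine and that segment's
#' top-view cosine. The full length adds a tail term: the shorter of the
#' two caudal-fin tips' projections onto the body axis, reconstructed
#' with the chosen tail vector's cosines. Ties between the two tail
#' projections resolve to the upper tip, deterministically.
#'
#' @param spec an [annotated_specimen()] with valid scales.
#' @return Each trait function returns a length in cm; [measure_specimen()]
#'   returns a one-row data frame with columns `specimen_id`, `FL`, `BL`,
#'   `BH`, `BT`, `HL`, `THH`, `THW` (all cm).
#' @name morphometry
NULL

#' @rdname morphometry
#' @export
body_thickness <- function(spec) {
  pt_dist(TP(spec, "fin-right"), TP(spec, "fin-left")) * spec$scales[["top"]]
}

#' @rdname morphometry
#' @export
body_height <- function(spec) {
  pt_dist(S(spec, "head-up"), S(spec, "head-down")) * spec$scales[["side"]]
}

#' @rdname morphometry
#' @export
tail_handle_height <- function(spec) {
  pt_dist(S(spec, "small-up"), S(spec, "small-down")) * spec$scales[["side"]]
}

#' @rdname morphometry
#' @export
head_length <- function(spec) {
  mid <- derive_midpoints(spec)
  reconstruct_3d_length(
    pt_dist(S(spec, "side-head"), S(spec, "head-fin")) * spec$scales[["side"]],
    axis_cosine(pt_vec(S(spec, "side-head"), S(spec, "head-fin"))),
    axis_cosine(pt_vec(TP(spec, "top-head"), mid$t10_fin_middle)))
}

#' @rdname morphometry
#' @export
body_length <- function(spec) {
  mid <- derive_midpoints(spec)
  ss <- spec$scales[["side"]]
  # head segment: mouth to head-middle, top inclination from mouth to fin-middle
  l_hm <- reconstruct_3d_length(
    pt_dist(S(spec, "side-head"), mid$s11_head_middle) * ss,
    axis_cosine(pt_vec(S(spec, "side-head"), mid$s11_head_middle)),
    axis_cosine(pt_vec(TP(spec, "top-head"), mid$t10_fin_middle)))
  # side-view mid-body length, distributed over the top-view polyline
  tmp <- (pt_dist(mid$s11_head_middle, mid$s12_small_middle) +
          pt_dist(S(spec, "side-tail"), mid$s12_small_middle)) * ss
  poly <- rbind(mid$t10_fin_middle, mid$t11_middle_middle,
                TP(spec, "middle"), TP(spec, "small-tail"))
  props <- polyline_proportions(poly)
  cos_side <- axis_cosine(pt_vec(mid$s12_small_middle, mid$s11_head_middle))
  cos_top <- vapply(1:3, function(i)
    axis_cosine(poly[i + 1L, ] - poly[i, ]), numeric(1))
  l_hm + sum(vapply(1:3, function(i)
    reconstruct_3d_length(tmp * props[i], cos_side, cos_top[i]), numeric(1)))
}

# tail term of the full length: shorter caudal-fin tip projection onto
# the body axis, reconstructed with the chosen tip's own side cosine
tail_length_cm <- function(spec) {
  mid <- derive_midpoints(spec)
  axis <- pt_vec(mid$s12_small_middle, mid$s11_head_middle)
  v_up <- pt_vec(S(spec, "tail-up"), S(spec, "side-tail"))
  v_down <- pt_vec(S(spec, "tail-down"), S(spec, "side-tail"))
  p_up <- scalar_projection(v_up, axis)
  p_down <- scalar_projection(v_down, axis)
  chosen <- if (p_up <= p_down) v_up else v_down   # tie: upper tip
  reconstruct_3d_length(
    min(p_up, p_down) * spec$scales[["side"]],
    axis_cosine(chosen),
    axis_cosine(pt_vec(TP(spec, "small-tail"), TP(spec, "top-tail"))))
}

#' @rdname morphometry
#' @export
full_length <- function(spec) {
  body_length(spec) + tail_length_cm(spec)
}

#' @rdname morphometry
#' @export
tail_handle_width <- function(spec) {
  mid <- derive_midpoints(spec)
  axis <- pt_vec(mid$s12_small_middle, mid$s11_head_middle)
  proj_front <- scalar_projection(
    pt_vec(mid$s12_small_middle, S(spec, "front-small")), axis)
  proj_back <- scalar_projection(
    pt_vec(S(spec, "side-tail"), mid$s12_small_middle), axis)
  reconstruct_3d_length(
    (proj_front + proj_back) * spec$scales[["side"]],
    axis_cosine(axis),
    axis_cosine(pt_vec(TP(spec, "small-tail"), TP(spec, "middle"))))
}

#' @rdname morphometry
#' @export
measure_specimen <- function(spec) {
  stopifnot(inherits(spec, "annotated_specimen"))
  findings <- validate_annotation(spec)
  if (length(findings))
    stop("specimen '", spec$specimen_id, "' failed validation:\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  one <- function(name, fn) {
    tryCatch(fn(spec), error = function(e)
      stop("measurement '", name, "' failed for specimen '",
           spec$specimen_id, "': ", conditionMessage(e), call. = FALSE))
  }
  data.frame(
    specimen_id = spec$specimen_id,
    FL  = one("full_length", full_length),
    BL  = one("body_length", body_length),
    BH  = one("body_height", body_height),
    BT  = one("body_thickness", body_thickness),
    HL  = one("head_length", head_length),
    THH = one("tail_handle_height", tail_handle_height),
    THW = one("tail_handle_width", tail_handle_width),
    stringsAsFactors = FALSE
  )
}

#' Write measurement records to CSV
#'
#' @param records data frame of measurement rows from
#'   [measure_specimen()].
#' @param path output CSV path.
#' @param digits decimal places for the length columns (default 3,
#'   matching manual measurement precision).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, digits = 3) {
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], round, digits = digits)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
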