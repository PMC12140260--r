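#' Keypoint skeletons for the two camera views
#'
#' The lateral (side) view carries ten named landmarks and the dorsal
#' (top) view nine; four derived pseudo-landmarks are midpoints of
#' annotated pairs. Every measurement consumes specific landmarks, so
#' annotation completeness is mandatory: specimens with missing points
#' are rejected from measurement rather than silently patched.
#'
#' @name skeleton
#' @keywords internal
NULL

#' Landmark labels of the side-view and top-view skeletons
#'
#' Side view (S1..S10): mouth, rear gill point, dorsal-fin inflection
#' and its ventral counterpart, anal-fin inflection, upper and lower
#' points of the narrowest caudal peduncle, caudal-fin base on the body
#' axis, and the upper and lower caudal-fin tips. Top view (T1..T9):
#' mouth, right and left pectoral-fin inflections, the dorsal point
#' above the dorsal-fin inflection, right and left ventral-fin
#' inflections, the second dorsal-fin inflection, the narrowest caudal
#' peduncle, and the caudal-fin tip.
#'
#' @format Character vectors of landmark labels, in skeleton order.
#' @export
SIDE_LABELS <- c("side-head", "head-fin", "head-up", "head-down",
                 "front-small", "small-up", "small-down", "side-tail",
                 "tail-up", "tail-down")

#' @rdname SIDE_LABELS
#' @export
TOP_LABELS <- c("top-head", "fin-right", "fin-left", "fin-up",
                "middle-right", "middle-left", "middle", "small-tail",
                "top-tail")

as_keypoint_matrix <- function(x, labels, view) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, as.numeric))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 2L)
    stop(view, "-view keypoints must have two columns (x, y)", call. = FALSE)
  if (is.null(rownames(x))) {
    if (nrow(x) != length(labels))
      stop(view, "-view keypoints: expected ", length(labels), " points, got ",
           nrow(x), call. = FALSE)
    rownames(x) <- labels
  } else {
    missing <- setdiff(labels, rownames(x))
    if (length(missing))
      stop(view, "-view keypoints missing label(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    x <- x[labels, , drop = FALSE]
  }
  colnames(x) <- c("x", "y")
  x
}

#' Assemble an annotated specimen from both views
#'
#' @param specimen_id character scalar identifying the fish.
#' @param side 10 x 2 matrix (or list of `c(x, y)`) of side-view
#'   keypoints; rows may be named with [SIDE_LABELS], otherwise skeleton
#'   order is assumed.
#' @param top 9 x 2 matrix of top-view keypoints (see [TOP_LABELS]).
#' @param scales scale parameters from [calibrate_views()] or
#'   [scale_params()]: cm per pixel for each view.
#' @param image_size optional list with `side` and/or `top` entries,
#'   each `c(width, height)` in pixels, used for bounds checking.
#' @param metadata optional named list of free-form metadata.
#' @return An object of class `annotated_specimen`.
#' @export
annotated_specimen <- function(specimen_id, side, top, scales,
                               image_size = NULL, metadata = list()) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L)
  side <- as_keypoint_matrix(side, SIDE_LABELS, "side")
  top <- as_keypoint_matrix(top, TOP_LABELS, "top")
  scales <- as_scale_params(scales)
  structure(list(specimen_id = specimen_id, side = side, top = top,
                 scales = scales, image_size = image_size,
                 metadata = metadata),
            class = "annotated_specimen")
}

#' @export
print.annotated_specimen <- function(x, ...) {
  cat("<annotated_specimen>", x$specimen_id, "\n")
  cat("  side view: ", nrow(x$side), " keypoints; top view: ",
      nrow(x$top), " keypoints\n", sep = "")
  cat(sprintf("  scales: %.6g cm/px (side), %.6g cm/px (top)\n",
              x$scales[["side"]], x$scales[["top"]]))
  invisible(x)
}

# shorthand accessors used throughout the measurement code
S <- function(spec, i) spec$side[i, ]
TP <- function(spec, i) spec$top[i, ]

#' Derived midpoints of the two skeletons
#'
#' Four pseudo-landmarks are defined as arithmetic midpoints of
#' annotated pairs: fin-middle (T10, midpoint of the two pectoral-fin
#' points), head-middle (S11, midpoint of head-up and head-down),
#' small-middle (S12, midpoint of small-up and small-down) and
#' middle-middle (T11, midpoint of the two ventral-fin points).
#'
#' @param side,top keypoint matrices as stored in an
#'   [annotated_specimen()], or the specimen itself may be passed as
#'   `side` with `top` missing.
#' @return Named list of length-2 points: `t10_fin_middle`,
#'   `s11_head_middle`, `s12_small_middle`, `t11_middle_middle`.
#' @export
derive_midpoints <- function(side, top) {
  if (missing(top) && inherits(side, "annotated_specimen")) {
    top <- side$top; side <- side$side
  }
  side <- as_keypoint_matrix(side, SIDE_LABELS, "side")
  top <- as_keypoint_matrix(top, TOP_LABELS, "top")
  mid <- function(a, b) (a + b) / 2
  list(
    t10_fin_middle    = mid(top["fin-left", ],    top["fin-right", ]),
    s11_head_middle   = mid(side["head-up", ],    side["head-down", ]),
    s12_small_middle  = mid(side["small-up", ],   side["small-down", ]),
    t11_middle_middle = mid(top["middle-left", ], top["middle-right", ])
  )
}

#' Validate an annotated specimen
#'
#' Checks that all 19 landmarks are present and finite, that points lie
#' inside the declared image bounds (when bounds are given), that the
#' scale parameters are strictly positive, and that the canonical
#' head-left orientation holds (mouth at smaller x than the caudal-fin
#' base in both views).
#'
#' @param spec an [annotated_specimen()].
#' @return Character vector of findings; empty when the specimen is
#'   well formed. Findings never raise errors so that batch runs can
#'   report all problems at once.
#' @export
validate_annotation <- function(spec) {
  findings <- character()
  for (view in c("side", "top")) {
    pts <- spec[[view]]
    labels <- if (view == "side") SIDE_LABELS else TOP_LABELS
    for (lab in labels) {
      if (!lab %in% rownames(pts) || anyNA(pts[lab, ]) ||
          !all(is.finite(pts[lab, ]))) {
        findings <- c(findings, sprintf("%s view: landmark '%s' missing or non-finite",
                                        view, lab))
        next
      }
      bounds <- spec$image_size[[view]]
      if (!is.null(bounds)) {
        p <- pts[lab, ]
        if (p[1] < 0 || p[2] < 0 || p[1] > bounds[1] || p[2] > bounds[2])
          findings <- c(findings,
                        sprintf("%s view: landmark '%s' at (%.1f, %.1f) outside %d x %d image",
                                view, lab, p[1], p[2], bounds[1], bounds[2]))
      }
    }
  }
  sc <- spec$scales
  if (!all(is.finite(sc)) || any(sc <= 0))
    findings <- c(findings, "scale parameters must be strictly positive and finite")
  ok <- function(pts, a, b) all(is.finite(pts[c(a, b), ]))
  if (ok(spec$side, "side-head", "side-tail") &&
      spec$side["side-head", 1] > spec$side["side-tail", 1])
    findings <- c(findings, "side view: head right of tail (canonical orientation is head-left)")
  if (ok(spec$top, "top-head", "top-tail") &&
      spec$top["top-head", 1] > spec$top["top-tail", 1])
    findings <- c(findings, "top view: head right of tail (canonical orientation is head-left)")
  findings
}

flip_view_x <- function(pts, width = NULL) {
  w <- if (is.null(width)) max(pts[, 1]) + min(pts[, 1]) else width
  pts[, 1] <- w - pts[, 1]
  pts
}

#' Read and write specimen annotations as JSON
#'
#' The annotation schema is a versioned JSON object:
#' `{schema, specimen_id, image_size: {side: [w, h], top: [w, h]},
#' keypoints: {side: {label: [x, y], ...}, top: {...}},
#' scales: {side_cm_per_px, top_cm_per_px}, metadata}` with labels
#' exactly as in [SIDE_LABELS] and [TOP_LABELS]. Writing then reading a
#' specimen reproduces its coordinates bit-exactly (coordinates are
#' serialised at full precision). Annotations violating the canonical
#' head-left orientation are mirrored about the image width on read,
#' with a warning.
#'
#' @param path file path of the annotation JSON.
#' @param flip_to_canonical mirror non-canonical annotations on read
#'   (default `TRUE`); set `FALSE` to load verbatim.
#' @return [read_annotation()] returns an [annotated_specimen()];
#'   [write_annotation()] returns `path` invisibly.
#' @export
read_annotation <- function(path, flip_to_canonical = TRUE) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  kp <- function(view, labels) {
    raw <- obj$keypoints[[view]]
    if (is.null(raw)) stop("annotation lacks ", view, "-view keypoints", call. = FALSE)
    m <- do.call(rbind, lapply(raw, as.numeric))
    as_keypoint_matrix(m, labels, view)
  }
  side <- kp("side", SIDE_LABELS)
  top <- kp("top", TOP_LABELS)
  image_size <- lapply(obj$image_size, as.numeric)
  if (flip_to_canonical) {
    if (side["side-head", 1] > side["side-tail", 1]) {
      warning("annotation '", obj$specimen_id,
              "': side view head-right; mirroring to canonical head-left")
      side <- flip_view_x(side, image_size$side[1])
    }
    if (top["top-head", 1] > top["top-tail", 1]) {
      warning("annotation '", obj$specimen_id,
              "': top view head-right; mirroring to canonical head-left")
      top <- flip_view_x(top, image_size$top[1])
    }
  }
  scales <- scale_params(obj$scales$side_cm_per_px, obj$scales$top_cm_per_px)
  md <- obj$metadata
  annotated_specimen(obj$specimen_id, side, top, scales,
                     image_size = image_size,
                     metadata = if (is.null(md)) list() else as.list(md))
}

#' @param spec an [annotated_specimen()] to serialise.
#' @rdname read_annotation
#' @export
write_annotation <- function(spec, path) {
  stopifnot(inherits(spec, "annotated_specimen"))
  as_kp_list <- function(pts) {
    out <- lapply(seq_len(nrow(pts)), function(i) unname(pts[i, ]))
    names(out) <- rownames(pts)
    out
  }
  obj <- list(
    schema = "fishmetry-annotation/1",
    specimen_id = spec$specimen_id,
    image_size = spec$image_size,
    keypoints = list(side = as_kp_list(spec$side), top = as_kp_list(spec$top)),
    scales = list(side_cm_per_px = unname(spec$scales[["side"]]),
                  top_cm_per_px = unname(spec$scales[["top"]])),
    metadata = spec$metadata
  )
  # I(17) significant digits: lossless round trip for doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
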