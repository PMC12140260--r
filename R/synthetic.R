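#' Synthetic 3D fish specimens with known ground-truth phenotypes
#'
#' The generator builds a piecewise-linear 3D body centreline -- head
#' segment (mouth to head-middle), two mid-body segments meeting at the
#' caudal peduncle (head-middle to small-middle to caudal-fin base) and
#' a tail segment to the caudal-fin tip -- and hangs every landmark of
#' the two skeletons off it: height landmarks vertically, thickness and
#' fin landmarks laterally, the caudal fork behind the fin base. Body
#' curvature lives in the horizontal (top-view) plane with a common
#' bend magnitude across the mid-body segments, and the whole mid-body
#' shares one side-view inclination, so that the dual-view measurement
#' decomposition is exact for these specimens: projecting a noiseless
#' fish into the two views and measuring it recovers the 3D ground
#' truth to numerical precision. Ground-truth phenotypes are computed
#' from the exact 3D landmark coordinates by the same segment
#' decomposition the measurements use (chain of 3D chord lengths for
#' body length, shorter-fork tail term for full length), not from a
#' smooth-spline arc length, so the round trip tests the
#' implementation rather than the decomposition's approximation error
#' on arbitrary shapes.
#'
#' @name synthetic_fish
#' @keywords internal
NULL

#' Parameters of a synthetic fish
#'
#' Defaults describe a market-size channel catfish (about 14 cm total
#' length). All lengths in cm, angles in degrees.
#'
#' @param head_length_cm mouth to head-middle 3D length.
#' @param mid_length_cm head-middle to small-middle 3D length.
#' @param peduncle_length_cm small-middle to caudal-fin base 3D length.
#' @param tail_length_cm caudal-fin base to upper fin tip 3D length.
#' @param body_height_cm dorsoventral extent at the head-middle station.
#' @param thickness_cm lateral extent at the pectoral station.
#' @param tail_handle_height_cm dorsoventral extent at the peduncle.
#' @param mid_width_cm lateral extent at the ventral-fin station.
#' @param head_frac position of the rear gill point along the head
#'   segment, in (0, 1); head length ground truth is
#'   `head_frac * head_length_cm`.
#' @param anal_frac position of the anal-fin inflection along the
#'   mid-body segment, in (0, 1).
#' @param t11_frac position of the ventral-fin station along the
#'   mid-body segment, in (0, 1).
#' @param bend_deg common magnitude of the horizontal-plane bend of the
#'   two mid-body segments, in (-60, 60); `bend_signs` gives each
#'   segment's direction (S-curve by default).
#' @param bend_signs length-2 vector of +-1.
#' @param tail_yaw_deg horizontal-plane direction of the tail segment.
#' @param head_yaw_deg,head_pitch_deg direction of the head segment.
#' @param side_slope_deg shared side-view inclination of the mid-body
#'   and tail (vertical rise per horizontal run).
#' @param fork_overshoot_cm how much farther the lower caudal lobe
#'   projects onto the body axis than the upper one (keeps the
#'   shorter-lobe choice unambiguous).
#' @param fork_drop_cm perpendicular offset of the lower lobe.
#' @param pose_offset_cm length-3 world offset `c(x, y, z)` of the
#'   mouth.
#' @param vertical_bend_deg extra out-of-plane (vertical) bend applied
#'   to the rear mid-body segment. Non-zero values break the shared
#'   side-view inclination, so the measurement decomposition is no
#'   longer exact; off by default and excluded from exactness tests.
#' @return A list of class `fish_params`.
#' @export
fish_params <- function(head_length_cm = 3.2,
                        mid_length_cm = 7.0,
                        peduncle_length_cm = 1.1,
                        tail_length_cm = 2.9,
                        body_height_cm = 2.4,
                        thickness_cm = 2.1,
                        tail_handle_height_cm = 1.5,
                        mid_width_cm = 1.6,
                        head_frac = 0.85,
                        anal_frac = 0.93,
                        t11_frac = 0.5,
                        bend_deg = 12,
                        bend_signs = c(1, -1),
                        tail_yaw_deg = 18,
                        head_yaw_deg = 6,
                        head_pitch_deg = 4,
                        side_slope_deg = 4,
                        fork_overshoot_cm = 0.35,
                        fork_drop_cm = 0.7,
                        pose_offset_cm = c(2, 4, 0),
                        vertical_bend_deg = 0) {
  p <- as.list(environment())
  lens <- c(p$head_length_cm, p$mid_length_cm, p$peduncle_length_cm,
            p$tail_length_cm, p$body_height_cm, p$thickness_cm,
            p$tail_handle_height_cm, p$mid_width_cm)
  if (!all(is.finite(unlist(p[names(p) != "bend_signs"]))) || any(lens <= 0))
    stop("generation error: lengths must be finite and > 0", call. = FALSE)
  if (abs(p$bend_deg) >= 60 || abs(p$tail_yaw_deg) >= 60 ||
      abs(p$head_yaw_deg) >= 60)
    stop("generation error: horizontal-plane angles must lie in (-60, 60) degrees",
         call. = FALSE)
  if (p$head_frac <= 0 || p$head_frac >= 1 || p$anal_frac <= 0 ||
      p$anal_frac >= 1 || p$t11_frac <= 0 || p$t11_frac >= 1)
    stop("generation error: fractions must lie in (0, 1)", call. = FALSE)
  if (!all(abs(p$bend_signs) == 1) || length(p$bend_signs) != 2L)
    stop("generation error: bend_signs must be two values of +-1", call. = FALSE)
  class(p) <- "fish_params"
  p
}

#' Draw realistic random fish parameters
#'
#' Samples sizes and poses uniformly within the ranges seen across a
#' harvest cohort (total length roughly 11-17 cm) and random bend
#' directions, for property-style validation over many specimens.
#'
#' @param seed integer seed; each seed gives one reproducible parameter
#'   draw.
#' @return A [fish_params()] object.
#' @export
random_fish_params <- function(seed) {
  with_seed(seed, {
    size <- stats::runif(1, 0.8, 1.2)   # overall scale factor
    fish_params(
      head_length_cm = size * stats::runif(1, 2.8, 3.6),
      mid_length_cm = size * stats::runif(1, 6.0, 8.0),
      peduncle_length_cm = size * stats::runif(1, 0.9, 1.4),
      tail_length_cm = size * stats::runif(1, 2.4, 3.3),
      body_height_cm = size * stats::runif(1, 1.9, 2.9),
      thickness_cm = size * stats::runif(1, 1.6, 2.4),
      tail_handle_height_cm = size * stats::runif(1, 1.1, 1.9),
      mid_width_cm = size * stats::runif(1, 1.3, 1.9),
      head_frac = stats::runif(1, 0.75, 0.92),
      anal_frac = stats::runif(1, 0.88, 0.96),
      t11_frac = stats::runif(1, 0.4, 0.6),
      bend_deg = stats::runif(1, 0, 40),
      bend_signs = sample(c(-1, 1), 2, replace = TRUE),
      tail_yaw_deg = stats::runif(1, -35, 35),
      head_yaw_deg = stats::runif(1, -20, 20),
      head_pitch_deg = stats::runif(1, -8, 8),
      side_slope_deg = stats::runif(1, -8, 8),
      pose_offset_cm = c(stats::runif(1, 1, 3), stats::runif(1, 3, 5),
                         stats::runif(1, -1, 1))
    )
  })
}

d3 <- function(a, b) sqrt(sum((b - a)^2))

#' Generate a synthetic 3D specimen
#'
#' @param params a [fish_params()] object (see [random_fish_params()]
#'   for seeded random draws).
#' @return A list of class `fish_specimen_3d` with `landmarks3d` (19 x 3
#'   matrix of world coordinates in cm, rows named with [SIDE_LABELS]
#'   then [TOP_LABELS]; world axes: x longitudinal, y vertical, z
#'   lateral), `truth` (named numeric of the seven phenotypes in cm)
#'   and `params`.
#' @export
generate_fish <- function(params = fish_params()) {
  stopifnot(inherits(params, "fish_params"))
  p <- params
  deg <- pi / 180
  m <- tan(p$side_slope_deg * deg)        # shared side-view slope dy/dx

  # head segment: arbitrary 3D direction
  yh <- p$head_yaw_deg * deg; ph <- p$head_pitch_deg * deg
  dir_h <- c(cos(ph) * cos(yh), sin(ph), cos(ph) * sin(yh))
  mouth <- as.numeric(p$pose_offset_cm)
  head_mid <- mouth + p$head_length_cm * dir_h
  gill <- mouth + p$head_frac * p$head_length_cm * dir_h

  # mid-body segments: horizontal-plane bend, shared side-view slope
  mid_seg <- function(len, yaw_deg, extra_slope = 0) {
    th <- yaw_deg * deg
    mm <- m + tan(extra_slope * deg)
    h <- len / sqrt(1 + mm^2 * cos(th)^2)
    c(h * cos(th), mm * h * cos(th), h * sin(th))
  }
  v_u <- mid_seg(p$mid_length_cm, p$bend_deg * p$bend_signs[1])
  v_w <- mid_seg(p$peduncle_length_cm, p$bend_deg * p$bend_signs[2],
                 p$vertical_bend_deg)
  small_mid <- head_mid + v_u
  fin_base <- small_mid + v_w

  # tail segment: free horizontal direction, shared side-view slope
  v_t <- mid_seg(p$tail_length_cm, p$tail_yaw_deg)
  tip <- fin_base + v_t
  # lower caudal lobe: strictly longer axis projection, offset
  # perpendicular to the body axis in the side view
  a_side <- (head_mid - small_mid)[1:2]
  a_side <- a_side / sqrt(sum(a_side^2))
  n_side <- c(-a_side[2], a_side[1])
  lower <- fin_base + v_t * (1 + p$fork_overshoot_cm / p$tail_length_cm) +
    c(n_side * p$fork_drop_cm, 0)

  up <- c(0, -1, 0); right <- c(0, 0, 1)   # vertical and lateral offsets
  anal <- head_mid + p$anal_frac * v_u
  vent <- head_mid + p$t11_frac * v_u

  L <- rbind(
    "side-head"    = mouth,
    "head-fin"     = gill,
    "head-up"      = head_mid + up * p$body_height_cm / 2,
    "head-down"    = head_mid - up * p$body_height_cm / 2,
    "front-small"  = anal,
    "small-up"     = small_mid + up * p$tail_handle_height_cm / 2,
    "small-down"   = small_mid - up * p$tail_handle_height_cm / 2,
    "side-tail"    = fin_base,
    "tail-up"      = tip,
    "tail-down"    = lower,
    "top-head"     = mouth,
    "fin-right"    = head_mid + right * p$thickness_cm / 2,
    "fin-left"     = head_mid - right * p$thickness_cm / 2,
    "fin-up"       = head_mid,
    "middle-right" = vent + right * p$mid_width_cm / 2,
    "middle-left"  = vent - right * p$mid_width_cm / 2,
    "middle"       = small_mid,
    "small-tail"   = fin_base,
    "top-tail"     = tip
  )
  colnames(L) <- c("x", "y", "z")

  # ground truth by the measurement decomposition, applied to the
  # exact 3D coordinates
  BL <- d3(mouth, head_mid) + d3(head_mid, small_mid) + d3(small_mid, fin_base)
  truth <- c(
    FL  = BL + d3(fin_base, tip),
    BL  = BL,
    BH  = d3(L["head-up", ], L["head-down", ]),
    BT  = d3(L["fin-right", ], L["fin-left", ]),
    HL  = d3(mouth, gill),
    THH = d3(L["small-up", ], L["small-down", ]),
    THW = d3(anal, small_mid) + d3(small_mid, fin_base)
  )
  structure(list(landmarks3d = L, truth = truth, params = p),
            class = "fish_specimen_3d")
}

#' @export
print.fish_specimen_3d <- function(x, ...) {
  cat("<fish_specimen_3d> ground truth (cm):\n")
  print(round(x$truth, 3))
  invisible(x)
}

#' Orthographic camera for one view
#'
#' The side camera images the (x, y) world plane (longitudinal,
#' vertical), the top camera the (x, z) plane (longitudinal, lateral);
#' the shared longitudinal axis maps to image x in both views, depth is
#' dropped. Pixel coordinates are world coordinates times
#' `pixels_per_cm` plus a principal offset.
#'
#' @param view `"side"` or `"top"`.
#' @param pixels_per_cm imaging scale (> 0); the matching measurement
#'   scale parameter is `1 / pixels_per_cm` cm per pixel.
#' @param image_size `c(width, height)` in pixels.
#' @param offset principal offset `c(x, y)` in pixels.
#' @return A list of class `camera_model`.
#' @export
camera_model <- function(view = c("side", "top"), pixels_per_cm = 20,
                         image_size = c(512, 256), offset = c(0, 0)) {
  view <- match.arg(view)
  stopifnot(pixels_per_cm > 0, length(image_size) == 2L, length(offset) == 2L)
  structure(list(view = view, pixels_per_cm = pixels_per_cm,
                 image_size = as.numeric(image_size),
                 offset = as.numeric(offset)),
            class = "camera_model")
}

#' Cameras framing a given specimen
#'
#' Chooses a per-view scale and principal offset so that the whole
#' specimen fits the requested image with a margin.
#'
#' @param fish a [generate_fish()] specimen.
#' @param image_size `c(width, height)` in pixels, both views.
#' @param margin fraction of the image left free around the specimen.
#' @return List with `side` and `top` [camera_model()]s.
#' @export
default_cameras <- function(fish, image_size = c(512, 256), margin = 0.12) {
  one <- function(view) {
    ax <- if (view == "side") c(1, 2) else c(1, 3)
    pts <- fish$landmarks3d[, ax, drop = FALSE]
    span <- apply(pts, 2, function(v) diff(range(v)))
    avail <- image_size * (1 - 2 * margin)
    ppc <- min(avail / pmax(span, 1e-9))
    off <- image_size / 2 - ppc * (apply(pts, 2, min) + span / 2)
    camera_model(view, ppc, image_size, off)
  }
  list(side = one("side"), top = one("top"))
}

#' Project a 3D specimen into an annotated dual-view specimen
#'
#' Drops each view's depth axis, applies the camera scale and offset,
#' and attaches the matching scale parameters (`1 / pixels_per_cm` per
#' view). A warning reports landmarks falling outside the image bounds.
#'
#' @param fish a [generate_fish()] specimen.
#' @param camera_side,camera_top [camera_model()]s for the two views;
#'   by default framed with [default_cameras()].
#' @return An [annotated_specimen()].
#' @export
project_specimen <- function(fish, camera_side = NULL, camera_top = NULL) {
  stopifnot(inherits(fish, "fish_specimen_3d"))
  if (is.null(camera_side) || is.null(camera_top)) {
    cams <- default_cameras(fish)
    if (is.null(camera_side)) camera_side <- cams$side
    if (is.null(camera_top)) camera_top <- cams$top
  }
  proj <- function(cam, labels) {
    ax <- if (cam$view == "side") c(1, 2) else c(1, 3)
    pts <- fish$landmarks3d[labels, ax, drop = FALSE]
    px <- sweep(pts * cam$pixels_per_cm, 2, cam$offset, "+")
    colnames(px) <- c("x", "y")
    out_of_bounds <- px[, 1] < 0 | px[, 2] < 0 |
      px[, 1] > cam$image_size[1] | px[, 2] > cam$image_size[2]
    if (any(out_of_bounds))
      warning(cam$view, " view: landmark(s) outside image bounds: ",
              paste(labels[out_of_bounds], collapse = ", "))
    px
  }
  stopifnot(camera_side$view == "side", camera_top$view == "top")
  annotated_specimen(
    specimen_id = "synthetic",
    side = proj(camera_side, SIDE_LABELS),
    top = proj(camera_top, TOP_LABELS),
    scales = scale_params(1 / camera_side$pixels_per_cm,
                          1 / camera_top$pixels_per_cm),
    image_size = list(side = camera_side$image_size,
                      top = camera_top$image_size),
    metadata = list(source = "synthetic")
  )
}

#' Add Gaussian annotation noise to a specimen
#'
#' Models human labelling and detector localisation error: independent
#' Gaussian displacement of every keypoint coordinate in both views.
#'
#' @param spec an [annotated_specimen()].
#' @param sigma noise standard deviation in pixels (>= 0); 0 returns
#'   the specimen unchanged.
#' @param seed integer seed for reproducibility.
#' @return The perturbed [annotated_specimen()].
#' @export
perturb_specimen <- function(spec, sigma, seed) {
  stopifnot(inherits(spec, "annotated_specimen"), sigma >= 0)
  if (sigma == 0) return(spec)
  with_seed(seed, {
    spec$side <- spec$side + stats::rnorm(length(spec$side), 0, sigma)
    spec$top <- spec$top + stats::rnorm(length(spec$top), 0, sigma)
  })
  spec
}

# even-odd point-in-polygon test, vectorised over query points
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise one view of a specimen as a grayscale image
#'
#' Draws the filled body silhouette (a polygon through the outline
#' landmarks, dilated slightly so every landmark is strictly interior)
#' over a noisy background: a deterministic, texture-free training
#' substrate for the keypoint detector.
#'
#' @param fish a [generate_fish()] specimen.
#' @param camera a [camera_model()] for the view to render.
#' @param seed integer seed controlling the background noise.
#' @return Numeric matrix `height x width` with values in `[0, 1]`
#'   (row = image y, column = image x).
#' @export
rasterize_view <- function(fish, camera, seed = 1) {
  stopifnot(inherits(fish, "fish_specimen_3d"), inherits(camera, "camera_model"))
  labels <- if (camera$view == "side") {
    c("side-head", "head-up", "small-up", "tail-up",
      "tail-down", "small-down", "head-down")
  } else {
    c("top-head", "fin-right", "middle-right", "small-tail",
      "top-tail", "middle-left", "fin-left")
  }
  ax <- if (camera$view == "side") c(1, 2) else c(1, 3)
  pts <- sweep(fish$landmarks3d[labels, ax, drop = FALSE] * camera$pixels_per_cm,
               2, camera$offset, "+")
  if (camera$view == "side" && pts["tail-up", 2] > pts["tail-down", 2]) {
    # keep the outline simple when the caudal lobes cross vertically
    pts[c("tail-up", "tail-down"), ] <- pts[c("tail-down", "tail-up"), ]
  }
  ctr <- colMeans(pts)
  pts <- sweep(sweep(pts, 2, ctr) * 1.15, 2, ctr, "+")  # dilate outline
  w <- camera$image_size[1]; h <- camera$image_size[2]
  gx <- rep(seq_len(w) - 0.5, each = h)
  gy <- rep(seq_len(h) - 0.5, times = w)
  mask <- matrix(points_in_polygon(gx, gy, pts[, 1], pts[, 2]), nrow = h)
  # thin body regions (fin tips, caudal fork) can pinch the polygon;
  # stamp a small disk at every landmark so each is solidly foreground
  all_labels <- if (camera$view == "side") SIDE_LABELS else TOP_LABELS
  lm <- sweep(fish$landmarks3d[all_labels, ax, drop = FALSE] *
                camera$pixels_per_cm, 2, camera$offset, "+")
  for (i in seq_len(nrow(lm)))
    mask <- mask | matrix((gx - lm[i, 1])^2 + (gy - lm[i, 2])^2 <= 1.5^2,
                          nrow = h)
  with_seed(seed, {
    img <- matrix(0.15 + stats::rnorm(h * w, 0, 0.03), nrow = h)
    img[mask] <- 0.85 + stats::rnorm(sum(mask), 0, 0.03)
  })
  pmin(pmax(img, 0), 1)
}

# run an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
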