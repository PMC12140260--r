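test_that("generated specimens are reproducible and internally consistent", {
  a <- generate_fish(random_fish_params(42))
  b <- generate_fish(random_fish_params(42))
  expect_identical(a$landmarks3d, b$landmarks3d)
  expect_identical(a$truth, b$truth)

  fish <- generate_fish(fish_params())
  p <- fish$params
  expect_gte(fish$truth[["FL"]], fish$truth[["BL"]])
  expect_equal(fish$truth[["BL"]],
               p$head_length_cm + p$mid_length_cm + p$peduncle_length_cm,
               tolerance = 1e-12)
  expect_equal(fish$truth[["HL"]], p$head_frac * p$head_length_cm,
               tolerance = 1e-12)
  expect_equal(fish$truth[["BH"]], p$body_height_cm, tolerance = 1e-12)
  # derived midpoints are exact 3D midpoints of their parents
  L <- fish$landmarks3d
  expect_equal((L["small-up", ] + L["small-down", ]) / 2, L["middle", ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the tail term equals an independent 3D dot-product computation", {
  for (s in c(3, 8, 21)) {
    fish <- generate_fish(random_fish_params(s))
    L <- fish$landmarks3d
    tail_3d <- sqrt(sum((L["tail-up", ] - L["side-tail", ])^2))
    expect_equal(fish$truth[["FL"]] - fish$truth[["BL"]], tail_3d,
                 tolerance = 1e-9)
    # lower lobe projects strictly farther onto the body axis (3D check)
    axis <- L["head-up", ] / 2 + L["head-down", ] / 2 -
      (L["small-up", ] + L["small-down", ]) / 2
    axis_side <- axis[1:2] / sqrt(sum(axis[1:2]^2))
    p_up <- abs(sum((L["tail-up", 1:2] - L["side-tail", 1:2]) * axis_side))
    p_down <- abs(sum((L["tail-down", 1:2] - L["side-tail", 1:2]) * axis_side))
    expect_gt(p_down, p_up)
  }
})

test_that("a straight fish is coplanar per view with additive lengths", {
  p <- fish_params(bend_deg = 0, tail_yaw_deg = 0, head_yaw_deg = 0,
                   head_pitch_deg = 0, side_slope_deg = 0)
  fish <- generate_fish(p)
  L <- fish$landmarks3d
  centreline <- c("side-head", "head-fin", "front-small", "side-tail",
                  "tail-up", "middle", "small-tail")
  expect_true(all(abs(L[centreline, "z"] - L["side-head", "z"]) < 1e-12))
  expect_true(all(abs(L[centreline, "y"] - L["side-head", "y"]) < 1e-12))
  expect_equal(fish$truth[["BL"]],
               p$head_length_cm + p$mid_length_cm + p$peduncle_length_cm)
})

test_that("projection honours the camera model and scale cancels out", {
  fish <- generate_fish(fish_params())
  off <- c(5, 10)
  unit_side <- camera_model("side", 1, c(40, 40), off)
  unit_top <- camera_model("top", 1, c(40, 40), off)
  spec <- project_specimen(fish, unit_side, unit_top)
  expect_equal(unname(spec$side["side-head", ]),
               unname(fish$landmarks3d["side-head", c("x", "y")]) + off)
  expect_equal(unname(spec$top["top-tail", ]),
               unname(fish$landmarks3d["top-tail", c("x", "z")]) + off)

  big_side <- camera_model("side", 2, c(80, 80), off)
  big_top <- camera_model("top", 2, c(80, 80), off)
  spec2 <- project_specimen(fish, big_side, big_top)
  expect_equal(pt_dist(spec2$side["side-head", ], spec2$side["side-tail", ]),
               2 * pt_dist(spec$side["side-head", ], spec$side["side-tail", ]))
  expect_equal(unname(spec2$scales[["side"]]), 0.5)
  # measurement output is camera-scale invariant
  expect_equal(measure_specimen(spec2)[-1], measure_specimen(spec)[-1],
               tolerance = 1e-9)
})

test_that("ground truth is invariant to pose offset", {
  p1 <- fish_params(pose_offset_cm = c(0, 0, 0))
  p2 <- fish_params(pose_offset_cm = c(5, -2, 1.5))
  expect_equal(generate_fish(p1)$truth, generate_fish(p2)$truth,
               tolerance = 1e-12)
})

test_that("out-of-plane bending breaks exactness only when requested", {
  flat <- measure_specimen(project_specimen(generate_fish(fish_params())))
  fishv <- generate_fish(fish_params(vertical_bend_deg = 25))
  recv <- measure_specimen(project_specimen(fishv))
  rel <- abs(recv$BL - fishv$truth[["BL"]]) / fishv$truth[["BL"]]
  expect_gt(rel, 1e-6)   # decomposition is approximate off-plane
  expect_lt(rel, 0.05)   # but still close
  expect_true(is.finite(flat$BL))
})

test_that("perturbation is seeded, unbiased at sigma zero and folded-normal in size", {
  fish <- generate_fish(fish_params())
  spec <- project_specimen(fish)
  expect_identical(perturb_specimen(spec, 0, 1), spec)
  n1 <- perturb_specimen(spec, 2, 99)
  n2 <- perturb_specimen(spec, 2, 99)
  expect_identical(n1$side, n2$side)
  expect_false(identical(n1$side, spec$side))

  # mean keypoint displacement ~ sigma * sqrt(pi / 2) (Rayleigh mean)
  sigma <- 1.5
  disp <- unlist(lapply(1:600, function(r) {
    q <- perturb_specimen(spec, sigma, 10000 + r)
    sqrt(rowSums((q$side - spec$side)^2))
  }))
  expect_equal(mean(disp), sigma * sqrt(pi / 2), tolerance = 0.03)
})

test_that("rasterised views contain every landmark inside the silhouette", {
  fish <- generate_fish(random_fish_params(5))
  cams <- default_cameras(fish, image_size = c(64, 64))
  for (view in c("side", "top")) {
    img <- rasterize_view(fish, cams[[view]], seed = 5)
    expect_equal(dim(img), c(64, 64))
    expect_true(all(img >= 0 & img <= 1))
    spec <- project_specimen(fish, cams$side, cams$top)
    pts <- spec[[view]]
    vals <- img[cbind(pmin(pmax(ceiling(pts[, 2]), 1), 64),
                      pmin(pmax(ceiling(pts[, 1]), 1), 64))]
    expect_true(all(vals > 0.5))   # foreground intensity
  }
  expect_identical(rasterize_view(fish, cams$side, seed = 5),
                   rasterize_view(fish, cams$side, seed = 5))
})
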