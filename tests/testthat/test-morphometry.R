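test_that("planar traits are landmark distances times the view scale", {
  spec <- straight_specimen()
  expect_equal(body_thickness(spec), 1)   # 20 px * 0.05
  expect_equal(body_height(spec), 2)      # 20 px * 0.1
  expect_equal(tail_handle_height(spec), 1)
  # degenerate pair
  z <- spec; z$top["fin-left", ] <- z$top["fin-right", ]
  expect_equal(body_thickness(z), 0)
  # scale linearity
  spec2 <- straight_specimen(top_scale = 0.1)
  expect_equal(body_thickness(spec2), 2 * body_thickness(spec))
})

test_that("head length reconstructs through both views", {
  spec <- straight_specimen()
  expect_equal(head_length(spec), 2.8)    # both cosines 1
  tilted <- spec
  tilted$top["fin-right", ] <- c(30, 120)
  tilted$top["fin-left", ] <- c(30, 140)  # T10 = (30, 130), cos_beta = 1/sqrt(2)
  expect_equal(head_length(tilted), 2.8 * sqrt(2), tolerance = 1e-12)
})

test_that("straight axis-aligned fish measures to its hand-computed values", {
  spec <- straight_specimen()
  rec <- measure_specimen(spec)
  expect_equal(unlist(rec[names(straight_expected)]), straight_expected,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_gte(rec$FL, rec$BL)
})

test_that("a tilted top polyline strictly lengthens the body estimate", {
  spec <- straight_specimen()
  bent <- spec
  bent$top["middle", ] <- c(80, 125)   # middle segment off-axis
  expect_gt(body_length(bent), body_length(spec))
})

test_that("the shorter caudal lobe projection is used, ties keep equality", {
  spec <- straight_specimen()
  # upper lobe projects 15 px, lower 18 px -> min 15, cos_beta = 1
  expect_equal(full_length(spec) - body_length(spec), 1.5, tolerance = 1e-12)
  # mirror-symmetric fork: both choices agree
  sym <- spec
  sym$side["tail-up", ] <- c(115, 45)
  sym$side["tail-down", ] <- c(115, 55)
  f1 <- full_length(sym)
  sym2 <- sym
  sym2$side["tail-up", ] <- c(115, 55)
  sym2$side["tail-down", ] <- c(115, 45)
  expect_equal(full_length(sym2), f1)
})

test_that("tail-handle width sums the two axis projections", {
  spec <- straight_specimen()
  expect_equal(tail_handle_width(spec), 3)   # (10 + 20) px * 0.1
  z <- spec
  z$side["front-small", ] <- c(80, 50)
  z$side["side-tail", ] <- c(80, 50)
  z$side["small-up", ] <- c(80, 45); z$side["small-down", ] <- c(80, 55)
  expect_equal(tail_handle_width(z), 0)
})

test_that("measurements are translation-invariant and scale-linear", {
  spec <- straight_specimen()
  base <- measure_specimen(spec)
  shifted <- spec
  shifted$side <- sweep(shifted$side, 2, c(11, 3), "+")
  shifted$top <- sweep(shifted$top, 2, c(-4, 9), "+")
  shifted$image_size <- NULL
  expect_equal(measure_specimen(shifted)[-1], base[-1], tolerance = 1e-12)

  doubled <- spec
  doubled$scales <- scale_params(0.2, 0.05)
  rec <- measure_specimen(doubled)
  for (tr in c("FL", "BL", "BH", "HL", "THH", "THW"))
    expect_equal(rec[[tr]], 2 * base[[tr]], tolerance = 1e-12)
  expect_equal(rec$BT, base$BT)   # top-view trait untouched
})

test_that("dual-view reconstruction never shrinks below the planar value", {
  for (s in 1:20) {
    fish <- generate_fish(random_fish_params(s))
    spec <- project_specimen(fish)
    ss <- spec$scales[["side"]]
    mid <- derive_midpoints(spec)
    planar_bl <- (pt_dist(spec$side["side-head", ], mid$s11_head_middle) +
                  pt_dist(mid$s11_head_middle, mid$s12_small_middle) +
                  pt_dist(spec$side["side-tail", ], mid$s12_small_middle)) * ss
    expect_gte(body_length(spec), planar_bl - 1e-9)
    planar_hl <- pt_dist(spec$side["side-head", ], spec$side["head-fin", ]) * ss
    expect_gte(head_length(spec), planar_hl - 1e-9)
  }
})

test_that("noiseless synthetic fish are recovered to 1e-6 relative", {
  worst <- 0
  for (s in 1:100) {
    fish <- generate_fish(random_fish_params(s))
    rec <- measure_specimen(project_specimen(fish))
    rel <- max(abs(unlist(rec[-1]) - fish$truth) / fish$truth)
    worst <- max(worst, rel)
    expect_gte(rec$FL, rec$BL)
  }
  expect_lt(worst, 1e-6)
})

test_that("measurement error grows with annotation noise", {
  fish <- generate_fish(fish_params())
  cams <- default_cameras(fish, image_size = c(512, 256))
  clean <- project_specimen(fish, cams$side, cams$top)
  sigmas <- c(0, 1, 2, 4)
  med_err <- sapply(sigmas, function(sg) {
    errs <- sapply(1:200, function(r) {
      noisy <- perturb_specimen(clean, sg, seed = 7000 + r)  # paired noise draws
      rec <- measure_specimen(noisy)
      abs(unlist(rec[-1]) - fish$truth)
    })
    apply(errs, 1, stats::median)
  })
  # columns are sigma levels, rows traits: medians non-decreasing in sigma
  for (tr in seq_len(nrow(med_err)))
    expect_true(all(diff(med_err[tr, ]) >= -1e-9))
})

test_that("measurement failures name the offending trait", {
  spec <- straight_specimen()
  spec$top["small-tail", ] <- c(100, 100)
  spec$top["top-tail", ] <- c(100, 130)   # vertical tail in top view
  expect_error(measure_specimen(spec), "full_length")
})

test_that("measurement CSV rounds to the requested precision", {
  spec <- straight_specimen()
  spec$side["head-fin", ] <- c(28.123456, 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(measure_specimen(spec), path, digits = 3)
  back <- utils::read.csv(path)
  expect_equal(back$HL, round(head_length(spec), 3))
  expect_named(back, c("specimen_id", "FL", "BL", "BH", "BT", "HL", "THH", "THW"))
})
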