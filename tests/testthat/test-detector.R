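test_that("config validates the resolution relationship", {
  cfg <- detector_config(10, input_size = 64, heatmap_size = 16)
  expect_equal(cfg$upscale_factor, 4L)
  expect_error(detector_config(10, input_size = 60, heatmap_size = 16),
               "multiple")
  expect_error(detector_config(10, input_size = 48, heatmap_size = 16),
               "power of two")
  expect_error(detector_config(10, input_size = 64, heatmap_size = 8,
                               hourglass_order = 4), "divisible")
})

test_that("heatmap encoding puts unit peaks at the keypoints", {
  cfg <- detector_config(2, input_size = 64, heatmap_size = 16, sigma = 1.2)
  hm <- encode_heatmaps(rbind(c(32, 32), c(8, 56)), cfg)
  expect_equal(dim(hm), c(16, 16, 2))
  expect_equal(hm[9, 9, 1], 1)          # centre cell (0-based 8,8)
  expect_equal(max(hm[, , 2]), 1)
  # distant keypoints have disjoint strong-response regions
  expect_equal(sum(hm[, , 1] > 0.5 & hm[, , 2] > 0.5), 0)
  # interior bump mass approximates the Gaussian integral 2*pi*sigma^2
  expect_equal(sum(hm[, , 1]), 2 * pi * 1.2^2, tolerance = 0.01)
  expect_error(encode_heatmaps(rbind(c(-1, 5)), cfg), "bounds")
})

test_that("decoding is argmax times the upscale factor with row-major ties", {
  cfg <- detector_config(1, input_size = 2048, heatmap_size = 128,
                         hourglass_order = 2)
  expect_equal(cfg$upscale_factor, 16L)
  hm <- array(0, c(128, 128, 1))
  hm[21, 11, 1] <- 1          # 0-based heatmap position (x = 10, y = 20)
  expect_equal(unname(decode_heatmaps(hm, cfg)[1, ]), c(160, 320))
  # tie: equal maxima resolve to the lowest row-major index
  hm[21, 11, 1] <- 0.5
  hm[5, 40, 1] <- 0.5         # row 5 scans earlier
  hm[30, 2, 1] <- 0.5
  expect_equal(unname(decode_heatmaps(hm, cfg)[1, ]), c(39, 4) * 16)
  # degenerate map falls back to the image centre with a warning
  expect_warning(out <- decode_heatmaps(array(0, c(128, 128, 1)), cfg),
                 "degenerate")
  expect_equal(unname(out[1, ]), c(1024, 1024))
})

test_that("decode(encode(k)) displacement is bounded by the upscale factor", {
  cfg <- detector_config(1, input_size = 64, heatmap_size = 16, sigma = 1.5)
  set.seed(21)
  for (i in 1:200) {
    kp <- matrix(runif(2, 0, 64), 1)
    back <- decode_heatmaps(encode_heatmaps(kp, cfg), cfg)
    expect_true(all(abs(back - kp) <= cfg$upscale_factor))
  }
})

test_that("the model honours its shape contract across legal configs", {
  for (spec in list(list(K = 3, N = 32, n = 16, stacks = 2, order = 4),
                    list(K = 1, N = 8, n = 8, stacks = 1, order = 1),
                    list(K = 5, N = 32, n = 8, stacks = 3, order = 2))) {
    cfg <- detector_config(spec$K, input_size = spec$N, heatmap_size = spec$n,
                           num_stacks = spec$stacks, hourglass_order = spec$order,
                           channels = 4)
    model <- build_hourglass(cfg, seed = 2)
    img <- matrix(runif(spec$N^2), spec$N)
    hm <- predict_heatmaps(model, img)
    expect_equal(dim(hm), c(spec$n, spec$n, spec$K))
    kp <- suppressWarnings(detect_keypoints(model, img))
    expect_equal(nrow(kp), spec$K)
  }
})

test_that("parameter count grows strictly with hourglass order", {
  count <- function(order) {
    cfg <- detector_config(2, input_size = 32, heatmap_size = 32,
                           num_stacks = 1, hourglass_order = order, channels = 4)
    m <- build_hourglass(cfg, seed = 1)
    sum(vapply(m$params, function(p) length(p$W) + length(p$b), numeric(1)))
  }
  counts <- vapply(1:4, count, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- detector_config(2, input_size = 8, heatmap_size = 4,
                         num_stacks = 2, hourglass_order = 2, channels = 3,
                         sigma = 1)
  model <- build_hourglass(cfg, seed = 4)
  set.seed(9)
  img <- matrix(runif(64), 8)
  kp <- rbind(c(2.5, 3.5), c(6, 5))
  loss_of <- function(P) {
    fwd <- fishmetry:::model_fwd(P, cfg, fishmetry:::images_to_batch(list(img)), 1L)
    Tg <- fishmetry:::targets_to_batch(list(kp), cfg)
    mean(vapply(fwd$outs, function(o) sum((o - Tg)^2) / length(Tg), numeric(1)))
  }
  P <- model$params
  fwd <- fishmetry:::model_fwd(P, cfg, fishmetry:::images_to_batch(list(img)), 1L)
  Tg <- fishmetry:::targets_to_batch(list(kp), cfg)
  douts <- lapply(fwd$outs, function(o)
    2 * (o - Tg) / length(Tg) / cfg$num_stacks)
  grads <- fishmetry:::model_bwd(P, cfg, fwd, douts, 1L)
  eps <- 1e-6
  for (nm in c("stem0", "st1.hg.up", "st1.hg.mid.low", "st2.head",
               "st1.remap_out")) {
    for (pos in c(1L, length(P[[nm]]$W))) {
      Pp <- P; Pp[[nm]]$W[pos] <- Pp[[nm]]$W[pos] + eps
      Pm <- P; Pm[[nm]]$W[pos] <- Pm[[nm]]$W[pos] - eps
      numeric_grad <- (loss_of(Pp) - loss_of(Pm)) / (2 * eps)
      expect_equal(grads[[nm]]$W[pos], numeric_grad, tolerance = 1e-4,
                   label = paste("grad", nm, pos))
    }
  }
})

test_that("training is deterministic, inert at zero steps, and learns", {
  cfg <- detector_config(3, input_size = 16, heatmap_size = 8,
                         num_stacks = 1, hourglass_order = 1, channels = 4)
  model <- build_hourglass(cfg, seed = 7)
  set.seed(12)
  imgs <- lapply(1:4, function(i) matrix(runif(256), 16))
  kps <- lapply(1:4, function(i) matrix(runif(6, 2, 14), 3))

  zero <- train_detector(model, imgs, kps, steps = 0)
  expect_identical(zero$model$params, model$params)

  f1 <- train_detector(model, imgs, kps, steps = 10)
  f2 <- train_detector(model, imgs, kps, steps = 10)
  expect_identical(f1$loss, f2$loss)
  expect_lt(f1$loss[10], f1$loss[1])
})
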