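#' Stacked-hourglass keypoint detector
#'
#' A compact heatmap-regression detector in the stacked-hourglass
#' style: a convolutional stem pools the input down to heatmap
#' resolution, then a cascade of symmetric encoder-decoder (hourglass)
#' modules with skip connections at every scale refines per-keypoint
#' response maps, with intermediate supervision after every module.
#' Training minimises the mean squared error between predicted maps and
#' Gaussian ground-truth heatmaps with the Adam optimiser. Keypoints
#' are decoded by per-map argmax times the input/heatmap resolution
#' ratio (no sub-pixel refinement by default), which bounds the
#' quantisation error by half the upscale factor per axis.
#'
#' The network is implemented directly in R (im2col convolutions via
#' BLAS matrix products, hand-written backward passes), sized for CPU
#' experiments on small rasterised views rather than full-resolution
#' photographs; one model is trained per view.
#'
#' @name keypoint_detector
#' @keywords internal
NULL

#' Detector configuration
#'
#' @param num_keypoints maps to regress (10 for the side view, 9 top).
#' @param input_size square input resolution in pixels.
#' @param heatmap_size square heatmap resolution; must divide
#'   `input_size` with a power-of-two ratio (the upscale factor), and
#'   be divisible by `2^hourglass_order`.
#' @param sigma Gaussian bump standard deviation in heatmap pixels.
#' @param num_stacks number of hourglass modules (default 2).
#' @param hourglass_order nesting depth of each module (default 4).
#' @param channels feature channels throughout the trunk.
#' @param learning_rate Adam step size (default 1e-3).
#' @return A list of class `detector_config` with the derived
#'   `upscale_factor` field.
#' @export
detector_config <- function(num_keypoints, input_size = 64, heatmap_size = 16,
                            sigma = 1.5, num_stacks = 2, hourglass_order = 4,
                            channels = 8, learning_rate = 1e-3) {
  stopifnot(num_keypoints >= 1, input_size >= heatmap_size, heatmap_size >= 2)
  if (input_size %% heatmap_size != 0)
    stop("config error: input_size must be a multiple of heatmap_size",
         call. = FALSE)
  factor <- input_size %/% heatmap_size
  if (bitwAnd(factor, factor - 1L) != 0L)
    stop("config error: input/heatmap ratio must be a power of two",
         call. = FALSE)
  if (heatmap_size %% (2^hourglass_order) != 0)
    stop("config error: heatmap_size must be divisible by 2^hourglass_order",
         call. = FALSE)
  structure(list(num_keypoints = as.integer(num_keypoints),
                 input_size = as.integer(input_size),
                 heatmap_size = as.integer(heatmap_size),
                 sigma = sigma,
                 num_stacks = as.integer(num_stacks),
                 hourglass_order = as.integer(hourglass_order),
                 channels = as.integer(channels),
                 learning_rate = learning_rate,
                 upscale_factor = as.integer(factor)),
            class = "detector_config")
}

#' Encode keypoints as Gaussian ground-truth heatmaps
#'
#' Each keypoint at input-resolution position (x, y) becomes an
#' unnormalised Gaussian bump (peak value 1) centred at
#' (x, y) / upscale_factor on the heatmap grid (0-based cell
#' coordinates).
#'
#' @param keypoints numeric n x 2 matrix of (x, y) input-resolution
#'   pixel coordinates, inside `[0, input_size]`.
#' @param config a [detector_config()].
#' @return Array `heatmap_size x heatmap_size x n` (dims y, x, map).
#' @export
encode_heatmaps <- function(keypoints, config) {
  keypoints <- as.matrix(keypoints)
  stopifnot(ncol(keypoints) == 2L)
  if (any(!is.finite(keypoints)) || any(keypoints < 0) ||
      any(keypoints > config$input_size))
    stop("encode error: keypoint outside input bounds", call. = FALSE)
  n <- config$heatmap_size
  grid <- seq_len(n) - 1
  out <- array(0, c(n, n, nrow(keypoints)))
  for (k in seq_len(nrow(keypoints))) {
    cx <- keypoints[k, 1] / config$upscale_factor
    cy <- keypoints[k, 2] / config$upscale_factor
    out[, , k] <- exp(-(outer((grid - cy)^2, (grid - cx)^2, "+")) /
                        (2 * config$sigma^2))
  }
  out
}

#' Decode heatmaps to input-resolution keypoints
#'
#' Per-map argmax (ties resolve to the lowest row-major index) scaled
#' by the upscale factor. An all-zero or non-finite map decodes to the
#' input centre with a warning.
#'
#' @param stack heatmap array from [encode_heatmaps()] or a model
#'   forward pass.
#' @param config a [detector_config()].
#' @return Numeric n x 2 matrix of (x, y) input-resolution coordinates.
#' @export
decode_heatmaps <- function(stack, config) {
  n <- config$heatmap_size
  stopifnot(dim(stack)[1] == n, dim(stack)[2] == n)
  K <- dim(stack)[3]
  out <- matrix(NA_real_, K, 2, dimnames = list(NULL, c("x", "y")))
  for (k in seq_len(K)) {
    m <- stack[, , k]
    if (!any(is.finite(m)) || max(m, na.rm = TRUE) <= 0 ||
        !is.finite(max(m, na.rm = TRUE))) {
      warning("decode: degenerate heatmap for map ", k, "; using image centre")
      out[k, ] <- config$input_size / 2
      next
    }
    hits <- which(m == max(m), arr.ind = TRUE)
    # lowest row-major index: scan rows (y) first, then columns
    pick <- hits[order((hits[, 1] - 1) * n + (hits[, 2] - 1))[1], ]
    out[k, ] <- c(pick[2] - 1, pick[1] - 1) * config$upscale_factor
  }
  out
}

## ---- tensor primitives -----------------------------------------------
## Batched feature maps are stored as (B*H*W) x C matrices; within an
## image, pixels are column-major (y fastest), images are stacked in
## order. Index tables for im2col, pooling and upsampling are memoised
## per (H, W, B) shape.

.idx_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, B, k = 3L) {
  key <- paste("c", H, W, B, k, sep = "_")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  pad <- (k - 1L) %/% 2L
  HW <- H * W
  i_vec <- rep(rep(seq_len(H), times = W), times = B)
  j_vec <- rep(rep(seq_len(W), each = H), times = B)
  b_off <- rep((seq_len(B) - 1L) * HW, each = HW)
  idx <- matrix(1L, B * HW, k * k)
  o <- 0L
  for (dx in -pad:pad) for (dy in -pad:pad) {
    o <- o + 1L
    ii <- i_vec + dy; jj <- j_vec + dx
    valid <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    idx[valid, o] <- b_off[valid] + (jj[valid] - 1L) * H + ii[valid] + 1L
  }
  .idx_cache[[key]] <- idx
  idx
}

pool_idx <- function(H, W, B) {
  key <- paste("p", H, W, B, sep = "_")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  HW <- H * W
  i2 <- rep(rep(seq_len(H2), times = W2), times = B)
  j2 <- rep(rep(seq_len(W2), each = H2), times = B)
  b_off <- rep((seq_len(B) - 1L) * HW, each = H2 * W2)
  at <- function(di, dj) b_off + (2L * j2 - 2L + dj) * H + (2L * i2 - 1L + di)
  out <- list(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L))
  .idx_cache[[key]] <- out
  out
}

conv_fwd <- function(X, H, W, B, p, k = 3L) {
  if (k == 1L) {
    Y <- X %*% p$W
    Y <- sweep(Y, 2, p$b, "+")
    return(list(Y = Y, col = X))
  }
  idx <- im2col_idx(H, W, B, k)
  Xp <- rbind(0, X)
  col <- Xp[as.vector(idx), , drop = FALSE]
  dim(col) <- c(nrow(X), k * k * ncol(X))
  Y <- col %*% p$W
  Y <- sweep(Y, 2, p$b, "+")
  list(Y = Y, col = col)
}

conv_bwd <- function(dY, cache, H, W, B, p, k = 3L, cin) {
  g <- list(W = crossprod(cache$col, dY), b = colSums(dY))
  if (k == 1L) {
    return(list(dX = dY %*% t(p$W), grad = g))
  }
  idx <- im2col_idx(H, W, B, k)
  dcol <- dY %*% t(p$W)            # (BHW) x (k2*cin)
  k2 <- k * k
  dX <- matrix(0, nrow(dY), cin)
  for (o in seq_len(k2)) {
    rows <- idx[, o]
    sel <- rows > 1L
    block <- dcol[sel, (seq_len(cin) - 1L) * k2 + o, drop = FALSE]
    tgt <- rows[sel] - 1L
    dX[tgt, ] <- dX[tgt, ] + block
  }
  list(dX = dX, grad = g)
}

relu_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(Y = X, mask = mask)
}

pool_fwd <- function(X, H, W, B) {
  ix <- pool_idx(H, W, B)
  (X[ix[[1]], , drop = FALSE] + X[ix[[2]], , drop = FALSE] +
   X[ix[[3]], , drop = FALSE] + X[ix[[4]], , drop = FALSE]) / 4
}

pool_bwd <- function(dY, H, W, B) {
  ix <- pool_idx(H, W, B)
  dX <- matrix(0, B * H * W, ncol(dY))
  q <- dY / 4
  for (m in 1:4) dX[ix[[m]], ] <- dX[ix[[m]], ] + q
  dX
}

upsample_fwd <- function(X, H2, W2, B) {
  # H2, W2: output size (input is H2/2 x W2/2)
  ix <- pool_idx(H2, W2, B)
  out <- matrix(0, B * H2 * W2, ncol(X))
  for (m in 1:4) out[ix[[m]], ] <- X
  out
}

upsample_bwd <- function(dY, H2, W2, B) {
  ix <- pool_idx(H2, W2, B)
  dY[ix[[1]], , drop = FALSE] + dY[ix[[2]], , drop = FALSE] +
    dY[ix[[3]], , drop = FALSE] + dY[ix[[4]], , drop = FALSE]
}

## ---- parameter construction ------------------------------------------

conv_init <- function(k, cin, cout, gain = 1) {
  list(W = matrix(stats::rnorm(k * k * cin * cout,
                               sd = gain * sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout))
}

hg_param_names <- function(prefix, order) {
  own <- paste0(prefix, c(".up", ".low", ".out"))
  mid <- if (order > 1) hg_param_names(paste0(prefix, ".mid"), order - 1)
         else paste0(prefix, ".mid")
  c(own, mid)
}

#' Build an untrained stacked-hourglass model
#'
#' @param config a [detector_config()].
#' @param seed integer seed for weight initialisation.
#' @return A list of class `hourglass_model` with `params` (named list
#'   of convolution weights) and `config`.
#' @export
build_hourglass <- function(config, seed = 1) {
  stopifnot(inherits(config, "detector_config"))
  C <- config$channels; K <- config$num_keypoints
  pools <- as.integer(round(log2(config$upscale_factor)))
  with_seed(seed, {
    params <- list(stem0 = conv_init(3, 1, C))
    for (i in seq_len(pools))
      params[[paste0("pool", i)]] <- conv_init(3, C, C)
    for (s in seq_len(config$num_stacks)) {
      pfx <- paste0("st", s)
      for (nm in hg_param_names(paste0(pfx, ".hg"), config$hourglass_order))
        params[[nm]] <- conv_init(3, C, C)
      params[[paste0(pfx, ".feat")]] <- conv_init(3, C, C)
      params[[paste0(pfx, ".head")]] <- conv_init(1, C, K, gain = 0.1)
      if (s < config$num_stacks) {
        params[[paste0(pfx, ".remap_out")]] <- conv_init(1, K, C, gain = 0.1)
        params[[paste0(pfx, ".remap_feat")]] <- conv_init(1, C, C, gain = 0.1)
      }
    }
    structure(list(params = params, config = config), class = "hourglass_model")
  })
}

#' @export
print.hourglass_model <- function(x, ...) {
  n <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat("<hourglass_model> ", x$config$num_stacks, " stacks, order ",
      x$config$hourglass_order, ", ", n, " parameters\n", sep = "")
  invisible(x)
}

## ---- forward / backward ----------------------------------------------

hg_fwd <- function(X, H, W, B, pfx, order, P) {
  cache <- list()
  up_c <- conv_fwd(X, H, W, B, P[[paste0(pfx, ".up")]])
  up_r <- relu_fwd(up_c$Y)
  low_in <- pool_fwd(X, H, W, B)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  low_c <- conv_fwd(low_in, H2, W2, B, P[[paste0(pfx, ".low")]])
  low_r <- relu_fwd(low_c$Y)
  if (order > 1) {
    mid <- hg_fwd(low_r$Y, H2, W2, B, paste0(pfx, ".mid"), order - 1, P)
    mid_out <- mid$Y
  } else {
    mid_c <- conv_fwd(low_r$Y, H2, W2, B, P[[paste0(pfx, ".mid")]])
    mid_r <- relu_fwd(mid_c$Y)
    mid <- list(conv = mid_c, relu = mid_r)
    mid_out <- mid_r$Y
  }
  out_c <- conv_fwd(mid_out, H2, W2, B, P[[paste0(pfx, ".out")]])
  out_r <- relu_fwd(out_c$Y)
  Y <- up_r$Y + upsample_fwd(out_r$Y, H, W, B)
  list(Y = Y,
       cache = list(up_c = up_c, up_r = up_r, low_c = low_c, low_r = low_r,
                    mid = mid, out_c = out_c, out_r = out_r))
}

hg_bwd <- function(dY, cache, H, W, B, pfx, order, P, grads) {
  C <- ncol(dY)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  # skip branch
  d_up <- dY
  d_up[!cache$up_r$mask] <- 0
  r <- conv_bwd(d_up, cache$up_c, H, W, B, P[[paste0(pfx, ".up")]], 3L, C)
  grads[[paste0(pfx, ".up")]] <- r$grad
  dX <- r$dX
  # low branch
  d_out <- upsample_bwd(dY, H, W, B)
  d_out[!cache$out_r$mask] <- 0
  r <- conv_bwd(d_out, cache$out_c, H2, W2, B, P[[paste0(pfx, ".out")]], 3L, C)
  grads[[paste0(pfx, ".out")]] <- r$grad
  d_mid <- r$dX
  if (order > 1) {
    b <- hg_bwd(d_mid, cache$mid$cache, H2, W2, B, paste0(pfx, ".mid"),
                order - 1, P, grads)
    grads <- b$grads
    d_low <- b$dX
  } else {
    d_mid[!cache$mid$relu$mask] <- 0
    r <- conv_bwd(d_mid, cache$mid$conv, H2, W2, B,
                  P[[paste0(pfx, ".mid")]], 3L, C)
    grads[[paste0(pfx, ".mid")]] <- r$grad
    d_low <- r$dX
  }
  d_low[!cache$low_r$mask] <- 0
  r <- conv_bwd(d_low, cache$low_c, H2, W2, B, P[[paste0(pfx, ".low")]], 3L, C)
  grads[[paste0(pfx, ".low")]] <- r$grad
  dX <- dX + pool_bwd(r$dX, H, W, B)
  list(dX = dX, grads = grads)
}

model_fwd <- function(P, config, X, B) {
  N <- config$input_size; n <- config$heatmap_size
  pools <- as.integer(round(log2(config$upscale_factor)))
  cache <- list()
  c0 <- conv_fwd(X, N, N, B, P$stem0); r0 <- relu_fwd(c0$Y)
  cache$stem0 <- list(conv = c0, relu = r0)
  feat <- r0$Y
  H <- N
  for (i in seq_len(pools)) {
    pooled <- pool_fwd(feat, H, H, B)
    H <- H %/% 2L
    ci <- conv_fwd(pooled, H, H, B, P[[paste0("pool", i)]])
    ri <- relu_fwd(ci$Y)
    cache[[paste0("pool", i)]] <- list(conv = ci, relu = ri)
    feat <- ri$Y
  }
  outs <- vector("list", config$num_stacks)
  stacks <- vector("list", config$num_stacks)
  for (s in seq_len(config$num_stacks)) {
    pfx <- paste0("st", s)
    hg <- hg_fwd(feat, n, n, B, paste0(pfx, ".hg"), config$hourglass_order, P)
    fc <- conv_fwd(hg$Y, n, n, B, P[[paste0(pfx, ".feat")]])
    fr <- relu_fwd(fc$Y)
    head <- conv_fwd(fr$Y, n, n, B, P[[paste0(pfx, ".head")]], 1L)
    st <- list(hg = hg, fc = fc, fr = fr, head = head, inp = feat)
    outs[[s]] <- head$Y
    if (s < config$num_stacks) {
      ro <- conv_fwd(head$Y, n, n, B, P[[paste0(pfx, ".remap_out")]], 1L)
      rf <- conv_fwd(fr$Y, n, n, B, P[[paste0(pfx, ".remap_feat")]], 1L)
      st$ro <- ro; st$rf <- rf
      feat <- feat + ro$Y + rf$Y
    }
    stacks[[s]] <- st
  }
  list(outs = outs, cache = cache, stacks = stacks)
}

model_bwd <- function(P, config, fwd, douts, B) {
  n <- config$heatmap_size
  N <- config$input_size
  pools <- as.integer(round(log2(config$upscale_factor)))
  grads <- list()
  C <- config$channels; K <- config$num_keypoints
  d_feat <- NULL   # gradient flowing into the trunk feature after stack s
  for (s in rev(seq_len(config$num_stacks))) {
    pfx <- paste0("st", s)
    st <- fwd$stacks[[s]]
    d_head <- douts[[s]]
    if (s < config$num_stacks) {
      # d_feat currently holds gradient w.r.t. feat entering stack s+1
      r <- conv_bwd(d_feat, st$ro, n, n, B, P[[paste0(pfx, ".remap_out")]], 1L, K)
      grads[[paste0(pfx, ".remap_out")]] <- r$grad
      d_head <- d_head + r$dX
      r2 <- conv_bwd(d_feat, st$rf, n, n, B, P[[paste0(pfx, ".remap_feat")]], 1L, C)
      grads[[paste0(pfx, ".remap_feat")]] <- r2$grad
      d_fr <- r2$dX
    } else {
      d_fr <- matrix(0, B * n * n, C)
    }
    r <- conv_bwd(d_head, st$head, n, n, B, P[[paste0(pfx, ".head")]], 1L, C)
    grads[[paste0(pfx, ".head")]] <- r$grad
    d_fr <- d_fr + r$dX
    d_fr[!st$fr$mask] <- 0
    r <- conv_bwd(d_fr, st$fc, n, n, B, P[[paste0(pfx, ".feat")]], 3L, C)
    grads[[paste0(pfx, ".feat")]] <- r$grad
    b <- hg_bwd(r$dX, st$hg$cache, n, n, B, paste0(pfx, ".hg"),
                config$hourglass_order, P, grads)
    grads <- b$grads
    d_inp <- b$dX
    if (s < config$num_stacks) d_inp <- d_inp + d_feat  # identity path
    d_feat <- d_inp
  }
  # stem, in reverse
  H <- n
  for (i in rev(seq_len(pools))) {
    st <- fwd$cache[[paste0("pool", i)]]
    d_feat[!st$relu$mask] <- 0
    r <- conv_bwd(d_feat, st$conv, H, H, B, P[[paste0("pool", i)]], 3L, C)
    grads[[paste0("pool", i)]] <- r$grad
    H <- H * 2L
    d_feat <- pool_bwd(r$dX, H, H, B)
  }
  st <- fwd$cache$stem0
  d_feat[!st$relu$mask] <- 0
  r <- conv_bwd(d_feat, st$conv, N, N, B, P$stem0, 3L, 1L)
  grads$stem0 <- r$grad
  grads
}

## ---- training ---------------------------------------------------------

images_to_batch <- function(images) {
  matrix(unlist(lapply(images, as.vector), use.names = FALSE), ncol = 1)
}

targets_to_batch <- function(keypoint_list, config) {
  mats <- lapply(keypoint_list, function(kp) {
    hm <- encode_heatmaps(kp, config)
    matrix(hm, ncol = dim(hm)[3])
  })
  do.call(rbind, mats)
}

#' Train a detector on images with known keypoints
#'
#' Full-batch Adam on the summed-stack heatmap MSE. Deterministic given
#' the model (whose initialisation is seeded) and the data; the same
#' inputs reproduce the same loss trace bit for bit.
#'
#' @param model a [build_hourglass()] model.
#' @param images list of `input_size x input_size` numeric matrices.
#' @param keypoints list (same length) of n x 2 keypoint matrices in
#'   input-resolution pixels.
#' @param steps optimisation steps; 0 returns the model unchanged.
#' @param learning_rate Adam step size; defaults to the config value.
#' @return List with `model` (trained) and `loss` (per-step trace,
#'   averaged over stacks, images and pixels).
#' @export
train_detector <- function(model, images, keypoints, steps = 300,
                           learning_rate = NULL) {
  stopifnot(inherits(model, "hourglass_model"), length(images) >= 1,
            length(images) == length(keypoints))
  config <- model$config
  lr <- if (is.null(learning_rate)) config$learning_rate else learning_rate
  if (steps == 0) return(list(model = model, loss = numeric(0)))
  X <- images_to_batch(images)
  Tg <- targets_to_batch(keypoints, config)
  B <- length(images)
  P <- model$params
  mstate <- vstate <- lapply(P, function(p)
    list(W = array(0, dim(as.matrix(p$W))), b = numeric(length(p$b))))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  denom <- length(Tg)
  loss_trace <- numeric(steps)
  for (step in seq_len(steps)) {
    fwd <- model_fwd(P, config, X, B)
    douts <- vector("list", config$num_stacks)
    loss <- 0
    for (s in seq_len(config$num_stacks)) {
      diff <- fwd$outs[[s]] - Tg
      loss <- loss + sum(diff^2) / denom
      douts[[s]] <- 2 * diff / denom
    }
    loss <- loss / config$num_stacks
    for (s in seq_len(config$num_stacks))
      douts[[s]] <- douts[[s]] / config$num_stacks
    if (!is.finite(loss))
      stop("training error: loss diverged (non-finite) at step ", step,
           call. = FALSE)
    loss_trace[step] <- loss
    grads <- model_bwd(P, config, fwd, douts, B)
    bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
    for (nm in names(P)) {
      g <- grads[[nm]]
      for (f in c("W", "b")) {
        mstate[[nm]][[f]] <- beta1 * mstate[[nm]][[f]] + (1 - beta1) * g[[f]]
        vstate[[nm]][[f]] <- beta2 * vstate[[nm]][[f]] + (1 - beta2) * g[[f]]^2
        P[[nm]][[f]] <- P[[nm]][[f]] -
          lr * (mstate[[nm]][[f]] / bc1) /
            (sqrt(vstate[[nm]][[f]] / bc2) + eps)
      }
    }
  }
  model$params <- P
  list(model = model, loss = loss_trace)
}

#' Predicted heatmaps for one image
#'
#' @param model a (typically trained) [build_hourglass()] model.
#' @param image `input_size x input_size` numeric matrix.
#' @return Heatmap array from the final stack,
#'   `heatmap_size x heatmap_size x num_keypoints`.
#' @export
predict_heatmaps <- function(model, image) {
  config <- model$config
  fwd <- model_fwd(model$params, config, images_to_batch(list(image)), 1L)
  out <- fwd$outs[[config$num_stacks]]
  array(out, c(config$heatmap_size, config$heatmap_size, config$num_keypoints))
}

#' Detect keypoints on one image
#'
#' Runs the model and decodes the final stack's heatmaps by argmax.
#'
#' @inheritParams predict_heatmaps
#' @return n x 2 matrix of (x, y) input-resolution coordinates.
#' @export
detect_keypoints <- function(model, image) {
  decode_heatmaps(predict_heatmaps(model, image), model$config)
}
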