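# A straight, axis-aligned specimen whose seven measurements are
# hand-computable planar lengths times the scales: side scale 0.1,
# top scale 0.05.
straight_specimen <- function(side_scale = 0.1, top_scale = 0.05) {
  side <- rbind(
    "side-head"   = c(0, 50),
    "head-fin"    = c(28, 50),
    "head-up"     = c(30, 40),
    "head-down"   = c(30, 60),
    "front-small" = c(70, 60),
    "small-up"    = c(80, 45),
    "small-down"  = c(80, 55),
    "side-tail"   = c(100, 50),
    "tail-up"     = c(115, 45),
    "tail-down"   = c(118, 55)
  )
  top <- rbind(
    "top-head"     = c(0, 100),
    "fin-right"    = c(30, 90),
    "fin-left"     = c(30, 110),
    "fin-up"       = c(30, 95),
    "middle-right" = c(55, 95),
    "middle-left"  = c(55, 105),
    "middle"       = c(80, 100),
    "small-tail"   = c(100, 100),
    "top-tail"     = c(115, 100)
  )
  annotated_specimen("straight", side, top,
                     scale_params(side_scale, top_scale),
                     image_size = list(side = c(200, 120), top = c(200, 200)))
}

# hand-computed expectations for straight_specimen(0.1, 0.05)
straight_expected <- c(FL = 11.5, BL = 10, BH = 2, BT = 1, HL = 2.8,
                       THH = 1, THW = 3)

# 20 rasterised synthetic side views with projected keypoints, the
# detector's overfit training set
detector_training_set <- function(n = 20, image_px = 64) {
  images <- vector("list", n); kps <- vector("list", n)
  for (i in seq_len(n)) {
    fish <- generate_fish(random_fish_params(i))
    cams <- default_cameras(fish, image_size = c(image_px, image_px))
    spec <- project_specimen(fish, cams$side, cams$top)
    images[[i]] <- rasterize_view(fish, cams$side, seed = i)
    kps[[i]] <- unname(spec$side)
  }
  list(images = images, keypoints = kps)
}
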