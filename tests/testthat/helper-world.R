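# Shared fixtures: synthetic tubes with exact geometry, a reduced "small
# world" (192 px canvas/analysis frame) for fast end-to-end runs, and one
# cached desk-scale U-Net trained once per test run.

# Straight tube of width `w` at orientation `theta_deg` through a generic
# (non-lattice) center; returns the exact-rule mask and the geometry.
# The generic sub-pixel offset avoids phase-locked rasterization
# degeneracies (a centerline through exact half-integer lattice positions
# makes the closed-boundary mask a biased representation of the width).
tube_fixture <- function(theta_deg, w, S = 300, len = 120) {
  th <- theta_deg * pi / 180
  ctr <- c((S + 1) / 2 + 0.23, (S + 1) / 2 - 0.41)
  d <- c(sin(th), cos(th))
  acc <- matrix(Inf, S, S)
  acc <- retvas:::polyline_distance_update(acc, rbind(ctr - len * d, ctr + len * d),
                                           w / 2 + 2)
  list(mask = matrix(as.integer(acc <= w / 2), S), ctr = ctr, dir = d,
       width = w)
}

small_scene_cfg <- function(...) {
  scene_config(canvas_px = 192L, disc_diameter_px = 40,
               arteriole_width_range = c(5, 7.5),
               venule_width_range = c(7, 9.5), ...)
}

small_pre_cfg <- function() preprocess_config(analysis_px = 192L)

# One desk-scale model trained on the small world, cached for the whole
# test run (training takes a couple of minutes on one CPU).
.tv_cache <- new.env(parent = emptyenv())

cached_small_model <- function() {
  if (!is.null(.tv_cache$model)) return(.tv_cache$model)
  ts <- synthetic_training_set(8, seed = 100, config = small_scene_cfg(),
                               pre_config = small_pre_cfg())
  m <- build_unet(unet_spec(base_channels = 8L), seed = 5)
  m <- unet_train(m, ts, n_patches = 2000L, epochs = 4L, seed = 42)
  .tv_cache$model <- m
  m
}

# render a small-world scene and push it through preprocessing
small_world_frame <- function(scene) {
  out <- render(scene)
  sq <- structure(list(pixels = out$image, side_px = scene$canvas_px,
                       field_mm = scene$field_mm,
                       pixel_scale_mm = scene$field_mm / scene$canvas_px),
                  class = "square_fundus")
  list(pre = preprocess_fundus(sq, small_pre_cfg()), truth = out$truth,
       image = out$image)
}

dice_coef <- function(a, b) 2 * sum(a == 1 & b == 1) / (sum(a) + sum(b))
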