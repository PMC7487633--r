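# Image-conditioning chain: crop arithmetic, grayscale weights, CLAHE
# behaviour, stretch/gamma mapping, border mean filtering, and the stage
# invariants (shape preservation, [0,1] range, determinism).

test_that("square crop removes symmetric black bands and calibrates scale", {
  frame <- array(seq_len(1024 * 720 * 3) %% 251, c(1024, 720, 3))
  sq <- crop_to_square(frame)
  expect_equal(dim(sq$pixels), c(720, 720, 3))
  # slicing oracle: rows 153..872 (152 removed top, 152 bottom)
  expect_identical(sq$pixels, frame[153:872, , , drop = FALSE])
  expect_equal(sq$pixel_scale_mm, 7 / 720)
  expect_equal(sq$pixel_scale_mm, 0.009722, tolerance = 1e-4)

  sq2 <- crop_to_square(array(1, c(600, 600, 3)))
  expect_equal(dim(sq2$pixels), c(600, 600, 3))

  expect_error(crop_to_square(array(1, c(600, 800, 3))), "landscape")
})

test_that("grayscale conversion uses the 0.299/0.587/0.114 weights", {
  cfg <- preprocess_config()
  expect_equal(cfg$gray_weights, c(0.299, 0.587, 0.114))
  white <- crop_to_square(array(255, c(700, 700, 3)))
  g <- to_analysis_gray(white, cfg)
  expect_equal(dim(g), c(565, 565))
  expect_true(all(abs(g - 1) < 1e-12))

  const <- crop_to_square(array(rep(c(100, 150, 200), each = 700 * 700),
                                c(700, 700, 3)))
  g2 <- to_analysis_gray(const, cfg)
  expect_equal(unclass(g2)[300, 300], 140.75 / 255, tolerance = 1e-12)
  expect_true(all(abs(g2 - 140.75 / 255) < 1e-9))

  expect_error(preprocess_config(gray_weights = c(0.3, 0.6, 0.2)), "sum to 1")
})

test_that("CLAHE is deterministic, range-preserving and flat-field neutral", {
  cfg <- preprocess_config()
  flat <- retvas:::new_analysis_image(matrix(0.37, 565, 565), "gray")
  out <- clahe_enhance(flat, cfg)
  expect_true(all(out == 0.37))         # constant image has nothing to equalize
  set.seed(11)
  img <- retvas:::new_analysis_image(
    retvas:::box_mean(matrix(runif(565^2), 565), 11), "gray")
  o1 <- clahe_enhance(img, cfg)
  o2 <- clahe_enhance(img, cfg)
  expect_identical(unclass(o1), unclass(o2))
  expect_true(all(o1 >= 0 & o1 <= 1))
  expect_equal(dim(o1), dim(img))
})

test_that("stretch/gamma maps quantile limits onto [0,1] with gamma 0.6", {
  cfg <- preprocess_config()
  expect_equal(cfg$gamma, 0.6)
  x <- retvas:::new_analysis_image(matrix(seq(0, 1, length.out = 100), 10),
                                   "clahe")
  x[1] <- 0.5   # ensure the worked-example input value is present exactly
  out <- stretch_gamma(x, cfg, limits = c(0.2, 0.8))
  expect_equal(unclass(out)[abs(x - 0.5) < 1e-9][1], 0.5^0.6,
               tolerance = 1e-12)
  expect_equal((0.3 / 0.6)^0.6, 0.6598, tolerance = 1e-4)
  expect_true(all(unclass(out)[x <= 0.2] == 0))
  expect_true(all(unclass(out)[x >= 0.8] == 1))
  # monotone non-decreasing in input intensity
  set.seed(2)
  v <- sort(runif(300))
  mv <- stretch_gamma(retvas:::new_analysis_image(matrix(v, 10), "clahe"), cfg)
  expect_true(all(diff(as.vector(unclass(mv))[order(v)]) >= 0))

  expect_warning(res <- stretch_gamma(
    retvas:::new_analysis_image(matrix(0.4, 8, 8), "clahe"), cfg),
    "degenerate")
  expect_true(all(res == 0))
})

test_that("mean filter is an 11x11 replicate-boundary average on the border band", {
  cfg <- preprocess_config()
  expect_equal(cfg$mean_filter_size, 11L)
  expect_identical(cfg$boundary, "replicate")
  const <- retvas:::new_analysis_image(matrix(0.62, 100, 100), "adjusted")
  out <- mean_filter(const, cfg)
  expect_true(all(abs(out - 0.62) < 1e-12))   # including every border pixel

  # impulse response under global filtering: an 11x11 block of 1/121
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  g <- mean_filter(retvas:::new_analysis_image(imp, "adjusted"), cfg,
                   band = Inf)
  expect_equal(sum(g > 0), 121)
  expect_true(all(abs(unclass(g)[16:26, 16:26] - 1 / 121) < 1e-12))

  # direct-convolution oracle with replicate padding, random image
  set.seed(3)
  x <- matrix(runif(30 * 30), 30)
  ref <- matrix(0, 30, 30)
  for (r in 1:30) for (c in 1:30) {
    rr <- pmin(pmax(r + (-5:5), 1), 30)
    cc <- pmin(pmax(c + (-5:5), 1), 30)
    ref[r, c] <- mean(x[rr, cc])
  }
  got <- retvas:::box_mean(x, 11)
  expect_lt(max(abs(got - ref)), 1e-9)

  # border-band blending leaves the interior untouched
  set.seed(4)
  y <- matrix(runif(100 * 100), 100)
  fb <- mean_filter(retvas:::new_analysis_image(y, "adjusted"), cfg, band = 11)
  expect_identical(unclass(fb)[20:80, 20:80], y[20:80, 20:80])
  expect_false(identical(unclass(fb)[1, ], y[1, ]))
})

test_that("every stage preserves shape and the [0,1] range deterministically", {
  sc <- generate_scene(6, small_scene_cfg())
  fr <- small_world_frame(sc)
  stages <- fr$pre[c("gray", "clahe", "adjusted", "filtered")]
  for (st in stages) {
    expect_equal(dim(st), c(192, 192))
    expect_true(all(st >= 0 & st <= 1))
  }
  fr2 <- small_world_frame(sc)
  expect_identical(unclass(fr$pre$filtered), unclass(fr2$pre$filtered))
  expect_equal(fr$pre$pixel_scale_mm, 7 / 192)
})
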