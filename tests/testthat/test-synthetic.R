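# Synthetic fundus generator: determinism, geometry invariants, exact
# ground-truth accounting, and repeat-acquisition semantics.

test_that("scene generation is deterministic and validates its parameters", {
  cfg <- scene_config()
  s1 <- generate_scene(1, cfg)
  s2 <- generate_scene(1, cfg)
  expect_identical(s1, s2)
  s3 <- generate_scene(2, cfg)
  expect_false(identical(s1$branches, s3$branches))

  expect_error(scene_config(n_venules = 0), "at least one")
  expect_error(scene_config(arteriole_width_range = c(0.5, 2)), "widths")
  expect_error(scene_config(canvas_px = -1), "canvas_px")
  expect_error(scene_config(disc_center = c(10, 10)), "outside")
})

test_that("all centerline vertices lie inside the inscribed circular field", {
  cfg <- scene_config(n_arterioles = 3, n_venules = 3)
  sc <- generate_scene(1, cfg)
  ctr <- (cfg$canvas_px + 1) / 2
  for (b in sc$branches) {
    rad <- sqrt((b$centerline[, 1] - ctr)^2 + (b$centerline[, 2] - ctr)^2)
    expect_true(all(rad <= cfg$canvas_px / 2))
  }
  # at least one arteriole and one venule cross the measurement annulus
  in_ann <- retvas:::branches_in_annulus(sc)
  labs <- vapply(sc$branches, `[[`, "", "label")
  expect_true(any(in_ann & labs == "arteriole"))
  expect_true(any(in_ann & labs == "venule"))
  # child branches are never wider than their parent
  for (i in seq_along(sc$branches)) {
    p <- sc$branches[[i]]$parent
    if (!is.na(p)) {
      expect_lte(sc$branches[[i]]$width_px, sc$branches[[p]]$width_px)
    }
  }
})

test_that("rendered mask obeys the hard geometric rule and density is exact", {
  # single straight horizontal tube, width 9 px, length 300 px, 720 canvas
  scene <- structure(list(
    seed = 0L, config = scene_config(), canvas_px = 720L, field_mm = 7,
    disc = list(center = c(360, 300), diameter_px = 150),
    branches = list(list(label = "venule",
                         centerline = rbind(c(360.3, 210.2), c(360.3, 510.2)),
                         width_px = 9, parent = NA_integer_)),
    background_level = 0.55, noise_sd = 0, vignette_strength = 0),
    class = "fundus_scene")
  out <- render(scene)
  # brute-force oracle: per-pixel distance to the segment
  RR <- matrix(seq_len(720), 720, 720)
  CC <- matrix(seq_len(720), 720, 720, byrow = TRUE)
  t <- pmin(pmax((CC - 210.2) / 300, 0), 1)
  dist <- sqrt((RR - 360.3)^2 + (CC - (210.2 + t * 300))^2)
  oracle_mask <- (dist <= 4.5) + 0L
  expect_identical(unname(out$truth$mask), unname(oracle_mask))
  expect_equal(out$truth$density_true, 100 * sum(oracle_mask) / 720^2)
  # nominal capsule area (9 x 300 rectangle plus two half-disc end caps)
  # within half a percent relative of the raster count
  expect_equal(out$truth$density_true,
               100 * (9 * 300 + pi * 4.5^2) / 720^2, tolerance = 5e-3)

  # no-noise, no-vignette limit: green channel background pixels are exactly
  # background_level (away from the disc, vessels and the field border)
  ctr <- (720 + 1) / 2
  rad <- sqrt((RR - ctr)^2 + (CC - ctr)^2)
  dd <- sqrt((RR - 360)^2 + (CC - 300)^2)
  bg <- rad < 355 & dd > 80 & dist > 8
  expect_true(all(out$image[, , 2][bg] == 0.55))
})

test_that("stored ground truth is self-consistent across seeds", {
  cfg <- scene_config()
  for (s in 1:3) {
    sc <- generate_scene(s, cfg)
    out <- render(sc)
    tr <- out$truth
    expect_equal(tr$density_true, 100 * sum(tr$mask) / length(tr$mask))
    pair <- tr$measured_pair
    expect_equal(tr$av_ratio_true,
                 tr$widths_px[pair["arteriole"]] / tr$widths_px[pair["venule"]])
    expect_true(tr$av_ratio_true > 0)
  }
})

test_that("perpendicular chords through the truth mask match branch widths", {
  sc <- generate_scene(4, scene_config())
  out <- render(sc)
  m <- out$truth$mask
  storage.mode(m) <- "double"
  for (bi in 1:2) {
    b <- sc$branches[[bi]]
    pts <- retvas:::densify_polyline(b$centerline, 1)
    k <- round(nrow(pts) / 2) + 0:2   # interior samples
    for (j in k) {
      d <- pts[min(j + 3, nrow(pts)), ] - pts[max(j - 3, 1), ]
      d <- d / sqrt(sum(d^2))
      w <- retvas:::chord_width(m, pts[j, ], c(-d[2], d[1]), 20)
      expect_lt(abs(w - b$width_px), 1)
    }
  }
})

test_that("repeat pairs emulate two acquisitions of one anatomy", {
  sc <- generate_scene(3, scene_config(noise_sd = 0.02))
  # identity jitter with a shared noise seed reproduces the image exactly
  p0 <- make_repeat_pair(sc, jitter = list(noise_seed_offsets = c(1L, 1L)),
                         seed = 9)
  expect_identical(p0$image1, p0$image2)
  # different noise seeds: same anatomy, difference is pure noise
  p1 <- make_repeat_pair(sc, jitter = list(noise_seed_offsets = c(1L, 2L)),
                         seed = 9)
  expect_identical(p1$truth1$mask, p1$truth2$mask)
  dmask <- p1$image1[, , 2][p1$truth1$mask == 1] -
    p1$image2[, , 2][p1$truth2$mask == 1]
  expect_lt(abs(mean(dmask)), 3 * sc$noise_sd)
  # pure translation shifts the truth centerlines exactly
  p2 <- make_repeat_pair(sc, jitter = list(translate_px = c(2, 0)), seed = 9)
  for (i in seq_along(p2$truth1$centerlines)) {
    expect_equal(unname(p2$truth2$centerlines[[i]]),
                 unname(sweep(p2$truth1$centerlines[[i]], 2, c(2, 0), `+`)),
                 tolerance = 1e-12)
  }
  # jitter that pushes the disc out of the field is rejected
  expect_error(make_repeat_pair(sc, jitter = list(translate_px = c(400, 0))),
               "outside")
})
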