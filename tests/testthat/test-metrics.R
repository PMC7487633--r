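# Vessel metrics: exact density accounting, the measurement annulus
# convention, centerline extraction, the five-measurement caliber protocol
# and A/V ratio arithmetic.

test_that("vessel density is exact integer arithmetic", {
  empty <- matrix(0L, 565, 565)
  expect_equal(vessel_density(empty)$density_percent, 0)
  full <- matrix(1L, 100, 100)
  expect_equal(vessel_density(full)$density_percent, 100)
  m <- matrix(0L, 565, 565); m[seq_len(20000)] <- 1L
  d <- vessel_density(m)
  expect_equal(d$vessel_px, 20000)
  expect_equal(d$density_percent, 100 * 20000 / 319225)
  expect_equal(d$density_percent, 6.2652, tolerance = 1e-4)
  expect_error(vessel_density(matrix(c(0, 2), 2)), "binary")
  # recount oracle on random masks
  set.seed(10)
  for (i in 1:5) {
    rm <- matrix(rbinom(2500, 1, runif(1, 0.05, 0.5)), 50)
    expect_identical(vessel_density(rm)$density_percent,
                     100 * sum(rm == 1) / 2500)
  }
})

test_that("the measurement annulus spans 0.5 to 1 disc diameter from the margin", {
  disc <- disc_geometry(c(200, 200), 100)
  ann <- annulus_from_disc(disc)
  expect_equal(ann$inner_radius_px, 100)
  expect_equal(ann$outer_radius_px, 150)
  expect_false(retvas:::in_annulus(ann, 200, 200 + 99))   # inside the gap
  expect_true(retvas:::in_annulus(ann, 200, 200 + 100))   # closed inner edge
  expect_true(retvas:::in_annulus(ann, 200, 200 + 150))   # closed outer edge
  expect_false(retvas:::in_annulus(ann, 200, 200 + 151))
  expect_warning(annulus_from_disc(disc, image_side = 300), "clipped")
})

test_that("centerline extraction follows the tube axis deterministically", {
  tm <- tube_fixture(30, 9)
  cl <- extract_centerline(tm$mask, retvas:::snap_to_vessel(tm$mask, tm$ctr))
  expect_gt(nrow(cl), 100)
  # every skeleton point within 1 px of the true axis
  n <- c(-tm$dir[2], tm$dir[1])
  offaxis <- abs((cl[, 1] - tm$ctr[1]) * n[1] + (cl[, 2] - tm$ctr[2]) * n[2])
  expect_lt(max(offaxis), 1)
  cl2 <- extract_centerline(tm$mask, retvas:::snap_to_vessel(tm$mask, tm$ctr))
  expect_identical(cl, cl2)
  # a single isolated pixel is degenerate and flagged
  single <- matrix(0L, 20, 20); single[10, 10] <- 1L
  cs <- extract_centerline(single, c(10, 10))
  expect_equal(nrow(cs), 1)
  expect_true(isTRUE(attr(cs, "unmeasurable")))
  expect_error(extract_centerline(single, c(5, 5)), "not on a vessel")
})

test_that("caliber sites respect the annulus and spacing constraints", {
  # tube crossing an annulus around a central disc
  S <- 300
  acc <- matrix(Inf, S, S)
  acc <- retvas:::polyline_distance_update(
    acc, rbind(c(150.3, 10), c(150.3, 290)), 5)
  mask <- matrix(as.integer(acc <= 3), S)
  disc <- disc_geometry(c(150, 150), 60)
  ann <- annulus_from_disc(disc)
  cl <- extract_centerline(mask, retvas:::snap_to_vessel(mask, c(150, 230)),
                           ann)
  cs <- measure_caliber(mask, cl, ann, vessel_label = "venule")
  expect_length(cs$widths_px, 5)
  expect_true(all(retvas:::in_annulus(ann, cs$sites[, 1], cs$sites[, 2])))
  gaps <- as.vector(dist(cs$sites))
  expect_true(all(gaps >= max(mean(cs$widths_px), 5) - 1e-9))
  expect_equal(cs$width_mean_px, 6, tolerance = 0.5)
  # physical conversion: px -> um via the pixel scale
  expect_equal(cs$width_mean_um, cs$width_mean_px * (7 / 720) * 1000)
  # an annulus the tube misses entirely is a measurement error
  far <- annulus_from_disc(disc_geometry(c(40, 40), 20))
  expect_error(extract_centerline(mask,
                                  retvas:::snap_to_vessel(mask, c(150, 230)),
                                  far),
               "no skeleton")
})

test_that("A/V ratio arithmetic and end-to-end recovery", {
  art <- structure(list(vessel_label = "arteriole", widths_px = rep(10, 5),
                        width_mean_px = 10, width_mean_um = 10 * 7 / 720 * 1e3,
                        sites = matrix(0, 5, 2)), class = "caliber_set")
  ven <- structure(list(vessel_label = "venule", widths_px = rep(13, 5),
                        width_mean_px = 13, width_mean_um = 13 * 7 / 720 * 1e3,
                        sites = matrix(0, 5, 2)), class = "caliber_set")
  expect_equal(av_ratio(art, ven)$av_ratio, 10 / 13)
  expect_equal(av_ratio(art, art)$av_ratio, 1)
  expect_equal(10 / 13, 0.7692, tolerance = 1e-4)
  # ground-truth recovery on two seeded scenes (the 20-scene sweep is part
  # of the acceptance suite)
  for (s in c(2, 3)) {
    sc <- generate_scene(s, scene_config())
    out <- render(sc)
    annot <- truth_annotation(out$truth, from_side = 720)
    av <- measure_av(out$truth$mask, annot)
    expect_equal(av$av_ratio, out$truth$av_ratio_true, tolerance = 0.05)
  }
})

test_that("the A/V ratio is invariant under uniform rescaling", {
  sc <- generate_scene(5, scene_config())
  out <- render(sc)
  annot <- truth_annotation(out$truth, from_side = 720)
  av1 <- measure_av(out$truth$mask, annot)
  # exact 2x scene: double every geometric quantity and re-render
  sc2 <- sc
  sc2$canvas_px <- sc$canvas_px * 2L
  sc2$config$canvas_px <- sc2$canvas_px
  sc2$disc$center <- (sc$disc$center - 0.5) * 2 + 0.5
  sc2$disc$diameter_px <- sc$disc$diameter_px * 2
  sc2$branches <- lapply(sc$branches, function(b) {
    b$centerline <- (b$centerline - 0.5) * 2 + 0.5
    b$width_px <- b$width_px * 2
    b
  })
  out2 <- render(sc2)
  annot2 <- truth_annotation(out2$truth, from_side = 1440)
  av2 <- measure_av(out2$truth$mask, annot2, pixel_scale_mm = 7 / 1440)
  expect_lt(abs(av2$av_ratio - av1$av_ratio) / av1$av_ratio, 0.02)
})
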