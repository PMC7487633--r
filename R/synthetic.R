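# Synthetic fundus scenes: a circular field containing an optic disc and a
# branching vascular tree with known per-branch widths and artery/vein
# labels, rendered to an RGB photo plus an exactly countable ground-truth
# mask. This is the validation substrate for every downstream stage.

#' Scene parameters for the synthetic fundus generator
#'
#' Defaults describe a smartphone-ophthalmoscope style photograph: a 720 px
#' square frame covering a 7.0 x 7.0 mm field, an optic disc of roughly
#' 1.5 mm diameter slightly nasal of center, and six major vessels (three
#' arteriole/venule pairs) radiating from the disc to the field edge.
#' Venules are drawn wider and darker than arterioles, as in real fundus
#' photographs; labels (not appearance) are authoritative.
#'
#' @param canvas_px square canvas side in pixels.
#' @param field_mm physical field of view covered by the canvas, in mm.
#' @param n_arterioles,n_venules number of major branches per class (each
#'   must be at least 1).
#' @param disc_center optional `(row, col)` disc center in pixels (1-based);
#'   default places the disc slightly nasal of the frame center.
#' @param disc_diameter_px optic disc diameter in pixels (default ~1.5 mm).
#' @param arteriole_width_range,venule_width_range ranges (px) from which
#'   per-branch constant widths are drawn.
#' @param arteriole_widths,venule_widths optional explicit width vectors
#'   (recycled over branches) overriding the ranges.
#' @param caliber_scale_range range of the per-scene global caliber scale
#'   factor applied to every branch width, emulating between-subject
#'   variation in overall vessel caliber (and hence vessel density, whose
#'   population spread in fundus studies is large). The A/V ratio is
#'   invariant to this factor.
#' @param background_level green-channel background intensity in \[0,1\]
#'   inside the field (red/blue channels are tinted around it).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units).
#' @param vignette_strength radial darkening toward the field edge, in
#'   \[0,1\].
#' @param arteriole_contrast,venule_contrast fractional darkening of vessels
#'   relative to the local background.
#' @param child_prob probability that a major branch spawns one child branch
#'   beyond the measurement annulus.
#' @param child_width_factor child width as a fraction of the parent width.
#' @return a `scene_config` list, validated.
#' @export
scene_config <- function(canvas_px = 720L, field_mm = 7.0,
                         n_arterioles = 3L, n_venules = 3L,
                         disc_center = NULL,
                         disc_diameter_px = round(0.21 * canvas_px),
                         arteriole_width_range = c(7, 11),
                         venule_width_range = c(10.5, 14),
                         arteriole_widths = NULL, venule_widths = NULL,
                         caliber_scale_range = c(0.75, 1.25),
                         background_level = 0.55, noise_sd = 0.02,
                         vignette_strength = 0.3,
                         arteriole_contrast = 0.35, venule_contrast = 0.5,
                         child_prob = 0.3, child_width_factor = 0.8) {
  if (canvas_px <= 0) stop("canvas_px must be positive", call. = FALSE)
  if (n_arterioles < 1L || n_venules < 1L) {
    stop("at least one arteriole and one venule are required", call. = FALSE)
  }
  widths <- c(arteriole_width_range, venule_width_range,
              arteriole_widths, venule_widths)
  if (any(widths < 1)) stop("vessel widths must be >= 1 px", call. = FALSE)
  if (is.null(disc_center)) {
    disc_center <- c(0.5, 0.42) * canvas_px
  }
  ctr <- (canvas_px + 1) / 2
  if (sqrt(sum((disc_center - ctr)^2)) + disc_diameter_px / 2 > canvas_px / 2) {
    stop("optic disc extends outside the circular field", call. = FALSE)
  }
  cfg <- list(canvas_px = as.integer(canvas_px), field_mm = field_mm,
              n_arterioles = as.integer(n_arterioles),
              n_venules = as.integer(n_venules),
              disc_center = as.numeric(disc_center),
              disc_diameter_px = as.numeric(disc_diameter_px),
              arteriole_width_range = arteriole_width_range,
              venule_width_range = venule_width_range,
              arteriole_widths = arteriole_widths,
              venule_widths = venule_widths,
              caliber_scale_range = caliber_scale_range,
              background_level = background_level, noise_sd = noise_sd,
              vignette_strength = vignette_strength,
              arteriole_contrast = arteriole_contrast,
              venule_contrast = venule_contrast,
              child_prob = child_prob, child_width_factor = child_width_factor)
  class(cfg) <- "scene_config"
  cfg
}

# Recursive midpoint displacement of the segment (p0, p1); returns the
# interior points (excluding endpoints), jittered perpendicular to the chord.
midpoint_displace <- function(p0, p1, depth, amp) {
  if (depth == 0L) return(NULL)
  mid <- (p0 + p1) / 2
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  n <- c(-d[2], d[1]) / max(len, 1e-9)
  mid <- mid + n * runif(1, -amp, amp) * len
  rbind(midpoint_displace(p0, mid, depth - 1L, amp), mid,
        midpoint_displace(mid, p1, depth - 1L, amp))
}

# largest t such that start + t*dir stays within radius R of ctr
ray_circle_t <- function(start, dir, ctr, R) {
  f <- start - ctr
  a <- sum(dir^2); b <- 2 * sum(f * dir); cc <- sum(f^2) - R^2
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(0)
  (-b + sqrt(disc)) / (2 * a)
}

#' Generate a synthetic fundus scene
#'
#' Builds the scene geometry (optic disc plus a labeled branching vascular
#' tree) deterministically from a seed. All centerlines lie inside the
#' inscribed circular field; every major branch starts on the disc margin
#' and reaches near the field edge, so it crosses the caliber-measurement
#' annulus (0.5 to 1 disc diameter from the disc margin). Child branches
#' attach beyond the annulus so measurements there are junction-free.
#'
#' @param seed integer seed; identical seed and config reproduce the scene
#'   bit for bit.
#' @param config a [scene_config()].
#' @return a `fundus_scene` object with fields `seed`, `config`, `disc`
#'   (`center`, `diameter_px`), and `branches` (each with `label`,
#'   `centerline` as an n x 2 (row, col) matrix, `width_px`, `parent`).
#' @export
generate_scene <- function(seed, config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(seed, {
    n_tot <- config$n_arterioles + config$n_venules
    # venules on alternating slots first (spatial alternation), exact counts
    labels <- rep(NA_character_, n_tot)
    labels[seq(1, n_tot, by = 2)][seq_len(min(config$n_venules, length(seq(1, n_tot, by = 2))))] <- "venule"
    nv_left <- config$n_venules - sum(labels == "venule", na.rm = TRUE)
    open <- which(is.na(labels))
    if (nv_left > 0) labels[open[seq_len(nv_left)]] <- "venule"
    labels[is.na(labels)] <- "arteriole"
    ctr <- rep((config$canvas_px + 1) / 2, 2)
    Rf <- config$canvas_px / 2
    D <- config$disc_diameter_px
    dc <- config$disc_center
    base_ang <- runif(1, 0, 2 * pi)
    caliber_scale <- runif(1, config$caliber_scale_range[1],
                           config$caliber_scale_range[2])
    widths_for <- function(lab, k) {
      if (lab == "arteriole") {
        if (!is.null(config$arteriole_widths)) {
          rep(config$arteriole_widths, length.out = config$n_arterioles)[k]
        } else runif(1, config$arteriole_width_range[1], config$arteriole_width_range[2])
      } else {
        if (!is.null(config$venule_widths)) {
          rep(config$venule_widths, length.out = config$n_venules)[k]
        } else runif(1, config$venule_width_range[1], config$venule_width_range[2])
      }
    }
    branches <- list()
    ka <- 0L; kv <- 0L
    for (i in seq_len(n_tot)) {
      ang <- base_ang + 2 * pi * (i - 1) / n_tot +
        runif(1, -0.2, 0.2) * 2 * pi / n_tot
      dir <- c(sin(ang), cos(ang))
      start <- dc + dir * (D / 2)
      tmax <- ray_circle_t(start, dir, ctr, 0.93 * Rf)
      end <- start + dir * max(tmax, D)
      pts <- rbind(start, midpoint_displace(start, end, 3L, 0.05), end)
      # clamp every vertex into the inscribed field
      rad <- sqrt(rowSums((pts - matrix(ctr, nrow(pts), 2, byrow = TRUE))^2))
      bad <- rad > 0.97 * Rf
      if (any(bad)) {
        sc <- 0.97 * Rf / rad[bad]
        pts[bad, ] <- matrix(ctr, sum(bad), 2, byrow = TRUE) +
          (pts[bad, , drop = FALSE] - matrix(ctr, sum(bad), 2, byrow = TRUE)) * sc
      }
      if (labels[i] == "arteriole") { ka <- ka + 1L; w <- widths_for("arteriole", ka) }
      else { kv <- kv + 1L; w <- widths_for("venule", kv) }
      w <- w * caliber_scale
      branches[[length(branches) + 1L]] <-
        list(label = labels[i], centerline = unname(pts), width_px = w,
             parent = NA_integer_)
      # optional child branch attached beyond the measurement annulus
      if (runif(1) < config$child_prob) {
        radd <- sqrt(rowSums((pts - matrix(dc, nrow(pts), 2, byrow = TRUE))^2))
        cand <- which(radd > 1.6 * D)
        if (length(cand) >= 2) {
          j <- cand[1]
          cstart <- pts[j, ]
          cang <- ang + sample(c(-1, 1), 1) * runif(1, 0.5, 0.9)
          cdir <- c(sin(cang), cos(cang))
          clen <- min(0.4 * tmax, ray_circle_t(cstart, cdir, ctr, 0.93 * Rf))
          if (clen > 10) {
            cend <- cstart + cdir * clen
            cpts <- rbind(cstart, midpoint_displace(cstart, cend, 2L, 0.05), cend)
            crad <- sqrt(rowSums((cpts - matrix(ctr, nrow(cpts), 2, byrow = TRUE))^2))
            cbad <- crad > 0.97 * Rf
            if (any(cbad)) {
              sc <- 0.97 * Rf / crad[cbad]
              cpts[cbad, ] <- matrix(ctr, sum(cbad), 2, byrow = TRUE) +
                (cpts[cbad, , drop = FALSE] - matrix(ctr, sum(cbad), 2, byrow = TRUE)) * sc
            }
            branches[[length(branches) + 1L]] <-
              list(label = labels[i], centerline = unname(cpts),
                   width_px = w * config$child_width_factor,
                   parent = length(branches))
          }
        }
      }
    }
    scene <- list(seed = as.integer(seed), config = config,
                  canvas_px = config$canvas_px, field_mm = config$field_mm,
                  disc = list(center = dc, diameter_px = D),
                  branches = branches,
                  background_level = config$background_level,
                  noise_sd = config$noise_sd,
                  vignette_strength = config$vignette_strength)
    class(scene) <- "fundus_scene"
    scene
  })
}

#' @export
print.fundus_scene <- function(x, ...) {
  labs <- vapply(x$branches, `[[`, "", "label")
  cat("Synthetic fundus scene (seed ", x$seed, ")\n", sep = "")
  cat("  canvas: ", x$canvas_px, " px, field ", x$field_mm, " mm (",
      signif(x$field_mm / x$canvas_px, 4), " mm/px)\n", sep = "")
  cat("  disc: center (", paste(round(x$disc$center, 1), collapse = ", "),
      "), diameter ", round(x$disc$diameter_px, 1), " px\n", sep = "")
  cat("  branches: ", sum(labs == "arteriole"), " arteriole / ",
      sum(labs == "venule"), " venule\n", sep = "")
  invisible(x)
}

# Minimum distance from each pixel center in a bounding box to a polyline,
# written into `acc` (a running minimum). Returns updated acc (full-canvas
# matrix, Inf where never touched).
polyline_distance_update <- function(acc, pts, reach) {
  H <- nrow(acc); W <- ncol(acc)
  for (s in seq_len(nrow(pts) - 1)) {
    p0 <- pts[s, ]; p1 <- pts[s + 1, ]
    r0 <- max(1L, floor(min(p0[1], p1[1]) - reach))
    r1 <- min(H, ceiling(max(p0[1], p1[1]) + reach))
    c0 <- max(1L, floor(min(p0[2], p1[2]) - reach))
    c1 <- min(W, ceiling(max(p0[2], p1[2]) + reach))
    if (r1 < r0 || c1 < c0) next
    rr <- r0:r1; cc <- c0:c1
    RR <- matrix(rr, length(rr), length(cc))
    CC <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    d <- p1 - p0
    L2 <- sum(d^2)
    if (L2 < 1e-12) {
      dist <- sqrt((RR - p0[1])^2 + (CC - p0[2])^2)
    } else {
      t <- ((RR - p0[1]) * d[1] + (CC - p0[2]) * d[2]) / L2
      t <- pmin(pmax(t, 0), 1)
      dist <- sqrt((RR - (p0[1] + t * d[1]))^2 + (CC - (p0[2] + t * d[2]))^2)
    }
    acc[rr, cc] <- pmin(acc[rr, cc], dist)
  }
  acc
}

# distance matrices per branch are expensive; compute one shared canvas
# accumulator per branch only where needed
branch_distance <- function(scene, branch) {
  acc <- matrix(Inf, scene$canvas_px, scene$canvas_px)
  polyline_distance_update(acc, branch$centerline, branch$width_px / 2 + 2)
}

# which branches have at least one densified centerline point with radial
# distance from the disc center inside [inner, outer]
branches_in_annulus <- function(scene) {
  ann <- annulus_from_disc(scene$disc)
  vapply(scene$branches, function(b) {
    pts <- densify_polyline(b$centerline, 1)
    r <- sqrt((pts[, 1] - scene$disc$center[1])^2 +
                (pts[, 2] - scene$disc$center[2])^2)
    any(r >= ann$inner_radius_px & r <= ann$outer_radius_px)
  }, logical(1))
}

# resample a polyline at approximately unit `step` spacing (keeps vertices'
# geometry via linear interpolation along arclength)
densify_polyline <- function(pts, step = 1) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < step) return(pts)
  ss <- seq(0, total, by = step)
  r <- approx(s, pts[, 1], xout = ss)$y
  c <- approx(s, pts[, 2], xout = ss)$y
  cbind(r, c, deparse.level = 0)
}

#' Render a synthetic scene to an image and exact ground truth
#'
#' Vessels are drawn as dark anti-aliased tubes of constant width on a
#' brighter, vignetted background with a bright optic disc; the ground-truth
#' mask instead follows the hard geometric rule: a pixel is vessel iff its
#' center lies within `width/2` of a branch centerline, so mask-derived
#' quantities (density, calibers) are exactly countable. The green channel
#' background inside the field equals `background_level` exactly when noise
#' and vignetting are zero.
#'
#' @param scene a [generate_scene()] result.
#' @param noise_seed integer seed for the additive noise field (defaults to
#'   `scene$seed + 1000`).
#' @return list with `image` (canvas x canvas x 3 array in \[0,1\]) and
#'   `truth`: `mask` (0/1 integer matrix), per-branch `centerlines`,
#'   `widths_px`, `labels`, `density_true` (percent), `av_ratio_true`,
#'   `measured_pair` (branch indices of the designated widest
#'   annulus-crossing arteriole and venule), and `disc`.
#' @export
render <- function(scene, noise_seed = scene$seed + 1000L) {
  stopifnot(inherits(scene, "fundus_scene"))
  S <- scene$canvas_px
  ctr <- (S + 1) / 2
  RR <- matrix(seq_len(S), S, S)
  CC <- matrix(seq_len(S), S, S, byrow = TRUE)
  rad <- sqrt((RR - ctr)^2 + (CC - ctr)^2)
  Rf <- S / 2
  infield <- rad <= Rf
  vign <- 1 - scene$vignette_strength * (rad / Rf)^2
  tint <- c(1.15, 1.0, 0.65)  # fundus-like: red-heavy background
  bgG <- scene$background_level * vign
  img <- array(0.05, c(S, S, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[infield] <- clip01(bgG * tint[ch])[infield]
    img[, , ch] <- plane
  }
  # optic disc: bright, slightly yellow, smooth 1.5 px edge
  dd <- sqrt((RR - scene$disc$center[1])^2 + (CC - scene$disc$center[2])^2)
  alpha_d <- clip01((scene$disc$diameter_px / 2 + 0.75 - dd) / 1.5)
  disc_col <- c(0.98, 0.90, 0.62)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - 0.85 * alpha_d) +
      0.85 * alpha_d * disc_col[ch]
  }
  # vessels: anti-aliased dark tubes; venules darker than arterioles
  mask <- matrix(0L, S, S)
  contr_scale <- c(0.55, 1.0, 0.85)  # per-channel darkening emphasis
  for (b in scene$branches) {
    dmat <- branch_distance(scene, b)
    alpha <- clip01(b$width_px / 2 + 0.5 - dmat)
    touched <- which(alpha > 0)
    contrast <- if (b$label == "venule") scene$config$venule_contrast else
      scene$config$arteriole_contrast
    for (ch in 1:3) {
      plane <- img[, , ch]
      tgt <- plane[touched] * (1 - contrast * contr_scale[ch])
      plane[touched] <- plane[touched] * (1 - alpha[touched]) +
        alpha[touched] * tgt
      img[, , ch] <- plane
    }
    mask[dmat <= b$width_px / 2] <- 1L
  }
  if (scene$noise_sd > 0) {
    noise <- with_seed(noise_seed, matrix(rnorm(S * S, 0, scene$noise_sd), S, S))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
  }
  img <- clip01(img)
  in_ann <- branches_in_annulus(scene)
  labs <- vapply(scene$branches, `[[`, "", "label")
  ws <- vapply(scene$branches, `[[`, 0.0, "width_px")
  ai <- which(labs == "arteriole" & in_ann)
  vi <- which(labs == "venule" & in_ann)
  if (length(ai) && length(vi)) {
    a_star <- ai[which.max(ws[ai])]
    v_star <- vi[which.max(ws[vi])]
    av_true <- ws[a_star] / ws[v_star]
    pair <- c(arteriole = a_star, venule = v_star)
  } else {
    av_true <- NA_real_
    pair <- c(arteriole = NA_integer_, venule = NA_integer_)
  }
  truth <- list(mask = mask,
                centerlines = lapply(scene$branches, `[[`, "centerline"),
                widths_px = ws, labels = labs,
                density_true = 100 * sum(mask) / (S * S),
                av_ratio_true = av_true, measured_pair = pair,
                disc = scene$disc)
  list(image = img, truth = truth)
}

# Rigid transform of scene geometry: rotate about the canvas center, then
# translate. Used by make_repeat_pair; re-rendering the transformed geometry
# avoids image resampling, so shifted centerlines are exact.
transform_scene <- function(scene, translate_px = c(0, 0), rotate_deg = 0,
                            illum_delta = 0) {
  th <- rotate_deg * pi / 180
  Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  ctr <- rep((scene$canvas_px + 1) / 2, 2)
  tf <- function(pts) {
    if (th == 0) {
      # pure translation stays exact (no floating-point round trip)
      sweep(pts, 2, translate_px, `+`)
    } else {
      sweep(t(Rm %*% t(sweep(pts, 2, ctr))), 2, ctr + translate_px, `+`)
    }
  }
  out <- scene
  out$disc$center <- as.numeric(tf(matrix(scene$disc$center, 1)))
  out$branches <- lapply(scene$branches, function(b) {
    b$centerline <- tf(b$centerline); b
  })
  out$background_level <- scene$background_level + illum_delta
  Rfld <- scene$canvas_px / 2
  if (sqrt(sum((out$disc$center - ctr)^2)) + out$disc$diameter_px / 2 > Rfld) {
    stop("jitter moves the optic disc outside the circular field",
         call. = FALSE)
  }
  out
}

#' Simulate two acquisitions of the same eye
#'
#' Renders the same vascular anatomy twice under small pose, illumination and
#' noise perturbations, emulating two fundus photographs of one eye taken in
#' a single session.
#'
#' @param scene a [generate_scene()] result.
#' @param jitter list with any of `translate_px` (length-2, applied to the
#'   second acquisition), `rotate_deg`, `illum_delta`, and
#'   `noise_seed_offsets` (length-2 integer offsets; equal offsets reuse the
#'   same noise field).
#' @param seed integer; base seed for the two noise fields.
#' @return list with `image1`, `image2`, `truth1`, `truth2`, and `scene2`
#'   (the transformed geometry).
#' @export
make_repeat_pair <- function(scene, jitter = list(), seed = scene$seed) {
  j <- modifyList(list(translate_px = c(0, 0), rotate_deg = 0,
                       illum_delta = 0, noise_seed_offsets = c(1L, 2L)),
                  jitter)
  scene2 <- transform_scene(scene, j$translate_px, j$rotate_deg, j$illum_delta)
  out1 <- render(scene, noise_seed = seed + j$noise_seed_offsets[1])
  out2 <- render(scene2, noise_seed = seed + j$noise_seed_offsets[2])
  list(image1 = out1$image, image2 = out2$image,
       truth1 = out1$truth, truth2 = out2$truth, scene2 = scene2)
}
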