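# Headline metrics: vessel density over the analysis frame, and the
# arteriole-to-venule caliber ratio measured by the annulus-constrained
# five-measurement protocol (five non-overlapping perpendicular width
# measurements per vessel, averaged, ratio of means).

#' Optic disc geometry
#'
#' @param center `(row, col)` disc center in pixels (1-based).
#' @param diameter_px disc diameter in pixels.
#' @return a `disc_geometry`.
#' @export
disc_geometry <- function(center, diameter_px) {
  if (diameter_px <= 0) stop("diameter_px must be positive", call. = FALSE)
  structure(list(center = as.numeric(center),
                 diameter_px = as.numeric(diameter_px)),
            class = "disc_geometry")
}

#' Caliber-measurement annulus from the disc geometry
#'
#' The measurement zone lies 0.5 to 1 disc diameter outward from the disc
#' margin: with disc diameter `D` (radius `D/2`), the annulus radii from
#' the disc center are `inner = D/2 + 0.5 D = D` and
#' `outer = D/2 + 1.0 D = 1.5 D`. The outer boundary is closed (a point at
#' exactly `outer` is inside).
#'
#' @param disc a [disc_geometry()] (or a list with `center` and
#'   `diameter_px`).
#' @param image_side optional image side in px; if the annulus extends
#'   beyond the image a warning is raised and the annulus is flagged
#'   clipped.
#' @return a `measurement_annulus` with `center`, `inner_radius_px`,
#'   `outer_radius_px`, `clipped`.
#' @export
annulus_from_disc <- function(disc, image_side = NULL) {
  D <- disc$diameter_px
  ann <- list(center = disc$center, inner_radius_px = D,
              outer_radius_px = 1.5 * D, clipped = FALSE)
  if (!is.null(image_side)) {
    lo <- disc$center - ann$outer_radius_px
    hi <- disc$center + ann$outer_radius_px
    if (any(lo < 1) || any(hi > image_side)) {
      warning("measurement annulus extends outside the image; ",
              "masking will be clipped")
      ann$clipped <- TRUE
    }
  }
  structure(ann, class = "measurement_annulus")
}

in_annulus <- function(ann, r, c) {
  d <- sqrt((r - ann$center[1])^2 + (c - ann$center[2])^2)
  d >= ann$inner_radius_px & d <= ann$outer_radius_px
}

#' Vessel density of a binary mask
#'
#' The percentage of vessel pixels over the entire analysis frame, by exact
#' integer counting.
#'
#' @param mask a binary (0/1) matrix, e.g. from [binarize()].
#' @return a `density_result`: `vessel_px`, `total_px`, `density_percent`.
#' @export
vessel_density <- function(mask) {
  m <- unclass(mask)
  if (!all(m %in% c(0L, 1L))) stop("mask must be strictly binary",
                                   call. = FALSE)
  vessel <- sum(m == 1L)
  total <- length(m)
  structure(list(vessel_px = vessel, total_px = total,
                 density_percent = 100 * vessel / total),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("Vessel density: %.4f%% (%d / %d px)\n", x$density_percent,
              x$vessel_px, x$total_px))
  invisible(x)
}

# 8-connected component of vessel pixels containing the seed, as a logical
# matrix; frontier-based flood fill.
vessel_component <- function(mask, seed_point) {
  H <- nrow(mask); W <- ncol(mask)
  sp <- round(seed_point)
  if (sp[1] < 1 || sp[1] > H || sp[2] < 1 || sp[2] > W ||
      mask[sp[1], sp[2]] != 1L) {
    stop("seed point (", seed_point[1], ", ", seed_point[2],
         ") is not on a vessel pixel", call. = FALSE)
  }
  # zero border pad prevents flat-index wrap-around across columns
  Hp <- H + 2L
  padded <- matrix(FALSE, Hp, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- mask == 1L
  comp <- matrix(FALSE, Hp, W + 2L)
  frontier <- (sp[1] + 1L) + sp[2] * Hp
  comp[frontier] <- TRUE
  shifts <- c(-1L, 1L, -Hp, Hp, -Hp - 1L, -Hp + 1L, Hp - 1L, Hp + 1L)
  while (length(frontier)) {
    nbr <- unique(as.vector(outer(frontier, shifts, `+`)))
    cand <- nbr[padded[nbr] & !comp[nbr]]
    comp[cand] <- TRUE
    frontier <- cand
  }
  comp[2:(H + 1L), 2:(W + 1L)]
}

#' Extract an ordered vessel centerline from a mask
#'
#' Skeletonizes (Guo-Hall thinning) the 8-connected vessel component
#' containing the seed point and returns the longest path through the
#' skeleton, restricted to the measurement annulus band when one is given.
#' Deterministic: the same mask and seed always give the same polyline.
#'
#' @param mask binary vessel mask.
#' @param seed_point `(row, col)` on a vessel pixel.
#' @param annulus optional [annulus_from_disc()] result restricting the
#'   path.
#' @return an n x 2 matrix of (row, col) skeleton coordinates ordered along
#'   the path, with attribute `unmeasurable = TRUE` for degenerate
#'   (single-point) paths.
#' @export
extract_centerline <- function(mask, seed_point, annulus = NULL) {
  comp <- vessel_component(unclass(mask), seed_point)
  skel <- thin_binary(matrix(as.integer(comp), nrow(comp)))
  pix <- which(skel == 1L, arr.ind = TRUE)
  if (!is.null(annulus)) {
    keep <- in_annulus(annulus, pix[, 1], pix[, 2])
    pix <- pix[keep, , drop = FALSE]
  }
  if (nrow(pix) == 0L) {
    stop("no skeleton pixels in the measurement region", call. = FALSE)
  }
  if (nrow(pix) == 1L) {
    out <- matrix(as.numeric(pix), 1, 2)
    attr(out, "unmeasurable") <- TRUE
    return(out)
  }
  # graph over 8-neighbouring skeleton pixels, edge weight = distance
  id <- seq_len(nrow(pix))
  key <- pix[, 1] + (pix[, 2] - 1) * nrow(mask)
  lookup <- new.env(hash = TRUE, size = length(key))
  for (k in id) assign(as.character(key[k]), k, envir = lookup)
  edges <- NULL; wts <- NULL
  H <- nrow(mask)
  for (dr in -1:1) for (dc in 0:1) {
    if (dc == 0 && dr <= 0) next   # each unordered pair once
    nk <- key + dr + dc * H
    tgt <- vapply(as.character(nk), function(s) {
      v <- mget(s, envir = lookup, ifnotfound = list(NA_integer_))[[1]]
      as.integer(v)
    }, 1L)
    valid <- !is.na(tgt) & (pix[, 1] + dr >= 1) & (pix[, 1] + dr <= H)
    if (any(valid)) {
      edges <- rbind(edges, cbind(id[valid], tgt[valid]))
      wts <- c(wts, rep(sqrt(dr^2 + dc^2), sum(valid)))
    }
  }
  if (is.null(edges)) {
    out <- matrix(as.numeric(pix[1, ]), 1, 2)
    attr(out, "unmeasurable") <- TRUE
    return(out)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  if (igraph::vcount(g) < nrow(pix)) {
    g <- igraph::add_vertices(g, nrow(pix) - igraph::vcount(g))
  }
  comp_id <- igraph::components(g)$membership
  main <- which.max(tabulate(comp_id))
  sub <- which(comp_id == main)
  # double sweep: farthest node from an arbitrary node, then the farthest
  # node from that one; the connecting geodesic is the centerline
  d1 <- igraph::distances(g, v = sub[1], to = sub)[1, ]
  u <- sub[which.max(d1)]
  d2 <- igraph::distances(g, v = u, to = sub)[1, ]
  v <- sub[which.max(d2)]
  path <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1]]
  out <- pix[as.integer(path), , drop = FALSE]
  storage.mode(out) <- "double"
  colnames(out) <- NULL
  if (nrow(out) < 2) attr(out, "unmeasurable") <- TRUE
  out
}

# perpendicular chord length through the mask at a continuous point, with
# linear subpixel interpolation of the 0.5 level crossings
chord_width <- function(mask, point, normal, max_reach, step = 0.1) {
  ts <- seq(step, max_reach, by = step)
  reach <- function(sign) {
    rr <- point[1] + sign * ts * normal[1]
    cc <- point[2] + sign * ts * normal[2]
    vals <- bilinear_at(mask, rr, cc, outside = 0)
    below <- which(vals < 0.5)
    if (!length(below)) return(max_reach)
    k <- below[1]
    if (k == 1L) {
      v0 <- bilinear_at(mask, point[1], point[2]); t0 <- 0
    } else {
      v0 <- vals[k - 1L]; t0 <- ts[k - 1L]
    }
    v1 <- vals[k]
    t0 + (0.5 - v0) / (v1 - v0) * (ts[k] - t0)
  }
  reach(1) + reach(-1)
}

#' Measure vessel caliber by the five-measurement protocol
#'
#' Selects five measurement sites on the centerline inside the measurement
#' annulus, evenly spaced along the arc (which maximizes the minimal
#' pairwise spacing, deterministically); at each site the perpendicular
#' chord length through the mask is measured with subpixel edge
#' interpolation. Sites must be mutually at least `max(local width, 5)` px
#' apart or a measurement error is raised.
#'
#' @param mask binary vessel mask.
#' @param centerline ordered (row, col) polyline from
#'   [extract_centerline()] (or ground truth).
#' @param annulus optional [annulus_from_disc()]; when given, only the
#'   in-annulus arc is used.
#' @param pixel_scale_mm physical pixel scale (mm per px) for micron
#'   output.
#' @param vessel_label `"arteriole"` or `"venule"` (recorded).
#' @return a `caliber_set`: `vessel_label`, `widths_px` (length 5),
#'   `width_mean_px`, `width_mean_um`, `sites` (5 x 2 matrix).
#' @export
measure_caliber <- function(mask, centerline, annulus = NULL,
                            pixel_scale_mm = 7.0 / 720,
                            vessel_label = c("arteriole", "venule")) {
  vessel_label <- match.arg(vessel_label)
  if (isTRUE(attr(centerline, "unmeasurable")) || nrow(centerline) < 2) {
    stop("centerline is degenerate; vessel unmeasurable", call. = FALSE)
  }
  pts <- densify_polyline(centerline, 0.5)
  if (!is.null(annulus)) {
    ok <- in_annulus(annulus, pts[, 1], pts[, 2])
    runs <- rle(ok)
    if (!any(runs$values)) {
      stop(vessel_label, ": centerline does not intersect the annulus",
           call. = FALSE)
    }
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    pts <- pts[starts[best]:ends[best], , drop = FALSE]
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  span <- s[length(s)]
  m <- unclass(mask)
  storage.mode(m) <- "double"
  site_at <- function(target_s) {
    k <- which.min(abs(s - target_s))
    # local tangent over a +-3 px arc window, by least squares
    win <- which(abs(s - s[k]) <= 3)
    P <- pts[win, , drop = FALSE]
    Pc <- sweep(P, 2, colMeans(P))
    sv <- svd(Pc)
    tangent <- sv$v[, 1]
    list(point = pts[k, ], normal = c(-tangent[2], tangent[1]))
  }
  n_sites <- 5L
  targets <- seq(0, span, length.out = n_sites)
  sites <- matrix(0, n_sites, 2)
  widths <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    st <- site_at(targets[i])
    sites[i, ] <- st$point
    widths[i] <- chord_width(m, st$point, st$normal,
                             max_reach = max(20, span / 2))
  }
  min_gap <- max(mean(widths), 5)
  if (span / (n_sites - 1) < min_gap) {
    stop(vessel_label, ": annulus arc too short for 5 non-overlapping ",
         "measurements (span ", round(span, 1), " px, required spacing ",
         round(min_gap, 1), " px)", call. = FALSE)
  }
  structure(list(vessel_label = vessel_label, widths_px = widths,
                 width_mean_px = mean(widths),
                 width_mean_um = mean(widths) * pixel_scale_mm * 1000,
                 sites = sites),
            class = "caliber_set")
}

#' @export
print.caliber_set <- function(x, ...) {
  cat(sprintf("%s caliber: mean %.2f px (%.1f um); widths: %s\n",
              x$vessel_label, x$width_mean_px, x$width_mean_um,
              paste(sprintf("%.2f", x$widths_px), collapse = ", ")))
  invisible(x)
}

#' Arteriole-to-venule ratio
#'
#' @param artery,vein [measure_caliber()] results for the designated
#'   parallel arteriole and venule.
#' @return an `av_result` with `artery`, `vein` and `av_ratio` (ratio of
#'   mean widths; the pixel scale cancels).
#' @export
av_ratio <- function(artery, vein) {
  stopifnot(inherits(artery, "caliber_set"), inherits(vein, "caliber_set"))
  structure(list(artery = artery, vein = vein,
                 av_ratio = artery$width_mean_px / vein$width_mean_px),
            class = "av_result")
}

#' @export
print.av_result <- function(x, ...) {
  cat(sprintf("A/V ratio: %.4f (arteriole %.2f px / venule %.2f px)\n",
              x$av_ratio, x$artery$width_mean_px, x$vein$width_mean_px))
  invisible(x)
}

#' Annotation for the designated measured pair of a synthetic ground truth
#'
#' Converts the ground truth of a rendered scene into the annotation format
#' [measure_av()] expects (disc geometry plus one seed point on the
#' designated arteriole and venule, each chosen mid-annulus), optionally
#' rescaled from the render canvas to another frame side.
#'
#' @param truth the `truth` component of a [render()] result.
#' @param from_side canvas side the truth coordinates live on.
#' @param to_side frame side to rescale the annotation to.
#' @return list with `disc`, `arteriole_seed`, `venule_seed`.
#' @export
truth_annotation <- function(truth, from_side, to_side = from_side) {
  sc <- to_side / from_side
  pick_seed <- function(idx) {
    pts <- densify_polyline(truth$centerlines[[idx]], 1)
    r <- sqrt((pts[, 1] - truth$disc$center[1])^2 +
                (pts[, 2] - truth$disc$center[2])^2)
    mid <- which.min(abs(r - 1.25 * truth$disc$diameter_px))
    pts[mid, ] * sc
  }
  list(disc = disc_geometry(truth$disc$center * sc,
                            truth$disc$diameter_px * sc),
       arteriole_seed = pick_seed(truth$measured_pair[["arteriole"]]),
       venule_seed = pick_seed(truth$measured_pair[["venule"]]))
}

#' Measure the A/V ratio of a mask given an annotation
#'
#' The annotation designates the disc geometry and one seed point each on
#' the measured arteriole and venule (mirroring the manual selection of a
#' parallel pair in clinical protocols). Centerlines are skeleton paths
#' through the annulus; widths follow the five-measurement protocol.
#'
#' @param mask binary vessel mask.
#' @param annot list with `disc` ([disc_geometry()]), `arteriole_seed`,
#'   `venule_seed` (each `(row, col)`).
#' @param pixel_scale_mm mm per pixel of the mask frame.
#' @return an `av_result`.
#' @export
measure_av <- function(mask, annot, pixel_scale_mm = 7.0 / 720) {
  ann <- annulus_from_disc(annot$disc, image_side = nrow(mask))
  snap <- function(seed) snap_to_vessel(unclass(mask), seed)
  art_cl <- extract_centerline(mask, snap(annot$arteriole_seed), ann)
  ven_cl <- extract_centerline(mask, snap(annot$venule_seed), ann)
  art <- measure_caliber(mask, art_cl, ann, pixel_scale_mm, "arteriole")
  ven <- measure_caliber(mask, ven_cl, ann, pixel_scale_mm, "venule")
  av_ratio(art, ven)
}

# nearest vessel pixel to a continuous seed (within a small search radius);
# segmentation masks can be eroded relative to ground-truth seeds
snap_to_vessel <- function(mask, seed, radius = 6L) {
  sp <- round(seed)
  H <- nrow(mask); W <- ncol(mask)
  rr <- max(1, sp[1] - radius):min(H, sp[1] + radius)
  cc <- max(1, sp[2] - radius):min(W, sp[2] + radius)
  sub <- mask[rr, cc, drop = FALSE]
  hit <- which(sub == 1L, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    stop("no vessel pixel within ", radius, " px of seed (",
         sp[1], ", ", sp[2], ")", call. = FALSE)
  }
  d <- (rr[hit[, 1]] - seed[1])^2 + (cc[hit[, 2]] - seed[2])^2
  k <- which.min(d)
  c(rr[hit[k, 1]], cc[hit[k, 2]])
}
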