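# Patch-based U-Net vessel segmentation: a 23-convolutional-layer
# encoder-decoder with skip connections, trained on random image patches
# with per-pixel binary cross-entropy, and applied by tiled inference with
# overlap averaging. Implemented from first principles on im2col/GEMM
# primitives (no deep-learning framework is required).

#' U-Net architecture specification
#'
#' The standard contracting/expanding architecture: `depth` levels of two
#' 3x3 convolutions + 2x2 max pooling, a two-convolution bottleneck, and a
#' mirrored expanding path whose levels are one 2x2 up-convolution plus two
#' 3x3 convolutions, closed by a final 1x1 convolution with sigmoid output.
#' With `depth = 4` the total number of convolutional layers is
#' 8 + 2 + 12 + 1 = 23.
#'
#' @param depth number of contraction levels.
#' @param base_channels feature channels at the first level (doubled per
#'   level). 16 is a desk-scale default; 8 trains faster on CPU.
#' @param patch_px training/inference patch side; must be divisible by
#'   `2^depth`.
#' @param in_channels input image channels (1 for the grayscale analysis
#'   frame).
#' @return a `unet_spec` with the audited `conv_layer_count`.
#' @export
unet_spec <- function(depth = 4L, base_channels = 16L, patch_px = 48L,
                      in_channels = 1L) {
  depth <- as.integer(depth)
  if (patch_px %% 2^depth != 0) {
    stop("patch_px must be divisible by 2^depth", call. = FALSE)
  }
  spec <- list(depth = depth, base_channels = as.integer(base_channels),
               patch_px = as.integer(patch_px),
               in_channels = as.integer(in_channels), out_channels = 1L,
               conv_layer_count = 2L * depth + 2L + 3L * depth + 1L)
  class(spec) <- "unet_spec"
  spec
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

#' Build a (randomly initialized) U-Net model
#'
#' @param spec a [unet_spec()]; the layer arithmetic must audit to exactly
#'   23 convolutional layers, otherwise a configuration error is raised.
#' @param seed seed for He-normal weight initialization.
#' @return a `unet` model object.
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  if (spec$conv_layer_count != 23L) {
    stop("U-Net layer arithmetic gives ", spec$conv_layer_count,
         " convolutional layers; the architecture requires exactly 23 ",
         "(depth 4)", call. = FALSE)
  }
  with_seed(seed, {
    d <- spec$depth; bc <- spec$base_channels
    ch <- bc * 2^(seq_len(d) - 1)        # per-level channels
    # field order matters: parameters and gradients are flattened
    # structurally (without names) for the optimizer
    params <- list(down = vector("list", d), bott = NULL,
                   up = vector("list", d), final = NULL)
    cin <- spec$in_channels
    for (i in seq_len(d)) {
      params$down[[i]] <- list(w1 = he_init(3, cin, ch[i]), b1 = numeric(ch[i]),
                               w2 = he_init(3, ch[i], ch[i]), b2 = numeric(ch[i]))
      cin <- ch[i]
    }
    cb <- bc * 2^d
    params$bott <- list(w1 = he_init(3, ch[d], cb), b1 = numeric(cb),
                        w2 = he_init(3, cb, cb), b2 = numeric(cb))
    cab <- cb
    for (i in rev(seq_len(d))) {
      params$up[[i]] <- list(
        uw = he_init(2, cab, ch[i]), ub = numeric(ch[i]),
        w1 = he_init(3, 2 * ch[i], ch[i]), b1 = numeric(ch[i]),
        w2 = he_init(3, ch[i], ch[i]), b2 = numeric(ch[i]))
      cab <- ch[i]
    }
    params$final <- list(w = he_init(1, bc, 1), b = numeric(1))
    model <- list(spec = spec, params = params, trained = FALSE,
                  loss_trace = NULL, config_hash = NULL)
    class(model) <- "unet"
    model
  })
}

#' Audit the number of convolutional layers of a built model
#'
#' Counts the actual weight tensors: 3x3 convolutions, 2x2 up-convolutions,
#' and the final 1x1 convolution.
#'
#' @param model a `unet` model (or a `unet_spec`).
#' @return integer layer count.
#' @export
unet_layer_count <- function(model) {
  if (inherits(model, "unet_spec")) return(model$conv_layer_count)
  stopifnot(inherits(model, "unet"))
  p <- model$params
  n <- length(p$down) * 2L + 2L +          # down convs + bottleneck
    length(p$up) * 3L +                    # upconv + two convs per level
    1L                                     # final 1x1
  # verify against the stored tensors
  tensors <- c(unlist(lapply(p$down, function(l) list(l$w1, l$w2)),
                      recursive = FALSE),
               list(p$bott$w1, p$bott$w2),
               unlist(lapply(p$up, function(l) list(l$uw, l$w1, l$w2)),
                      recursive = FALSE),
               list(p$final$w))
  stopifnot(length(tensors) == n)
  n
}

#' @export
print.unet <- function(x, ...) {
  cat("U-Net vessel segmentation model\n")
  cat("  conv layers:", unet_layer_count(x),
      "| depth:", x$spec$depth,
      "| base channels:", x$spec$base_channels,
      "| patch:", x$spec$patch_px, "px\n")
  cat("  trained:", x$trained, "\n")
  if (!is.null(x$loss_trace)) {
    cat("  loss trace:", paste(signif(x$loss_trace, 4), collapse = " "), "\n")
  }
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

sigmoid <- function(x) 1 / (1 + exp(-x))

# concatenate two (H,W,C,N) arrays along the channel axis
cat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Full forward pass; returns the sigmoid probability array and (optionally)
# every intermediate activation needed for backprop.
unet_forward <- function(model, x, keep = FALSE) {
  p <- model$params; d <- model$spec$depth
  cache <- list(x = x, down = vector("list", d), up = vector("list", d))
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    a1 <- relu(conv2d_fwd(x, p$down[[i]]$w1, p$down[[i]]$b1))
    a2 <- relu(conv2d_fwd(a1, p$down[[i]]$w2, p$down[[i]]$b2))
    pl <- maxpool2_fwd(a2)
    if (keep) cache$down[[i]] <- list(x = x, a1 = a1, a2 = a2, idx = pl$idx)
    skips[[i]] <- a2
    x <- pl$y
  }
  b1 <- relu(conv2d_fwd(x, p$bott$w1, p$bott$b1))
  b2 <- relu(conv2d_fwd(b1, p$bott$w2, p$bott$b2))
  if (keep) cache$bott <- list(x = x, a1 = b1, a2 = b2)
  x <- b2
  for (i in rev(seq_len(d))) {
    u <- relu(upconv2_fwd(x, p$up[[i]]$uw, p$up[[i]]$ub))
    ct <- cat4(skips[[i]], u)
    a1 <- relu(conv2d_fwd(ct, p$up[[i]]$w1, p$up[[i]]$b1))
    a2 <- relu(conv2d_fwd(a1, p$up[[i]]$w2, p$up[[i]]$b2))
    if (keep) cache$up[[i]] <- list(x = x, u = u, ct = ct, a1 = a1, a2 = a2)
    x <- a2
  }
  z <- conv2d_fwd(x, p$final$w, p$final$b)
  if (keep) cache$final <- list(x = x, z = z)
  prob <- sigmoid(z)
  if (keep) list(prob = prob, cache = cache) else prob
}

# Backward pass from d(loss)/d(pre-sigmoid logits); returns gradients in the
# same nested layout as the parameters.
unet_backward <- function(model, cache, dz) {
  p <- model$params; d <- model$spec$depth
  # same field order as the parameter list (structural flattening)
  g <- list(down = vector("list", d), bott = NULL,
            up = vector("list", d), final = NULL)
  bw <- conv2d_bwd(cache$final$x, p$final$w, dz)
  g$final <- list(w = bw$dw, b = bw$db)
  dx <- bw$dx
  for (i in seq_len(d)) {          # expanding path, from the last level up
    cu <- cache$up[[i]]
    d2 <- dx * (cu$a2 > 0)
    bw2 <- conv2d_bwd(cu$a1, p$up[[i]]$w2, d2)
    d1 <- bw2$dx * (cu$a1 > 0)
    bw1 <- conv2d_bwd(cu$ct, p$up[[i]]$w1, d1)
    nskip <- dim(cache$down[[i]]$a2)[3]
    dskip <- bw1$dx[, , seq_len(nskip), , drop = FALSE]
    du <- bw1$dx[, , nskip + seq_len(dim(cu$u)[3]), , drop = FALSE]
    du <- du * (cu$u > 0)
    bwu <- upconv2_bwd(cu$x, p$up[[i]]$uw, du)
    g$up[[i]] <- list(uw = bwu$dw, ub = bwu$db, w1 = bw1$dw, b1 = bw1$db,
                      w2 = bw2$dw, b2 = bw2$db)
    cache$up[[i]]$dskip <- dskip     # consumed by the matching down level
    dx <- bwu$dx
  }
  cb <- cache$bott
  d2 <- dx * (cb$a2 > 0)
  bw2 <- conv2d_bwd(cb$a1, p$bott$w2, d2)
  d1 <- bw2$dx * (cb$a1 > 0)
  bw1 <- conv2d_bwd(cb$x, p$bott$w1, d1)
  g$bott <- list(w1 = bw1$dw, b1 = bw1$db, w2 = bw2$dw, b2 = bw2$db)
  dx <- bw1$dx
  for (i in rev(seq_len(d))) {     # contracting path, from the bottom up
    cd <- cache$down[[i]]
    dpool <- maxpool2_bwd(dx, cd$idx, dim(cd$a2)[1], dim(cd$a2)[2])
    da2 <- (dpool + cache$up[[i]]$dskip) * (cd$a2 > 0)
    bw2 <- conv2d_bwd(cd$a1, p$down[[i]]$w2, da2)
    d1 <- bw2$dx * (cd$a1 > 0)
    bw1 <- conv2d_bwd(cd$x, p$down[[i]]$w1, d1)
    g$down[[i]] <- list(w1 = bw1$dw, b1 = bw1$db, w2 = bw2$dw, b2 = bw2$db)
    dx <- bw1$dx
  }
  g
}

#' Sample congruent image/mask training patches
#'
#' Draws `n` random patches uniformly over images and valid top-left
#' offsets; image and mask patches are cut congruently. Deterministic per
#' seed.
#'
#' @param ts a [training_set()].
#' @param n number of patches.
#' @param patch_px patch side in px.
#' @param seed RNG seed.
#' @return a `patch_batch`: `patches` and `targets` arrays of dimension
#'   `(patch_px, patch_px, 1, n)`, plus `source_indices` and `offsets`.
#' @export
sample_patches <- function(ts, n, patch_px, seed = 1L) {
  stopifnot(inherits(ts, "training_set"), n >= 1)
  sides <- vapply(ts$images, function(m) min(dim(m)), 0)
  if (patch_px > min(sides)) {
    stop("patch_px (", patch_px, ") exceeds the smallest image side (",
         min(sides), ")", call. = FALSE)
  }
  with_seed(seed, {
    k <- length(ts$images)
    src <- sample.int(k, n, replace = TRUE)
    patches <- array(0, c(patch_px, patch_px, 1, n))
    targets <- array(0, c(patch_px, patch_px, 1, n))
    offs <- matrix(0L, n, 2)
    for (j in seq_len(n)) {
      im <- ts$images[[src[j]]]; mk <- ts$masks[[src[j]]]
      r0 <- sample.int(nrow(im) - patch_px + 1L, 1L)
      c0 <- sample.int(ncol(im) - patch_px + 1L, 1L)
      patches[, , 1, j] <- im[r0:(r0 + patch_px - 1L), c0:(c0 + patch_px - 1L)]
      targets[, , 1, j] <- mk[r0:(r0 + patch_px - 1L), c0:(c0 + patch_px - 1L)]
      offs[j, ] <- c(r0, c0)
    }
    structure(list(patches = patches, targets = targets,
                   source_indices = src, offsets = offs),
              class = "patch_batch")
  })
}

#' Construct a validated training set
#'
#' @param images list of numeric matrices in \[0,1\] (preprocessed analysis
#'   frames).
#' @param masks list of strictly binary matrices, shape-matched 1:1.
#' @param provenance `"synthetic"` or `"drive_layout"`.
#' @return a `training_set`.
#' @export
training_set <- function(images, masks,
                         provenance = c("synthetic", "drive_layout")) {
  provenance <- match.arg(provenance)
  if (length(images) != length(masks) || length(images) == 0) {
    stop("images and masks must be non-empty and paired 1:1", call. = FALSE)
  }
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), dim(masks[[i]]))) {
      stop("image/mask shape mismatch at pair ", i, call. = FALSE)
    }
    if (!all(masks[[i]] %in% c(0, 1))) {
      stop("mask ", i, " is not strictly binary", call. = FALSE)
    }
  }
  structure(list(images = images, masks = masks, provenance = provenance),
            class = "training_set")
}

bce_loss_grad <- function(prob, target) {
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  n <- length(p)
  loss <- -mean(target * log(p) + (1 - target) * log(1 - p))
  dz <- (prob - target) / n   # gradient w.r.t. pre-sigmoid logits
  list(loss = loss, dz = dz)
}

# flatten nested gradient/parameter lists congruently (structural order;
# both lists are built with identical field order)
flatten_params <- function(p) unlist(p, use.names = FALSE)

# inverse of flatten_params: pour a flat vector back into the shape of a
# template parameter list, restoring array dims
unflatten_like <- function(flat, tmpl) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) {
      for (k in seq_along(node)) node[[k]] <- walk(node[[k]])
      node
    } else {
      n <- length(node)
      v <- flat[pos + seq_len(n)]
      pos <<- pos + n
      dim(v) <- dim(node)
      v
    }
  }
  walk(tmpl)
}

#' Train a U-Net on sampled patches
#'
#' Minimizes per-pixel binary cross-entropy on randomly sampled patches with
#' the Adam optimizer. Fully seeded: the same seed, data and
#' hyperparameters reproduce the loss trace exactly.
#'
#' @param model a [build_unet()] model.
#' @param ts a [training_set()].
#' @param n_patches number of random patches to sample.
#' @param batch_size minibatch size.
#' @param epochs training epochs over the sampled patches.
#' @param lr Adam learning rate.
#' @param seed RNG seed for patch sampling and shuffling.
#' @param verbose print per-epoch loss.
#' @return the trained model, with `loss_trace` (mean loss per epoch).
#' @export
unet_train <- function(model, ts, n_patches = 2000L, batch_size = 16L,
                       epochs = 5L, lr = 1e-3, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "unet"))
  batch <- sample_patches(ts, n_patches, model$spec$patch_px, seed = seed)
  n <- n_patches
  adam_m <- NULL; adam_v <- NULL; tstep <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + ep, sample.int(n))
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1, n)]
      xb <- batch$patches[, , , sel, drop = FALSE]
      tb <- batch$targets[, , , sel, drop = FALSE]
      fw <- unet_forward(model, xb, keep = TRUE)
      lg <- bce_loss_grad(fw$prob, tb)
      if (!is.finite(lg$loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      }
      losses <- c(losses, lg$loss)
      g <- unet_backward(model, fw$cache, lg$dz)
      gf <- flatten_params(g)
      pf <- flatten_params(model$params)
      if (is.null(adam_m)) { adam_m <- gf * 0; adam_v <- gf * 0 }
      tstep <- tstep + 1
      adam_m <- b1 * adam_m + (1 - b1) * gf
      adam_v <- b2 * adam_v + (1 - b2) * gf^2
      mhat <- adam_m / (1 - b1^tstep)
      vhat <- adam_v / (1 - b2^tstep)
      pf <- pf - lr * mhat / (sqrt(vhat) + eps)
      model$params <- unflatten_like(pf, model$params)
    }
    trace[ep] <- mean(losses)
    if (verbose) message("epoch ", ep, ": loss ", signif(trace[ep], 5))
  }
  model$trained <- TRUE
  model$loss_trace <- trace
  model
}

#' Tiled full-frame inference with overlap averaging
#'
#' Tiles the image with overlapping patches at the given stride (the final
#' row/column of tiles is clamped to the image edge so coverage is
#' complete) and averages per-pixel probabilities over all covering patches.
#'
#' @param model a trained `unet` (set `allow_untrained = TRUE` for stub
#'   models in tests).
#' @param img numeric matrix (analysis frame) in \[0,1\].
#' @param stride tile stride in px, at most the patch size.
#' @param allow_untrained permit inference with an untrained model.
#' @param chunk number of patches per forward pass (memory control).
#' @return a `probability_map` (numeric matrix in \[0,1\] with attribute
#'   `stride`).
#' @export
predict_map <- function(model, img, stride = model$spec$patch_px %/% 2L,
                        allow_untrained = FALSE, chunk = 64L) {
  stopifnot(inherits(model, "unet"))
  if (!model$trained && !allow_untrained) {
    stop("model is untrained; train it or pass allow_untrained = TRUE",
         call. = FALSE)
  }
  patch <- model$spec$patch_px
  if (stride > patch) stop("stride must not exceed the patch size",
                           call. = FALSE)
  x <- unclass(img)
  H <- nrow(x); W <- ncol(x)
  if (H < patch || W < patch) stop("image smaller than the patch size",
                                   call. = FALSE)
  starts <- function(side) unique(c(seq(1L, side - patch + 1L, by = stride),
                                    side - patch + 1L))
  rs <- starts(H); cs <- starts(W)
  grid <- expand.grid(r = rs, c = cs)
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (start in seq(1, nrow(grid), by = chunk)) {
    sel <- start:min(start + chunk - 1, nrow(grid))
    xb <- array(0, c(patch, patch, 1, length(sel)))
    for (j in seq_along(sel)) {
      r0 <- grid$r[sel[j]]; c0 <- grid$c[sel[j]]
      xb[, , 1, j] <- x[r0:(r0 + patch - 1), c0:(c0 + patch - 1)]
    }
    pb <- unet_forward(model, xb)
    for (j in seq_along(sel)) {
      r0 <- grid$r[sel[j]]; c0 <- grid$c[sel[j]]
      rr <- r0:(r0 + patch - 1); cc <- c0:(c0 + patch - 1)
      acc[rr, cc] <- acc[rr, cc] + pb[, , 1, j]
      cnt[rr, cc] <- cnt[rr, cc] + 1
    }
  }
  structure(acc / cnt, class = "probability_map", stride = stride)
}

#' Binarize a probability map
#'
#' @param pmap a [predict_map()] result (or any numeric matrix in \[0,1\]).
#' @param threshold decision threshold in (0, 1); a pixel is vessel iff its
#'   probability is `>= threshold`.
#' @return a `vessel_mask`: 0/1 integer matrix with attribute
#'   `threshold_used`.
#' @export
binarize <- function(pmap, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  m <- matrix(as.integer(unclass(pmap) >= threshold), nrow(pmap), ncol(pmap))
  structure(m, class = c("vessel_mask", class(m)), threshold_used = threshold)
}

#' Build a synthetic training set
#'
#' Generates seeded synthetic fundus scenes, runs each rendered photo
#' through the preprocessing chain, and pairs the filtered analysis frame
#' with the ground-truth mask resampled (nearest neighbour) to the analysis
#' side.
#'
#' @param n_scenes number of scenes.
#' @param seed base seed (scene `i` uses `seed + i`).
#' @param config a [scene_config()].
#' @param pre_config a [preprocess_config()].
#' @return a [training_set()] with provenance `"synthetic"`.
#' @export
synthetic_training_set <- function(n_scenes, seed = 1L,
                                   config = scene_config(),
                                   pre_config = preprocess_config()) {
  images <- vector("list", n_scenes)
  masks <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sc <- generate_scene(seed + i, config)
    out <- render(sc)
    sq <- structure(list(pixels = out$image, side_px = dim(out$image)[1],
                         field_mm = config$field_mm,
                         pixel_scale_mm = config$field_mm / dim(out$image)[1]),
                    class = "square_fundus")
    pp <- preprocess_fundus(sq, pre_config)
    images[[i]] <- unclass(pp$filtered)
    masks[[i]] <- resize_nearest(out$truth$mask, pre_config$analysis_px)
  }
  training_set(images, masks, "synthetic")
}
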