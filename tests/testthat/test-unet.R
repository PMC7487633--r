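# U-Net construction and training machinery: the 23-layer audit, shape
# contracts, patch sampling, loss descent, tiled inference with overlap
# averaging, and binarization.

tiny_spec <- unet_spec(depth = 4L, base_channels = 2L, patch_px = 16L)

# small learnable world: dark tubes on a bright background
tiny_training_set <- function(n = 4, side = 64, seed = 21) {
  imgs <- list(); msks <- list()
  set.seed(seed)
  for (i in seq_len(n)) {
    m <- matrix(0L, side, side)
    r <- sample(10:(side - 10), 1)
    m[(r - 2):(r + 2), ] <- 1L
    c <- sample(10:(side - 10), 1)
    m[, (c - 2):(c + 2)] <- 1L
    img <- 0.7 - 0.35 * m + matrix(rnorm(side^2, 0, 0.03), side)
    imgs[[i]] <- pmin(pmax(img, 0), 1); msks[[i]] <- m
  }
  training_set(imgs, msks, "synthetic")
}

test_that("the built network audits to exactly 23 convolutional layers", {
  m <- build_unet(unet_spec(), seed = 1)
  expect_identical(unet_layer_count(m), 23L)
  expect_identical(unet_layer_count(unet_spec()), 23L)
  # depth != 4 cannot reach 23 layers and is rejected at build time
  expect_error(build_unet(unet_spec(depth = 3, patch_px = 48)),
               "23")
  expect_error(unet_spec(depth = 4, patch_px = 50), "divisible")
})

test_that("forward pass honours shape contracts and the sigmoid range", {
  m <- build_unet(tiny_spec, seed = 2)
  x <- array(runif(16 * 16 * 3), c(16, 16, 1, 3))
  p <- retvas:::unet_forward(m, x)
  expect_equal(dim(p), c(16, 16, 1, 3))
  expect_true(all(p > 0 & p < 1))
  m48 <- build_unet(unet_spec(base_channels = 2L), seed = 2)
  p48 <- retvas:::unet_forward(m48, array(0.5, c(48, 48, 1, 1)))
  expect_equal(dim(p48), c(48, 48, 1, 1))
})

test_that("patch sampling is seeded, in-bounds and congruent", {
  ts <- tiny_training_set()
  b1 <- sample_patches(ts, 200, 16, seed = 7)
  b2 <- sample_patches(ts, 200, 16, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(b1$offsets >= 1 & b1$offsets <= 64 - 16 + 1))
  # congruent cutting: all-ones mask gives all-ones targets
  ts1 <- training_set(list(matrix(0.5, 40, 40)), list(matrix(1L, 40, 40)))
  bo <- sample_patches(ts1, 50, 16, seed = 1)
  expect_true(all(bo$targets == 1))
  expect_error(sample_patches(ts, 10, 100, seed = 1), "exceeds")
})

test_that("training reduces the loss and is reproducible", {
  ts <- tiny_training_set()
  m0 <- build_unet(tiny_spec, seed = 3)
  m1 <- unet_train(m0, ts, n_patches = 200, batch_size = 16, epochs = 2,
                   seed = 5)
  expect_lt(m1$loss_trace[2], m1$loss_trace[1])
  expect_true(m1$trained)
  m2 <- unet_train(m0, ts, n_patches = 200, batch_size = 16, epochs = 2,
                   seed = 5)
  expect_identical(m1$loss_trace, m2$loss_trace)
})

test_that("tiled inference averages overlapping patch predictions", {
  m <- build_unet(tiny_spec, seed = 4)
  m$trained <- TRUE
  img <- matrix(runif(40 * 40), 40)
  pm <- predict_map(m, img, stride = 8)
  expect_equal(dim(pm), c(40, 40))
  expect_true(all(pm >= 0 & pm <= 1))
  # brute force: mean over all covering patches at random pixels
  starts <- function(side, patch, stride)
    unique(c(seq(1, side - patch + 1, by = stride), side - patch + 1))
  rs <- starts(40, 16, 8); cs <- starts(40, 16, 8)
  set.seed(8)
  pts <- cbind(sample(40, 10), sample(40, 10))
  for (k in 1:10) {
    r <- pts[k, 1]; c <- pts[k, 2]
    vals <- c()
    for (r0 in rs) for (c0 in cs) {
      if (r >= r0 && r <= r0 + 15 && c >= c0 && c <= c0 + 15) {
        patch <- img[r0:(r0 + 15), c0:(c0 + 15)]
        pb <- retvas:::unet_forward(m, array(patch, c(16, 16, 1, 1)))
        vals <- c(vals, pb[r - r0 + 1, c - c0 + 1, 1, 1])
      }
    }
    expect_equal(unclass(pm)[r, c], mean(vals), tolerance = 1e-12)
  }
  # a zero-weight stub emits sigmoid(0) = 0.5 everywhere
  stub <- m
  stub$params <- retvas:::unflatten_like(
    rep(0, length(retvas:::flatten_params(m$params))), m$params)
  pm0 <- predict_map(stub, img, stride = 16)
  expect_true(all(pm0 == 0.5))
  # untrained models are refused unless explicitly allowed
  expect_error(predict_map(build_unet(tiny_spec), img), "untrained")
  expect_error(predict_map(m, img, stride = 17), "stride")
})

test_that("binarization is exact, recorded, and monotone in the threshold", {
  pm <- structure(matrix(c(0.4, 0.6, 0.5, 0.2), 2), class = "probability_map")
  expect_true(all(binarize(pm, 0.7) == 0))
  m5 <- binarize(pm, 0.5)
  expect_identical(as.vector(unclass(m5)), c(0L, 1L, 1L, 0L))
  expect_equal(attr(m5, "threshold_used"), 0.5)
  set.seed(9)
  rp <- matrix(runif(400), 20)
  counts <- sapply(seq(0.1, 0.9, 0.1), function(th) sum(binarize(rp, th)))
  expect_true(all(diff(counts) <= 0))
  expect_equal(sum(binarize(rp, 0.3)), sum(rp >= 0.3))  # counting oracle
  expect_error(binarize(rp, 0), "threshold")
  expect_error(binarize(rp, 1), "threshold")
})
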