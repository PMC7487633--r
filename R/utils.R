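# Shared numeric helpers: seeded evaluation, resampling, box filtering,
# bilinear lookup, and a tiny config hash.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Bilinear image resampling
#'
#' Resamples a numeric matrix to a new size using bilinear interpolation with
#' pixel-center alignment (output pixel centers are mapped uniformly onto the
#' input pixel grid).
#'
#' @param mat numeric matrix.
#' @param out_h,out_w output dimensions in pixels.
#' @return numeric matrix of dimension `out_h x out_w`.
#' @export
resize_bilinear <- function(mat, out_h, out_w = out_h) {
  H <- nrow(mat); W <- ncol(mat)
  if (H == out_h && W == out_w) return(mat)
  # map output center i-0.5 (0-based continuous) onto input coordinates
  rs <- (seq_len(out_h) - 0.5) * H / out_h - 0.5
  cs <- (seq_len(out_w) - 0.5) * W / out_w - 0.5
  r0 <- pmin(pmax(floor(rs), 0), H - 1); r1 <- pmin(r0 + 1, H - 1)
  c0 <- pmin(pmax(floor(cs), 0), W - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- pmin(pmax(rs - r0, 0), 1); fc <- pmin(pmax(cs - c0, 0), 1)
  A <- mat[r0 + 1, c0 + 1, drop = FALSE]; B <- mat[r0 + 1, c1 + 1, drop = FALSE]
  C <- mat[r1 + 1, c0 + 1, drop = FALSE]; D <- mat[r1 + 1, c1 + 1, drop = FALSE]
  FR <- matrix(fr, out_h, out_w); FC <- matrix(fc, out_h, out_w, byrow = TRUE)
  A * (1 - FR) * (1 - FC) + B * (1 - FR) * FC + C * FR * (1 - FC) + D * FR * FC
}

# Nearest-neighbour resampling (used for binary masks).
resize_nearest <- function(mat, out_h, out_w = out_h) {
  H <- nrow(mat); W <- ncol(mat)
  if (H == out_h && W == out_w) return(mat)
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * H / out_h), 1), H)
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * W / out_w), 1), W)
  mat[ri, ci, drop = FALSE]
}

# Uniform (box) mean filter with replicate boundary handling, via a
# summed-area table. `size` must be odd.
box_mean <- function(mat, size) {
  stopifnot(size %% 2 == 1)
  p <- (size - 1) / 2
  H <- nrow(mat); W <- ncol(mat)
  ri <- c(rep(1L, p), seq_len(H), rep(H, p))
  ci <- c(rep(1L, p), seq_len(W), rep(W, p))
  pad <- mat[ri, ci, drop = FALSE]
  sat <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed cumulative sums
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  r2 <- seq_len(H) + 2 * p; c2 <- seq_len(W) + 2 * p
  r1 <- seq_len(H) - 1;     c1 <- seq_len(W) - 1
  s <- sat[r2 + 1, c2 + 1, drop = FALSE] - sat[r1 + 1, c2 + 1, drop = FALSE] -
    sat[r2 + 1, c1 + 1, drop = FALSE] + sat[r1 + 1, c1 + 1, drop = FALSE]
  s / (size * size)
}

# Bilinear lookup of continuous (row, col) positions in a numeric matrix;
# positions outside the grid read as `outside`.
bilinear_at <- function(mat, r, c, outside = 0) {
  H <- nrow(mat); W <- ncol(mat)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- rep(outside, length(ri))
    if (any(ok)) out[ok] <- mat[cbind(ri[ok], ci[ok])]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0, c0 + 1) * (1 - fr) * fc +
    val(r0 + 1, c0) * fr * (1 - fc) + val(r0 + 1, c0 + 1) * fr * fc
}

# FNV-1a hash over a character scalar; used to stamp configs into outputs.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep within integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
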