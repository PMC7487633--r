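# Contrast-limited adaptive histogram equalization (Zuiderveld's algorithm):
# per-tile clipped histograms with excess redistribution, uniform target
# distribution, and bilinear interpolation between tile mappings. The image
# is quantized to 2^14 internal gray levels and reflect-padded to a whole
# number of tiles, matching the conventions of the widely used reference
# implementations, so outputs are directly comparable.

NR_OF_GRAY <- 16384L

# Redistribute the clipped histogram excess; `hist` integer vector, `clim`
# integer clip limit. Integer arithmetic throughout.
clahe_clip_histogram <- function(hist, clim) {
  excess_mask <- hist > clim
  n_excess <- sum(hist[excess_mask]) - sum(excess_mask) * clim
  hist[excess_mask] <- clim
  nb <- length(hist)
  bin_incr <- n_excess %/% nb
  upper <- clim - bin_incr
  low_mask <- hist < upper
  n_excess <- n_excess - sum(low_mask) * bin_incr
  hist[low_mask] <- hist[low_mask] + bin_incr
  mid_mask <- hist >= upper & hist < clim
  n_excess <- n_excess + sum(hist[mid_mask]) - sum(mid_mask) * clim
  hist[mid_mask] <- clim
  while (n_excess > 0) {
    prev <- n_excess
    for (start in seq_len(nb)) {
      under <- hist < clim
      step <- max(1, sum(under) %/% n_excess)
      sel <- seq.int(start, nb, by = step)
      sel <- sel[under[sel]]
      if (length(sel)) {
        hist[sel] <- hist[sel] + 1
        n_excess <- n_excess - length(sel)
      }
      if (n_excess <= 0) break
    }
    if (prev == n_excess) break
  }
  hist
}

# cumulate a clipped histogram into an integer LUT onto [0, NR_OF_GRAY - 1]
clahe_map_histogram <- function(hist, kernel_elements) {
  out <- cumsum(hist) * ((NR_OF_GRAY - 1) / kernel_elements)
  as.integer(pmin(out, NR_OF_GRAY - 1))
}

#' Low-level CLAHE on a numeric matrix
#'
#' @param img numeric matrix in \[0,1\].
#' @param kernel tile size `(rows, cols)` in pixels.
#' @param clip_limit normalized clip limit in (0, 1\].
#' @param nbins number of histogram bins.
#' @return numeric matrix in \[0,1\] (rescaled to its own full range, as the
#'   uniform target distribution prescribes). A constant image is returned
#'   unchanged.
#' @export
clahe <- function(img, kernel, clip_limit = 0.01, nbins = 256L) {
  kr <- as.integer(kernel[1]); kc <- as.integer(kernel[length(kernel)])
  H <- nrow(img); W <- ncol(img)
  u16 <- round(img * 65535)
  mn <- min(u16); mx <- max(u16)
  if (mx == mn) return(img)
  G <- matrix(as.integer(round((u16 - mn) / (mx - mn) * (NR_OF_GRAY - 1))),
              H, W)
  ps_r <- kr %/% 2L; ps_c <- kc %/% 2L
  pe_r <- (kr - H %% kr) %% kr + as.integer(ceiling(kr / 2))
  pe_c <- (kc - W %% kc) %% kc + as.integer(ceiling(kc / 2))
  ri <- c(rev(seq.int(2L, ps_r + 1L)), seq_len(H),
          seq.int(H - 1L, by = -1L, length.out = pe_r))
  ci <- c(rev(seq.int(2L, ps_c + 1L)), seq_len(W),
          seq.int(W - 1L, by = -1L, length.out = pe_c))
  G <- G[ri, ci]
  Hp <- nrow(G); Wp <- ncol(G)
  bin_size <- 1L + NR_OF_GRAY %/% nbins
  B <- G %/% bin_size                      # binned gray values, 0-based
  ns_r <- Hp %/% kr - 1L; ns_c <- Wp %/% kc - 1L
  # tile histograms over the grid offset by half a kernel
  rr <- ps_r + seq_len(ns_r * kr); cc <- ps_c + seq_len(ns_c * kc)
  sub <- B[rr, cc]
  br <- (seq_len(ns_r * kr) - 1L) %/% kr
  bc <- (seq_len(ns_c * kc) - 1L) %/% kc
  block_id <- matrix(br, length(rr), length(cc)) * ns_c +
    matrix(bc, length(rr), length(cc), byrow = TRUE)   # C-order block index
  counts <- tabulate(block_id * nbins + sub + 1L, nbins = ns_r * ns_c * nbins)
  hist_mat <- matrix(counts, nrow = nbins)             # bins x blocks
  kernel_elements <- kr * kc
  clim <- max(1L, as.integer(clip_limit * kernel_elements))
  luts <- apply(hist_mat, 2, function(h) {
    clahe_map_histogram(clahe_clip_histogram(h, clim), kernel_elements)
  })                                                    # nbins x blocks
  # assemble padded LUT grid (edge-replicated by one tile on each side)
  NRm <- ns_r + 2L; NCm <- ns_c + 2L
  map_arr <- array(0L, c(NRm, NCm, nbins))
  for (bi in seq_len(ns_r)) for (bj in seq_len(ns_c)) {
    map_arr[bi + 1L, bj + 1L, ] <- luts[, (bi - 1L) * ns_c + bj]
  }
  map_arr[1L, , ] <- map_arr[2L, , ]; map_arr[NRm, , ] <- map_arr[NRm - 1L, , ]
  map_arr[, 1L, ] <- map_arr[, 2L, ]; map_arr[, NCm, ] <- map_arr[, NCm - 1L, ]
  map_flat <- as.numeric(map_arr)
  # bilinear interpolation between the four surrounding tile mappings
  r0 <- seq_len(Hp) - 1L; c0 <- seq_len(Wp) - 1L
  BI <- matrix(r0 %/% kr, Hp, Wp)
  Uf <- matrix((r0 %% kr) / kr, Hp, Wp)
  BJ <- matrix(c0 %/% kc, Hp, Wp, byrow = TRUE)
  Vf <- matrix((c0 %% kc) / kc, Hp, Wp, byrow = TRUE)
  res <- matrix(0, Hp, Wp)
  for (ei in 0:1) for (ej in 0:1) {
    idx <- (BI + ei + 1L) + NRm * (BJ + ej) + as.numeric(NRm) * NCm * B
    wgt <- (if (ei == 0) 1 - Uf else Uf) * (if (ej == 0) 1 - Vf else Vf)
    res <- res + map_flat[idx] * wgt
  }
  res <- trunc(res)
  res <- res[ps_r + seq_len(H), ps_c + seq_len(W)]
  mn2 <- min(res); mx2 <- max(res)
  if (mx2 == mn2) return(matrix(0, H, W))
  (res - mn2) / (mx2 - mn2)
}
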