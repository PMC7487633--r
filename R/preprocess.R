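# Image-conditioning chain for fundus photographs: square crop with
# physical calibration, 565x565 analysis frame, weighted grayscale, CLAHE,
# stretch + gamma, and border mean filtering.

#' Preprocessing configuration
#'
#' Parameters of the image-conditioning chain. Defaults follow the protocol
#' used for smartphone ophthalmoscope photographs: grayscale weights
#' 0.299/0.587/0.114 (all three channels retained so the red-heavy fundus
#' keeps vessel detail), CLAHE on a 25 x 25 tile grid with clip limit 0.01,
#' intensity stretch to \[0,1\] with gamma 0.6, and an 11 x 11 replicate-
#' boundary averaging filter applied to the frame border to suppress the
#' edge artifact amplified by contrast enhancement.
#'
#' @param gray_weights RGB weights for grayscale conversion; must sum to 1.
#' @param clahe_tiles tile grid (rows, cols) for CLAHE.
#' @param clahe_clip normalized CLAHE clip limit in (0, 1\].
#' @param clahe_nbins histogram bins for CLAHE.
#' @param stretch_low_frac,stretch_high_frac saturation fractions defining
#'   the stretch input limits (low and 1-high intensity quantiles).
#' @param gamma gamma exponent applied after stretching.
#' @param mean_filter_size odd size of the uniform averaging filter.
#' @param boundary boundary handling for the filter (only "replicate").
#' @param border_band width in px of the border band the filtered image is
#'   blended into; `Inf` applies the filter globally.
#' @param analysis_px side of the square analysis frame (565 by default).
#' @return a validated `preprocess_config` list.
#' @export
preprocess_config <- function(gray_weights = c(0.299, 0.587, 0.114),
                              clahe_tiles = c(25L, 25L), clahe_clip = 0.01,
                              clahe_nbins = 256L,
                              stretch_low_frac = 0.01,
                              stretch_high_frac = 0.01,
                              gamma = 0.6, mean_filter_size = 11L,
                              boundary = "replicate", border_band = 11L,
                              analysis_px = 565L) {
  if (abs(sum(gray_weights) - 1) > 1e-9) {
    stop("gray_weights must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (clahe_clip <= 0 || clahe_clip > 1) {
    stop("clahe_clip must lie in (0, 1]", call. = FALSE)
  }
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (mean_filter_size %% 2 != 1) {
    stop("mean_filter_size must be odd", call. = FALSE)
  }
  boundary <- match.arg(boundary, "replicate")
  cfg <- list(gray_weights = gray_weights, clahe_tiles = as.integer(clahe_tiles),
              clahe_clip = clahe_clip, clahe_nbins = as.integer(clahe_nbins),
              stretch_low_frac = stretch_low_frac,
              stretch_high_frac = stretch_high_frac, gamma = gamma,
              mean_filter_size = as.integer(mean_filter_size),
              boundary = boundary, border_band = border_band,
              analysis_px = as.integer(analysis_px))
  class(cfg) <- "preprocess_config"
  cfg
}

new_analysis_image <- function(mat, stage) {
  structure(mat, class = c("analysis_image", class(mat)), stage = stage)
}

#' Crop a portrait video frame to a calibrated square
#'
#' Removes the black bands at the top and bottom of a portrait frame
#' (`floor((H-W)/2)` rows from the top, the remainder from the bottom),
#' yielding a W x W square whose physical field of view is `field_mm`
#' (7.0 mm by default), so the pixel scale is `field_mm / W` mm/px.
#'
#' @param frame H x W x 3 numeric array of 8-bit intensities (0..255), with
#'   H >= W.
#' @param field_mm physical side of the square field of view in mm.
#' @return a `square_fundus` object: `pixels` (S x S x 3), `side_px`,
#'   `field_mm`, `pixel_scale_mm`.
#' @export
crop_to_square <- function(frame, field_mm = 7.0) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L) {
    stop("frame must be an H x W x 3 array", call. = FALSE)
  }
  H <- d[1]; W <- d[2]
  if (W > H) {
    stop("frame is landscape (W > H); rotate to portrait before cropping",
         call. = FALSE)
  }
  top <- floor((H - W) / 2)
  rows <- seq_len(W) + top
  out <- frame[rows, , , drop = FALSE]
  structure(list(pixels = out, side_px = W, field_mm = field_mm,
                 pixel_scale_mm = field_mm / W),
            class = "square_fundus")
}

#' Convert a square frame to the grayscale analysis image
#'
#' Resamples to the `analysis_px` square (bilinear) and converts to
#' grayscale with the configured channel weights, scaled to \[0,1\].
#'
#' @param square a [crop_to_square()] result (pixels in 0..255 or \[0,1\]).
#' @param config a [preprocess_config()].
#' @return an `analysis_image` (stage `"gray"`).
#' @export
to_analysis_gray <- function(square, config = preprocess_config()) {
  stopifnot(inherits(square, "square_fundus"))
  px <- square$pixels
  if (max(px) > 1) px <- px / 255
  side <- config$analysis_px
  w <- config$gray_weights
  g <- w[1] * resize_bilinear(px[, , 1], side) +
    w[2] * resize_bilinear(px[, , 2], side) +
    w[3] * resize_bilinear(px[, , 3], side)
  new_analysis_image(clip01(g), "gray")
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE over the configured tile grid (tile kernel is
#' `ceiling(side / tiles)` px) with a normalized clip limit, 256 bins, a
#' uniform target distribution and bilinear interpolation between tile
#' mappings. The implementation follows the standard Zuiderveld algorithm
#' with reflect padding to a whole number of tiles.
#'
#' @param img `analysis_image` in \[0,1\].
#' @param config a [preprocess_config()].
#' @return an `analysis_image` (stage `"clahe"`).
#' @export
clahe_enhance <- function(img, config = preprocess_config()) {
  kernel <- ceiling(dim(img) / as.numeric(config$clahe_tiles))
  out <- clahe(unclass(img), kernel = kernel, clip_limit = config$clahe_clip,
               nbins = config$clahe_nbins)
  new_analysis_image(clip01(out), "clahe")
}

#' Intensity stretch with gamma correction
#'
#' Computes input limits `(lo, hi)` as the `stretch_low_frac` and
#' `1 - stretch_high_frac` intensity quantiles, maps
#' `x -> clip((x - lo)/(hi - lo), 0, 1)^gamma` onto the full output range.
#' The mapping is monotone non-decreasing. A constant image (hi == lo) maps
#' to all zeros with a warning.
#'
#' @param img `analysis_image` in \[0,1\].
#' @param config a [preprocess_config()].
#' @param limits optional explicit `(lo, hi)` input limits overriding the
#'   quantile rule.
#' @return an `analysis_image` (stage `"adjusted"`).
#' @export
stretch_gamma <- function(img, config = preprocess_config(), limits = NULL) {
  x <- unclass(img)
  if (is.null(limits)) {
    limits <- quantile(x, c(config$stretch_low_frac,
                            1 - config$stretch_high_frac), names = FALSE)
  }
  lo <- limits[1]; hi <- limits[2]
  if (hi <= lo) {
    warning("degenerate stretch limits (constant image); returning zeros")
    return(new_analysis_image(array(0, dim(x)), "adjusted"))
  }
  out <- clip01((x - lo) / (hi - lo))^config$gamma
  new_analysis_image(out, "adjusted")
}

#' Border mean filtering
#'
#' Applies the configured uniform averaging filter (11 x 11 by default) with
#' replicate boundary handling. The filtered image is blended into a border
#' band of width `band` px (linear ramp: full filtering at the frame edge,
#' none at depth `band`), suppressing the contrast-enhancement edge artifact
#' while leaving interior vessel contrast untouched. `band = Inf` filters
#' the whole frame.
#'
#' @param img `analysis_image` in \[0,1\].
#' @param config a [preprocess_config()].
#' @param band border band width in px; defaults to the config value.
#' @return an `analysis_image` (stage `"filtered"`).
#' @export
mean_filter <- function(img, config = preprocess_config(),
                        band = config$border_band) {
  x <- unclass(img)
  f <- box_mean(x, config$mean_filter_size)
  if (is.infinite(band)) {
    return(new_analysis_image(clip01(f), "filtered"))
  }
  H <- nrow(x); W <- ncol(x)
  dr <- pmin(seq_len(H) - 1, H - seq_len(H))
  dc <- pmin(seq_len(W) - 1, W - seq_len(W))
  dedge <- pmin(matrix(dr, H, W), matrix(dc, H, W, byrow = TRUE))
  wgt <- pmax(0, 1 - dedge / band)
  new_analysis_image(clip01(wgt * f + (1 - wgt) * x), "filtered")
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: crop (if given a raw portrait frame), grayscale
#' analysis frame, CLAHE, stretch/gamma, border mean filter. All stages are
#' retained for inspection.
#'
#' @param x a raw H x W x 3 frame array, or a `square_fundus`.
#' @param config a [preprocess_config()].
#' @param field_mm field of view used if `x` is a raw frame.
#' @return a `fundus_preproc` list: `square`, `gray`, `clahe`, `adjusted`,
#'   `filtered`, `pixel_scale_mm` (of the analysis frame), `config`.
#' @export
preprocess_fundus <- function(x, config = preprocess_config(),
                              field_mm = 7.0) {
  sq <- if (inherits(x, "square_fundus")) x else crop_to_square(x, field_mm)
  g <- to_analysis_gray(sq, config)
  cl <- clahe_enhance(g, config)
  adj <- stretch_gamma(cl, config)
  fil <- mean_filter(adj, config)
  structure(list(square = sq, gray = g, clahe = cl, adjusted = adj,
                 filtered = fil,
                 pixel_scale_mm = sq$field_mm / config$analysis_px,
                 config = config),
            class = "fundus_preproc")
}
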