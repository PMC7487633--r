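# File formats and configuration: PNG image I/O, ground-truth JSON,
# DRIVE-layout training data, YAML pipeline configuration with a stable
# hash stamped into every output.

#' Read a fundus photograph (PNG/JPEG)
#'
#' @param path image file; PNG is read natively. Returns 8-bit intensities.
#' @return H x W x 3 numeric array in 0..255.
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an image as 8-bit PNG
#'
#' @param img matrix or H x W x 3 array in \[0,1\] (or 0..255).
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  x <- unclass(img)
  if (max(x) > 1) x <- x / 255
  png::writePNG(clip01(x), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(unclass(mask)), nrow(mask)), path)
  invisible(path)
}

#' Read a 0/255 mask PNG back as a 0/1 matrix
#'
#' @param path PNG path.
#' @return integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m >= 0.5), nrow(m))
}

#' Write synthetic ground truth as JSON
#'
#' Branch polylines are exported in 0-based (row, col) pixel coordinates.
#'
#' @param truth the `truth` component of a [render()] result.
#' @param path output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(
    density_percent = truth$density_true,
    av_ratio = truth$av_ratio_true,
    measured_pair = as.list(truth$measured_pair),
    disc = list(center = truth$disc$center - 1, # 0-based
                diameter_px = truth$disc$diameter_px),
    branches = lapply(seq_along(truth$centerlines), function(i) {
      list(label = truth$labels[i], width_px = truth$widths_px[i],
           centerline = unname(truth$centerlines[[i]]) - 1)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DRIVE-layout training directory
#'
#' Expects the standard structure `dir/images/` and `dir/1st_manual/`
#' (an optional `dir/mask/` field-of-view directory is ignored by
#' default), pairing files by sorted order of their leading numeric ids.
#' Only PNG files can be read in this build (the original DRIVE TIFF/GIF
#' variants require converters not available here). Annotation images are
#' binarized at 50% gray when not already binary. Each image is passed
#' through the preprocessing chain to the filtered analysis frame; masks
#' are resampled to the analysis side.
#'
#' @param dir dataset root.
#' @param pre_config a [preprocess_config()].
#' @return a [training_set()] with provenance `"drive_layout"`.
#' @export
read_drive_layout <- function(dir, pre_config = preprocess_config()) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$",
                          full.names = TRUE))
  anns <- sort(list.files(file.path(dir, "1st_manual"), pattern = "\\.png$",
                          full.names = TRUE))
  idof <- function(p) sub("^([0-9]+).*", "\\1", basename(p))
  orphans <- c(setdiff(idof(imgs), idof(anns)), setdiff(idof(anns), idof(imgs)))
  if (length(orphans)) {
    stop("unpaired DRIVE files for ids: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  if (!length(imgs)) stop("no PNG images under ", dir, "/images",
                          call. = FALSE)
  images <- vector("list", length(imgs))
  masks <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    frame <- read_fundus(imgs[i])
    sq <- if (dim(frame)[1] == dim(frame)[2]) {
      structure(list(pixels = frame, side_px = dim(frame)[1], field_mm = 7.0,
                     pixel_scale_mm = 7.0 / dim(frame)[1]),
                class = "square_fundus")
    } else crop_to_square(frame)
    pp <- preprocess_fundus(sq, pre_config)
    images[[i]] <- unclass(pp$filtered)
    m <- png::readPNG(anns[i])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m <- matrix(as.integer(m >= 0.5), nrow(m))   # binarize at 50% gray
    masks[[i]] <- resize_nearest(m, pre_config$analysis_px)
  }
  training_set(images, masks, "drive_layout")
}

#' Pipeline configuration
#'
#' Bundles the preprocessing configuration, the U-Net specification and
#' training hyperparameters, the binarization threshold, and the seeds.
#' Round-trips losslessly through YAML; every pipeline run stamps the
#' config hash into its outputs.
#'
#' @param preprocess a [preprocess_config()].
#' @param unet a [unet_spec()].
#' @param train list of training hyperparameters (`n_patches`,
#'   `batch_size`, `epochs`, `lr`).
#' @param threshold probability binarization threshold.
#' @param stride inference tile stride in px.
#' @param seed base RNG seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            unet = unet_spec(),
                            train = list(n_patches = 2000L, batch_size = 16L,
                                         epochs = 5L, lr = 1e-3),
                            threshold = 0.5, stride = NULL, seed = 1L) {
  if (is.null(stride)) stride <- unet$patch_px %/% 2L
  cfg <- list(preprocess = preprocess, unet = unet, train = train,
              threshold = threshold, stride = as.integer(stride),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Stable hash of a configuration
#'
#' @param cfg any serializable configuration object.
#' @return 8-hex-digit hash string.
#' @export
config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE,
                              digits = NA))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Save / load a pipeline configuration as YAML
#'
#' `load_config(save_config(cfg))` reproduces the configuration (classes
#' are re-validated through the constructors).
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` the path; `load_config` the configuration.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    preprocess = do.call(preprocess_config, raw$preprocess[
      setdiff(names(raw$preprocess), character(0))]),
    unet = do.call(unet_spec, raw$unet[c("depth", "base_channels", "patch_px",
                                         "in_channels")]),
    train = raw$train, threshold = raw$threshold, stride = raw$stride,
    seed = raw$seed)
}
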