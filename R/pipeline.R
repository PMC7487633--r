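# End-to-end pipeline: preprocess -> segment -> density (and, with an
# annotation, caliber + A/V) for each photo; with two acquisitions per eye,
# test-retest repeatability reports. Each run writes a manifest with the
# config hash so results are auditable.

#' Run the full analysis pipeline over a set of photographs
#'
#' For every input photo: preprocessing to the analysis frame, U-Net
#' probability map, binarization, vessel density; when an annotation (disc
#' geometry plus arteriole/venule seed points) is supplied, the A/V caliber
#' ratio as well. When `eye_id` labels mark two acquisitions per eye,
#' test-retest repeatability reports are produced for each metric.
#' Per-file failures are logged and skipped; the run fails only if all
#' files fail.
#'
#' @param inputs character vector of image paths, or a list of in-memory
#'   H x W x 3 arrays (values 0..255 or \[0,1\]).
#' @param model a trained [build_unet()] model.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @param annotations optional list (one element per input, or `NULL`
#'   entries) with `disc`, `arteriole_seed`, `venule_seed` in analysis-frame
#'   coordinates.
#' @param eye_id optional vector marking which eye each input belongs to.
#' @return a `pipeline_run`: `metrics` data frame (one row per photo),
#'   `repeatability` (list of [repeat_report()]s, possibly empty),
#'   `manifest`, and per-photo `details`.
#' @export
run_pipeline <- function(inputs, model, config = pipeline_config(),
                         out_dir = NULL, annotations = NULL, eye_id = NULL) {
  stopifnot(inherits(model, "unet"))
  n <- length(inputs)
  if (n == 0) stop("no inputs", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  names_in <- if (is.character(inputs)) basename(inputs) else
    sprintf("image_%03d", seq_len(n))
  hash <- config_hash(config)
  rows <- list(); details <- list(); outputs <- character(0)
  failures <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      frame <- if (is.character(inputs)) read_fundus(inputs[i]) else inputs[[i]]
      sq <- if (dim(frame)[1] == dim(frame)[2]) {
        structure(list(pixels = frame, side_px = dim(frame)[1],
                       field_mm = 7.0,
                       pixel_scale_mm = 7.0 / dim(frame)[1]),
                  class = "square_fundus")
      } else crop_to_square(frame)
      pp <- preprocess_fundus(sq, config$preprocess)
      pmap <- predict_map(model, pp$filtered, stride = config$stride)
      mask <- binarize(pmap, config$threshold)
      dens <- vessel_density(mask)
      av <- NA_real_
      if (!is.null(annotations) && !is.null(annotations[[i]])) {
        avr <- tryCatch(
          measure_av(mask, annotations[[i]],
                     pixel_scale_mm = pp$pixel_scale_mm),
          error = function(e) {
            message("A/V measurement failed for ", names_in[i], ": ",
                    conditionMessage(e))
            NULL
          })
        if (!is.null(avr)) av <- avr$av_ratio
      }
      if (!is.null(out_dir)) {
        base <- tools::file_path_sans_ext(names_in[i])
        p1 <- file.path(out_dir, paste0(base, "_prob.png"))
        p2 <- file.path(out_dir, paste0(base, "_mask.png"))
        write_image_png(unclass(pmap), p1)
        write_mask_png(mask, p2)
        outputs <- c(outputs, p1, p2)
      }
      list(row = data.frame(input = names_in[i],
                            eye_id = if (is.null(eye_id)) NA else eye_id[i],
                            density_percent = dens$density_percent,
                            av_ratio = av,
                            threshold = config$threshold,
                            config_hash = hash,
                            stringsAsFactors = FALSE),
           detail = list(mask = mask, density = dens))
    }, error = function(e) {
      message("pipeline failed for ", names_in[i], ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, names_in[i]) else {
      rows[[length(rows) + 1L]] <- res$row
      details[[names_in[i]]] <- res$detail
    }
  }
  if (!length(rows)) {
    stop("all ", n, " inputs failed: ", paste(failures, collapse = ", "),
         call. = FALSE)
  }
  metrics <- do.call(rbind, rows)
  repeatability <- list()
  if (!is.null(eye_id)) {
    ok_eyes <- names(which(table(metrics$eye_id) == 2))
    if (length(ok_eyes) >= 2) {
      first <- metrics[!duplicated(metrics$eye_id) &
                         metrics$eye_id %in% ok_eyes, ]
      second <- metrics[duplicated(metrics$eye_id) &
                          metrics$eye_id %in% ok_eyes, ]
      second <- second[match(first$eye_id, second$eye_id), ]
      repeatability$density_percent <- repeat_report(
        repeat_pair(first$density_percent, second$density_percent,
                    "density_percent"))
      if (all(is.finite(first$av_ratio)) && all(is.finite(second$av_ratio))) {
        repeatability$av_ratio <- repeat_report(
          repeat_pair(first$av_ratio, second$av_ratio, "av_ratio"))
      }
    }
  }
  manifest <- list(inputs = names_in, failures = failures,
                   config_hash = hash,
                   package_version = as.character(packageVersion("retvas")),
                   outputs = outputs,
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    manifest$outputs <- c(manifest$outputs,
                          file.path(out_dir, "metrics.csv"),
                          file.path(out_dir, "manifest.json"))
  }
  structure(list(metrics = metrics, repeatability = repeatability,
                 manifest = manifest, details = details),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", nrow(x$metrics), "photos analysed",
      if (length(x$manifest$failures))
        paste0("(", length(x$manifest$failures), " failed)") else "", "\n")
  cat("  config hash:", x$manifest$config_hash, "\n")
  cat(sprintf("  density %%: %s\n",
              paste(sprintf("%.3f", x$metrics$density_percent),
                    collapse = ", ")))
  if (any(is.finite(x$metrics$av_ratio))) {
    cat(sprintf("  A/V ratio: %s\n",
                paste(sprintf("%.3f", x$metrics$av_ratio), collapse = ", ")))
  }
  for (rep in x$repeatability) print(rep)
  invisible(x)
}
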