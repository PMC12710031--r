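#' Pipeline run configuration
#'
#' @param input_dir Directory of input frames (PNG/TIFF/JPEG).
#' @param template_path Path to the chart template crop.
#' @param output_dir Output directory (created if missing).
#' @param overexposure_threshold Channel value above which a patch is
#'   excluded from the CCM fit; default 250.
#' @param min_patches Minimum patches for the fit; default 6.
#' @param inner_area_fraction Patch-area fraction sampled; default 0.8.
#' @param length_expand,width_expand Mask expansion fractions per
#'   direction; defaults 0.3 and 0.5.
#' @param delta_e_threshold Segmentation threshold; default 10.
#' @param detection [detection_params()].
#' @param chart_variant Chart variant id.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, template_path, output_dir,
                       overexposure_threshold = 250, min_patches = 6L,
                       inner_area_fraction = 0.8,
                       length_expand = 0.3, width_expand = 0.5,
                       delta_e_threshold = 10,
                       detection = detection_params(),
                       chart_variant = "classic-srgb-d65",
                       seed = 1L) {
  stopifnot(inner_area_fraction > 0, inner_area_fraction <= 1,
            length_expand >= 0, width_expand >= 0,
            overexposure_threshold > 0, overexposure_threshold <= 255)
  structure(list(input_dir = input_dir, template_path = template_path,
                 output_dir = output_dir,
                 overexposure_threshold = overexposure_threshold,
                 min_patches = as.integer(min_patches),
                 inner_area_fraction = inner_area_fraction,
                 length_expand = length_expand, width_expand = width_expand,
                 delta_e_threshold = delta_e_threshold,
                 detection = detection, chart_variant = chart_variant,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the end-to-end correction pipeline
#'
#' For every frame in the input directory: detect the chart, sample the
#' 24 patches, flag overexposed patches, fit the per-frame correction
#' matrix, write the corrected frame (PNG), the chart mask (PNG), the
#' detection diagnostics and the CCM (JSON), and record the chart patch
#' ΔE00 before and after correction. Frames whose chart cannot be
#' detected are recorded as failed and the run continues.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report`: `$frames` (per-image data frame with
#'   detection diagnostics and before/after ΔE), `$n_failed`,
#'   `$mean_delta_e_original`, `$mean_delta_e_corrected`. Written as
#'   `report.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  chart <- load_reference_chart(config$chart_variant)
  template <- read_rgb(config$template_path)
  params <- config$detection
  template_features <- detect_keypoints(template, params)

  files <- sort(list.files(config$input_dir,
                           pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("no input images found in ", config$input_dir)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    id <- tools::file_path_sans_ext(basename(files[i]))
    row <- data.frame(image_id = id, success = FALSE,
                      n_matches = NA_integer_, inlier_ratio = NA_real_,
                      n_patches_used = NA_integer_,
                      delta_e_original = NA_real_,
                      delta_e_corrected = NA_real_,
                      reason = NA_character_)
    res <- tryCatch({
      image <- read_rgb(files[i])
      det <- detect_chart(image, template, chart, params,
                          template_features = template_features)
      write_detection_json(det, file.path(config$output_dir,
                                          paste0(id, "_detection.json")))
      if (!det$success) {
        row$reason <- det$reason
        warning("frame ", id, ": chart not detected (", det$reason, ")")
      } else {
        polys <- locate_patches(det, chart, config$inner_area_fraction)
        obs <- extract_patch_colors(image, polys, image_id = id)
        obs <- filter_overexposed(obs, config$overexposure_threshold)
        excl <- obs$patches$index[!obs$patches$included]
        if (length(excl))
          warning("frame ", id, ": excluded overexposed patches ",
                  paste(excl, collapse = ", "))
        ccm <- fit_ccm(obs, chart, min_patches = config$min_patches)
        corrected <- apply_ccm(image, ccm)
        mask <- make_mask(det, config$length_expand, config$width_expand,
                          dim(image)[1:2], chart)
        write_rgb(corrected, file.path(config$output_dir,
                                       paste0(id, "_corrected.png")))
        write_mask(mask$mask, file.path(config$output_dir,
                                        paste0(id, "_mask.png")))
        write_ccm_json(ccm, file.path(config$output_dir,
                                      paste0(id, "_ccm.json")))
        row$success <- TRUE
        row$n_matches <- det$n_keypoint_matches
        row$inlier_ratio <- det$inlier_ratio
        row$n_patches_used <- length(ccm$patches_used)
        row$delta_e_original <- mean_patch_delta_e(obs, chart)
        row$delta_e_corrected <- mean_patch_delta_e(obs, chart, ccm)
      }
      row
    }, error = function(e) {
      row$reason <- conditionMessage(e)
      warning("frame ", id, " failed: ", conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }

  frames <- do.call(rbind, rows)
  report <- structure(list(
    frames = frames,
    n_failed = sum(!frames$success),
    mean_delta_e_original = mean(frames$delta_e_original, na.rm = TRUE),
    mean_delta_e_corrected = mean(frames$delta_e_corrected, na.rm = TRUE)
  ), class = "pipeline_report")

  jsonlite::write_json(unclass(report),
                       file.path(config$output_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", na = "null")
  if (all(!frames$success))
    stop("pipeline failed: no frame succeeded")
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline: %d frames, %d failed; chart dE %.2f -> %.2f\n",
              nrow(x$frames), x$n_failed,
              x$mean_delta_e_original, x$mean_delta_e_corrected))
  invisible(x)
}

write_detection_json <- function(det, path) {
  jsonlite::write_json(list(
    success = det$success,
    homography = if (det$success) det$homography else NULL,
    corners_image = if (det$success) det$corners_image else NULL,
    n_keypoint_matches = det$n_keypoint_matches,
    n_inliers = det$n_inliers,
    inlier_ratio = det$inlier_ratio,
    reason = det$reason
  ), path, digits = NA, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
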