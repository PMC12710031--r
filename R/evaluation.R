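#' Per-pixel ΔE map against a reference color
#'
#' Converts every pixel to Lab and computes CIEDE2000 against a single
#' reference Lab color (e.g. the ground-truth leaf color from a
#' colorimeter).
#'
#' @param image RGB array (0--255).
#' @param reference Lab triple (`L`, `a`, `b`).
#' @return Numeric `h x w` matrix of ΔE00 values.
#' @export
delta_e_map <- function(image, reference) {
  stopifnot(length(dim(image)) == 3L, length(reference) == 3L)
  d <- dim(image)
  lab <- srgb_to_lab(flatten_rgb(image))
  matrix(ciede2000(lab, matrix(reference, 1L)), d[1], d[2])
}

#' Threshold a ΔE map into a segmentation
#'
#' Selects pixels whose color error is strictly below the threshold
#' (ΔE below 10 by default approximates the region whose color matches
#' the reference).
#'
#' @param delta_map ΔE raster from [delta_e_map()].
#' @param threshold Strict upper bound on ΔE; default 10.
#' @return A `segmentation_result`: `$map` (logical matrix),
#'   `$threshold`, `$n_selected`, `$n_total`.
#' @export
segment_by_threshold <- function(delta_map, threshold = 10) {
  stopifnot(is.matrix(delta_map), threshold > 0)
  map <- delta_map < threshold
  structure(list(map = map, threshold = threshold,
                 n_selected = sum(map), n_total = length(map)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation (dE < %g): %d / %d pixels (%.1f%%)\n",
              x$threshold, x$n_selected, x$n_total,
              100 * x$n_selected / x$n_total))
  invisible(x)
}

#' Overlap ratio of a predicted region with ground truth
#'
#' Pixelwise logical AND of the predicted and ground-truth masks,
#' divided by the ground-truth area.
#'
#' @param predicted Logical matrix (or `segmentation_result`).
#' @param truth Logical matrix, non-empty.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_ratio <- function(predicted, truth) {
  if (inherits(predicted, "segmentation_result")) predicted <- predicted$map
  stopifnot(is.matrix(predicted), is.matrix(truth),
            all(dim(predicted) == dim(truth)))
  n_truth <- sum(truth)
  if (n_truth == 0L) stop("ground-truth region is empty")
  sum(predicted & truth) / n_truth
}

#' Cross-camera color consistency report
#'
#' Treats each patch's measurements across cameras as a cluster in Lab
#' space. For every camera, a CCM is fitted on its own observations and
#' the per-patch ΔE00 against the reference is computed before and after
#' correction; for every patch, the mean intracluster distance across
#' cameras is computed before and after. Lower intracluster distance
#' means better cross-sensor consistency.
#'
#' @param per_camera_observations Named list (>= 2) of
#'   `patch_observations`, one per camera.
#' @param chart A `reference_chart`.
#' @param min_patches Passed to [fit_ccm()].
#' @return A list: `$per_camera` (data frame: camera, mean ΔE original /
#'   corrected), `$per_patch` (data frame: patch index, intracluster
#'   distance original / corrected), `$summary` (grand means).
#' @export
camera_consistency_report <- function(per_camera_observations,
                                      chart = load_reference_chart(),
                                      min_patches = 6L) {
  obs <- per_camera_observations
  if (length(obs) < 2L) stop("need observations from at least 2 cameras")
  if (is.null(names(obs)) || any(!nzchar(names(obs))))
    names(obs) <- paste0("camera", seq_along(obs))
  ref_lab <- chart_reference_lab(chart)

  lab_orig <- lab_corr <- vector("list", length(obs))
  cam_rows <- vector("list", length(obs))
  for (i in seq_along(obs)) {
    ccm <- fit_ccm(obs[[i]], chart, min_patches = min_patches)
    rgb_o <- observed_rgb(obs[[i]], included_only = FALSE)
    rgb_c <- correct_observations(obs[[i]], ccm)
    lab_orig[[i]] <- srgb_to_lab(rgb_o)
    lab_corr[[i]] <- srgb_to_lab(rgb_c)
    cam_rows[[i]] <- data.frame(
      camera = names(obs)[i],
      mean_delta_e_original = mean(ciede2000(lab_orig[[i]], ref_lab)),
      mean_delta_e_corrected = mean(ciede2000(lab_corr[[i]], ref_lab)))
  }

  per_patch <- data.frame(
    index = 1:24,
    intracluster_original = vapply(1:24, function(p)
      intracluster_distance(t(vapply(lab_orig, function(m) m[p, ],
                                     numeric(3)))), numeric(1)),
    intracluster_corrected = vapply(1:24, function(p)
      intracluster_distance(t(vapply(lab_corr, function(m) m[p, ],
                                     numeric(3)))), numeric(1)))

  per_camera <- do.call(rbind, cam_rows)
  list(per_camera = per_camera, per_patch = per_patch,
       summary = data.frame(
         mean_delta_e_original = mean(per_camera$mean_delta_e_original),
         mean_delta_e_corrected = mean(per_camera$mean_delta_e_corrected),
         mean_intracluster_original = mean(per_patch$intracluster_original),
         mean_intracluster_corrected = mean(per_patch$intracluster_corrected)))
}

#' Plot-level color summary
#'
#' Mean RGB and Lab over a plot region, plus the normalized (R + B)
#' chromaticity index `(R + B) / (R + G + B)` computed on the plot-mean
#' channels — a chlorophyll-sensitive maturity indicator (chlorophyll
#' absorbs red and blue, so greener, later-maturing plots score lower).
#'
#' @param image RGB array (0--255).
#' @param plot_region Polygon (`n x 2` matrix of pixel coordinates) or
#'   logical mask matrix.
#' @param plot_id Optional identifier.
#' @return A `plot_color_summary`: `$plot_id`, `$mean_rgb`, `$mean_lab`,
#'   `$normalized_r_plus_b`, `$n_pixels`.
#' @export
plot_color_summary <- function(image, plot_region, plot_id = NA_character_) {
  stopifnot(length(dim(image)) == 3L)
  d <- dim(image)
  if (is.matrix(plot_region) && ncol(plot_region) == 2L &&
      !is.logical(plot_region)) {
    px <- pixels_in_polygon(plot_region, d[1], d[2])
  } else {
    mask <- plot_region
    stopifnot(is.matrix(mask), all(dim(mask) == d[1:2]))
    idx <- which(mask != 0, arr.ind = TRUE)
    px <- cbind(row = idx[, 1], col = idx[, 2])
  }
  if (nrow(px) == 0L) stop("plot region contains no pixels")
  lin <- px[, "row"] + (px[, "col"] - 1L) * d[1]
  npx <- d[1] * d[2]
  mean_rgb <- c(R = mean(image[lin]), G = mean(image[lin + npx]),
                B = mean(image[lin + 2L * npx]))
  s <- sum(mean_rgb)
  structure(list(plot_id = plot_id, mean_rgb = mean_rgb,
                 mean_lab = srgb_to_lab(clip255(mean_rgb)),
                 normalized_r_plus_b =
                   if (s > 0) unname((mean_rgb["R"] + mean_rgb["B"]) / s) else NA_real_,
                 n_pixels = nrow(px)),
            class = "plot_color_summary")
}

#' @export
print.plot_color_summary <- function(x, ...) {
  cat(sprintf("plot %s: mean RGB (%.1f, %.1f, %.1f), norm(R+B) %.3f, %d px\n",
              x$plot_id, x$mean_rgb[1], x$mean_rgb[2], x$mean_rgb[3],
              x$normalized_r_plus_b, x$n_pixels))
  invisible(x)
}

#' Regress maturity against a color index
#'
#' Ordinary least squares of maturity date on the normalized (R + B)
#' index (convenience wrapper reporting R² and p value).
#'
#' @param maturity Numeric response (e.g. days to maturity).
#' @param index Numeric predictor (e.g. normalized R + B per plot).
#' @return List: `$fit` (the `lm`), `$r_squared`, `$p_value`.
#' @export
maturity_color_regression <- function(maturity, index) {
  fit <- stats::lm(maturity ~ index)
  sm <- summary(fit)
  pv <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  list(fit = fit, r_squared = sm$r.squared, p_value = pv)
}

#' Compare fixed-reference and in-flight correction strategies
#'
#' For each frame of a series, patch observations are taken from the
#' detected (or truth) chart pose. The in-flight strategy fits a fresh
#' CCM per frame; each fixed-reference strategy fits one CCM on a single
#' reference frame and applies it to every frame. Reported per strategy:
#' the per-frame mean patch ΔE00 and its series mean.
#'
#' @param series Output of [generate_flight_series()], or a list of
#'   `list(frame, truth)` pairs.
#' @param reference_frame_indices Frames to use as fixed references.
#' @param chart A `reference_chart`.
#' @param template Optional template crop for keypoint detection; when
#'   `NULL` the truth homography is used for patch localization.
#' @param params [detection_params()] when detecting.
#' @param inner_area_fraction Patch sampling fraction.
#' @param overexposure_threshold Passed to [filter_overexposed()].
#' @return List: `$per_frame` (data frame: frame, strategy, mean ΔE),
#'   `$summary` (data frame: strategy, mean ΔE, sd), `$uncorrected_mean`.
#' @export
compare_fixed_vs_inflight <- function(series, reference_frame_indices,
                                      chart = load_reference_chart(),
                                      template = NULL,
                                      params = detection_params(),
                                      inner_area_fraction = 0.8,
                                      overexposure_threshold = 250) {
  n <- length(series)
  stopifnot(n >= 1L, all(reference_frame_indices %in% seq_len(n)))

  template_features <- if (!is.null(template))
    detect_keypoints(template, params) else NULL

  obs <- vector("list", n)
  failed <- integer(0)
  for (f in seq_len(n)) {
    frame <- series[[f]]$frame
    det <- if (is.null(template)) {
      detection_from_homography(series[[f]]$truth$homography, chart)
    } else {
      detect_chart(frame, template, chart, params,
                   template_features = template_features)
    }
    if (!isTRUE(det$success)) { failed <- c(failed, f); next }
    polys <- locate_patches(det, chart, inner_area_fraction)
    o <- extract_patch_colors(frame, polys, image_id = paste0("frame", f))
    obs[[f]] <- filter_overexposed(o, overexposure_threshold)
  }
  if (length(failed))
    stop("chart not detectable in frames: ", paste(failed, collapse = ", "))

  strategies <- c("in-flight", paste0("fixed#", reference_frame_indices))
  rows <- list()
  for (f in seq_len(n)) {
    de_in <- mean_patch_delta_e(obs[[f]], chart, fit_ccm(obs[[f]], chart))
    rows[[length(rows) + 1L]] <-
      data.frame(frame = f, strategy = "in-flight", mean_delta_e = de_in)
  }
  for (r in reference_frame_indices) {
    ccm_r <- fit_ccm(obs[[r]], chart)
    for (f in seq_len(n)) {
      rows[[length(rows) + 1L]] <-
        data.frame(frame = f, strategy = paste0("fixed#", r),
                   mean_delta_e = mean_patch_delta_e(obs[[f]], chart, ccm_r))
    }
  }
  per_frame <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(strategies, function(s) {
    v <- per_frame$mean_delta_e[per_frame$strategy == s]
    data.frame(strategy = s, mean_delta_e = mean(v), sd_delta_e = stats::sd(v))
  }))
  uncorrected <- mean(vapply(obs, function(o)
    mean_patch_delta_e(o, chart), numeric(1)))
  list(per_frame = per_frame, summary = summary,
       uncorrected_mean = uncorrected)
}
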