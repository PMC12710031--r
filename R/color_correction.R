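#' Flag overexposed patches
#'
#' Marks patches whose mean value in any RGB channel strictly exceeds
#' the threshold as excluded, so saturated patches do not bias the
#' correction fit. Filtering only flags; no observation is removed.
#'
#' @param observations A `patch_observations`.
#' @param threshold Channel value above which a patch is excluded,
#'   in (0, 255]; default 250.
#' @return The observations with updated `included` flags.
#' @export
filter_overexposed <- function(observations, threshold = 250) {
  stopifnot(inherits(observations, "patch_observations"))
  if (!(threshold > 0 && threshold <= 255))
    stop("threshold must be in (0, 255]")
  p <- observations$patches
  over <- p$R > threshold | p$G > threshold | p$B > threshold
  observations$patches$included <- p$included & !over
  observations
}

#' Fit the bias-augmented color correction matrix
#'
#' Least-squares fit of the 4 x 3 matrix M minimizing
#' `|| [A | 1] M - C ||` over the included patches, where A holds the
#' observed patch RGB means and C the chart's reference RGB values. The
#' constant-1 column is the bias term, absorbing additive offsets. The
#' solution is computed by QR factorization (mathematically the
#' normal-equations solution `(A'A)^{-1} A'C`, but numerically stable).
#'
#' @param observations A `patch_observations` (after
#'   [filter_overexposed()]).
#' @param chart A `reference_chart`.
#' @param min_patches Hard minimum of included patches; default 6. A
#'   warning is issued below 9, where correction accuracy is known to
#'   degrade.
#' @return A `correction_matrix` object: `$M` (4 x 3, rows R, G, B,
#'   bias), `$patches_used`, `$source_image_id`, `$fit_residual_rms`.
#' @export
fit_ccm <- function(observations, chart = load_reference_chart(),
                    min_patches = 6L) {
  stopifnot(inherits(observations, "patch_observations"),
            inherits(chart, "reference_chart"))
  p <- observations$patches
  used <- p$index[p$included]
  n <- length(used)
  if (n < min_patches)
    stop("only ", n, " included patches; at least ", min_patches,
         " are required to fit the correction matrix")
  if (n < 9L)
    warning("fitting on ", n, " patches; accuracy stabilizes with >= 9")

  A <- cbind(observed_rgb(observations, included_only = TRUE), 1)
  C <- chart_reference_rgb(chart)[used, , drop = FALSE]
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("augmented observation matrix is rank deficient; the included ",
         "patches are collinear in RGB space - include more (or less ",
         "collinear) patches")
  M <- qr.coef(qrA, C)
  resid <- A %*% M - C
  structure(list(M = unname(M), patches_used = used,
                 source_image_id = observations$image_id,
                 fit_residual_rms = sqrt(mean(resid^2))),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("4x3 correction matrix (%d patches, residual RMS %.3f)\n",
              length(x$patches_used), x$fit_residual_rms))
  print(round(x$M, 5))
  invisible(x)
}

#' Apply a correction matrix to an image
#'
#' Flattens the frame to an `n x 3` matrix, appends the constant bias
#' column, multiplies by M, clips to `[0, 255]` and reshapes. The image
#' must be on the same 0--255 scale the matrix was fitted on.
#'
#' @param image RGB array (0--255).
#' @param ccm A `correction_matrix`, or a bare 4 x 3 matrix.
#' @return Corrected RGB array, same dimensions.
#' @export
apply_ccm <- function(image, ccm) {
  M <- if (inherits(ccm, "correction_matrix")) ccm$M else as.matrix(ccm)
  if (!all(dim(M) == c(4L, 3L))) stop("correction matrix must be 4 x 3")
  if (!all(is.finite(M))) stop("correction matrix contains non-finite values")
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (max(image) <= 1 && min(image) >= 0 && max(image) > 0)
    stop("image appears to be on a 0-1 scale; the correction matrix is ",
         "fitted on 0-255 values - rescale before applying")
  d <- dim(image)
  flat <- cbind(flatten_rgb(image), 1)
  unflatten_rgb(clip255(flat %*% M), d)
}

#' Correct patch observations with a CCM
#'
#' Applies the bias-augmented matrix to the 24 observed patch means
#' (the patch-level analogue of [apply_ccm()]).
#'
#' @param observations A `patch_observations`.
#' @param ccm A `correction_matrix` or 4 x 3 matrix.
#' @return 24 x 3 matrix of corrected patch RGB, clipped to `[0, 255]`.
#' @export
correct_observations <- function(observations, ccm) {
  M <- if (inherits(ccm, "correction_matrix")) ccm$M else as.matrix(ccm)
  A <- cbind(observed_rgb(observations, included_only = FALSE), 1)
  clip255(A %*% M)
}

#' Mean chart color error of an observation set
#'
#' Mean CIEDE2000 between the (optionally corrected) patch means and the
#' chart's reference Lab values, over all 24 patches.
#'
#' @param observations A `patch_observations`.
#' @param chart A `reference_chart`.
#' @param ccm Optional correction to apply first.
#' @return Scalar mean ΔE00.
#' @export
mean_patch_delta_e <- function(observations, chart = load_reference_chart(),
                               ccm = NULL) {
  rgb <- if (is.null(ccm)) observed_rgb(observations, included_only = FALSE)
         else correct_observations(observations, ccm)
  mean(ciede2000(srgb_to_lab(rgb), chart_reference_lab(chart)))
}

#' Patch-count sensitivity of the correction
#'
#' Quantifies how correction accuracy depends on the number of chart
#' patches used in the fit: for each requested count n, fits a CCM on a
#' subset of n included patches, applies it to all 24 observed patches,
#' and reports the mean ΔE00 against the reference Lab values. With the
#' `"random"` policy each count is replicated with fresh seeded draws;
#' `"saturation-descending"` deterministically keeps the n most
#' saturated patches (max - min channel value of the reference color).
#'
#' @param observations A `patch_observations`.
#' @param chart A `reference_chart`.
#' @param counts Integer vector of patch counts to evaluate.
#' @param selection_order `"random"` or `"saturation-descending"`.
#' @param replicates Replicates per count for the random policy.
#' @param seed Integer seed for the random policy.
#' @param min_patches Passed to [fit_ccm()].
#' @return Data frame with columns `n_patches`, `mean_delta_e` (averaged
#'   over replicates), `sd_delta_e`.
#' @export
patch_count_sensitivity <- function(observations,
                                    chart = load_reference_chart(),
                                    counts = c(6, 9, 12, 15, 18, 21, 24),
                                    selection_order = c("random",
                                                        "saturation-descending"),
                                    replicates = 10L, seed = 1L,
                                    min_patches = 6L) {
  selection_order <- match.arg(selection_order)
  p <- observations$patches
  avail <- p$index[p$included]
  counts <- sort(unique(as.integer(counts)))
  ok <- counts >= min_patches & counts <= length(avail)
  if (any(!ok))
    warning("skipping counts outside [", min_patches, ", ", length(avail),
            "]: ", paste(counts[!ok], collapse = ", "))
  counts <- counts[ok]

  sat_order <- NULL
  if (selection_order == "saturation-descending") {
    ref <- chart_reference_rgb(chart)[avail, , drop = FALSE]
    sat <- apply(ref, 1L, max) - apply(ref, 1L, min)
    sat_order <- avail[order(sat, decreasing = TRUE)]
  }

  rows <- lapply(counts, function(n) {
    des <- if (n == length(avail) || selection_order == "saturation-descending")
      numeric(1)  # deterministic: single replicate
    else numeric(replicates)
    for (r in seq_along(des)) {
      subset_idx <- if (n == length(avail)) avail
        else if (selection_order == "saturation-descending") sat_order[1:n]
        else {
          set.seed(seed + 1000L * r + n)
          sort(sample(avail, n))
        }
      obs_n <- observations
      obs_n$patches$included <- p$included & p$index %in% subset_idx
      ccm <- suppressWarnings(fit_ccm(obs_n, chart, min_patches = min_patches))
      des[r] <- mean_patch_delta_e(observations, chart, ccm)
    }
    data.frame(n_patches = n, mean_delta_e = mean(des),
               sd_delta_e = if (length(des) > 1L) stats::sd(des) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Serialize a correction matrix to JSON
#'
#' @param ccm A `correction_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccm_json <- function(ccm, path) {
  stopifnot(inherits(ccm, "correction_matrix"))
  jsonlite::write_json(list(
    M = ccm$M, patches_used = ccm$patches_used,
    source_image_id = ccm$source_image_id,
    fit_residual_rms = ccm$fit_residual_rms
  ), path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a correction matrix from JSON
#'
#' @param path Path written by [write_ccm_json()].
#' @return A `correction_matrix`.
#' @export
read_ccm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(M = matrix(unlist(x$M), 4L, 3L),
                 patches_used = as.integer(x$patches_used),
                 source_image_id = x$source_image_id,
                 fit_residual_rms = as.numeric(x$fit_residual_rms)),
            class = "correction_matrix")
}
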