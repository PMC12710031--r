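#' Detection parameters
#'
#' Configuration for [detect_chart()]. Matching uses nearest-neighbour
#' descriptor matching with a Lowe ratio test, followed by RANSAC
#' homography estimation.
#'
#' @param min_matches Minimum ratio-test matches to attempt estimation;
#'   default 12.
#' @param ratio Lowe ratio-test threshold; default 0.75.
#' @param ransac_threshold RANSAC reprojection threshold in pixels;
#'   default 3.
#' @param min_inlier_ratio Minimum fraction of matches that must be
#'   homography inliers for a detection to count as a success; default
#'   0.25 (a chart-content check provides the false-positive guard).
#' @param contrast_thr,edge_thr,n_octave_layers Keypoint detector
#'   settings (difference-of-Gaussian contrast threshold, edge-response
#'   ratio, scales per octave).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_matches = 12L, ratio = 0.75,
                             ransac_threshold = 3, min_inlier_ratio = 0.25,
                             contrast_thr = 0.03, edge_thr = 10,
                             n_octave_layers = 3L) {
  structure(list(min_matches = min_matches, ratio = ratio,
                 ransac_threshold = ransac_threshold,
                 min_inlier_ratio = min_inlier_ratio,
                 contrast_thr = contrast_thr, edge_thr = edge_thr,
                 n_octave_layers = n_octave_layers),
            class = "detection_params")
}

# luma grayscale on [0,1] from an RGB 0-255 array
rgb_to_gray <- function(image) {
  (0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]) / 255
}

#' Detect scale/rotation-invariant keypoints in an image
#'
#' Difference-of-Gaussian scale-space extrema with subpixel refinement,
#' dominant-orientation assignment and 128-dimensional gradient-histogram
#' descriptors. Coordinates are continuous, 0-based (pixel `[r, c]` has
#' center `(c - 0.5, r - 0.5)`).
#'
#' @param image RGB array (0--255) or grayscale matrix (0--1).
#' @param params A [detection_params()] list.
#' @return List with `keypoints` (`n x 5`: x, y, size, angle, response)
#'   and `descriptors` (`n x 128`).
#' @export
detect_keypoints <- function(image, params = detection_params()) {
  gray <- if (length(dim(image)) == 3L) rgb_to_gray(image) else image
  .detect_keypoints_cpp(gray,
                        n_octave_layers = as.integer(params$n_octave_layers),
                        contrast_thr = params$contrast_thr,
                        edge_thr = params$edge_thr)
}

#' Match descriptor sets with a Lowe ratio test
#'
#' Brute-force nearest-neighbour matching from `query` descriptors to
#' `train` descriptors; a match is kept when the best distance is below
#' `ratio` times the second-best distance.
#'
#' @param query,train Descriptor matrices (`n x 128`).
#' @param ratio Ratio-test threshold.
#' @return Two-column integer matrix (`query_idx`, `train_idx`).
#' @export
match_descriptors <- function(query, train, ratio = 0.75) {
  if (nrow(query) == 0L || nrow(train) < 2L)
    return(cbind(query_idx = integer(0), train_idx = integer(0)))
  # squared Euclidean distances via the expansion ||a-b||^2
  d2 <- matrix(rowSums(query^2), nrow(query), nrow(train)) +
        matrix(rowSums(train^2), nrow(query), nrow(train), byrow = TRUE) -
        2 * tcrossprod(query, train)
  d2[d2 < 0] <- 0
  keep_q <- integer(0); keep_t <- integer(0)
  for (i in seq_len(nrow(d2))) {
    ord <- order(d2[i, ])[1:2]
    if (sqrt(d2[i, ord[1]]) < ratio * sqrt(d2[i, ord[2]])) {
      keep_q <- c(keep_q, i)
      keep_t <- c(keep_t, ord[1])
    }
  }
  cbind(query_idx = keep_q, train_idx = keep_t)
}

#' Locate the reference chart in a frame
#'
#' Matches keypoints between a chart template crop and the frame,
#' estimates the template-to-image homography with RANSAC, and composes
#' it with the layout-to-template scaling so the returned homography
#' maps chart layout space directly to image pixels. The template is a
#' tight crop of the full chart (border included), as obtained by
#' cropping a representative frame.
#'
#' @param image RGB array (0--255 scale), the frame to search.
#' @param template RGB array (0--255), the chart template crop.
#' @param chart A `reference_chart` (layout geometry); default Classic.
#' @param params A [detection_params()] list.
#' @param template_features Optional precomputed [detect_keypoints()]
#'   result for `template` (reused across frames in batch runs).
#' @return A `chart_detection` object: `$success`, `$homography`
#'   (3 x 3, layout to image), `$corners_image` (4 x 2, TL/TR/BR/BL),
#'   `$n_keypoint_matches`, `$n_inliers`, `$inlier_ratio`, `$reason`
#'   (on failure).
#' @export
detect_chart <- function(image, template, chart = load_reference_chart(),
                         params = detection_params(),
                         template_features = NULL) {
  stopifnot(length(dim(image)) == 3L, length(dim(template)) == 3L)
  feat_t <- if (is.null(template_features)) detect_keypoints(template, params)
            else template_features
  feat_i <- detect_keypoints(image, params)

  fail <- function(reason, n_matches = 0L, n_inliers = 0L) {
    structure(list(success = FALSE, homography = NULL, corners_image = NULL,
                   n_keypoint_matches = n_matches, n_inliers = n_inliers,
                   inlier_ratio = if (n_matches > 0) n_inliers / n_matches else 0,
                   reason = reason),
              class = "chart_detection")
  }

  if (nrow(feat_t$keypoints) < 4L) return(fail("too few template keypoints"))
  if (nrow(feat_i$keypoints) < 4L) return(fail("too few image keypoints"))

  # first attempt at the configured ratio; if it does not yield a
  # validated detection, retry once with a relaxed ratio test (the
  # geometric and chart-content checks below guard against false
  # accepts, so the relaxation only recovers borderline frames)
  for (ratio in unique(c(params$ratio, max(params$ratio, 0.85)))) {
    det <- detect_chart_once(image, feat_t, feat_i, chart, params, ratio,
                             template, fail)
    if (isTRUE(det$success)) return(det)
  }
  det
}

detect_chart_once <- function(image, feat_t, feat_i, chart, params, ratio,
                              template, fail) {
  m <- match_descriptors(feat_t$descriptors, feat_i$descriptors,
                         ratio = ratio)
  n_matches <- nrow(m)
  if (n_matches < params$min_matches)
    return(fail(sprintf("only %d ratio-test matches (minimum %d)",
                        n_matches, params$min_matches), n_matches))

  # coarse pose-consistency prefilter: true matches share a common
  # template-to-image scale ratio and rotation, so keep the dominant
  # mode of (log2 size ratio, angle difference) when it is populated
  keep <- pose_consistent_matches(feat_t$keypoints, feat_i$keypoints, m)
  m_f <- if (sum(keep) >= 8L) m[keep, , drop = FALSE] else m

  src <- feat_t$keypoints[m_f[, "query_idx"], c("x", "y"), drop = FALSE]
  dst <- feat_i$keypoints[m_f[, "train_idx"], c("x", "y"), drop = FALSE]
  rr <- ransac_homography(src, dst, threshold = params$ransac_threshold)
  if (is.null(rr))
    return(fail("no homography consensus", n_matches))
  if (rr$n_inliers / nrow(m_f) < params$min_inlier_ratio)
    return(fail(sprintf("inlier ratio %.2f below minimum %.2f",
                        rr$n_inliers / nrow(m_f), params$min_inlier_ratio),
                n_matches, rr$n_inliers))

  # guided re-matching: project every template keypoint through the
  # current estimate, pair it with the nearest-descriptor image keypoint
  # in a small spatial neighbourhood, and refit on the enlarged set;
  # second pass with a tighter radius polishes the estimate
  rr <- guided_refit(rr, feat_t, feat_i, params, radius = 4)
  rr <- guided_refit(rr, feat_t, feat_i, params, radius = 2)
  if (rr$n_inliers < max(8L, ceiling(params$min_inlier_ratio * n_matches)))
    return(fail(sprintf("only %d homography inliers", rr$n_inliers),
                n_matches, rr$n_inliers))

  H_layout <- rr$H %*% layout_to_template(chart, dim(template))
  corners <- apply_homography(H_layout, chart$corners)
  if (!all(is.finite(corners)) || !quad_is_convex(corners) ||
      polygon_area(corners) < 64)
    return(fail("degenerate chart quadrilateral", n_matches, rr$n_inliers))
  if (!verify_chart_content(image, H_layout, chart))
    return(fail("chart content check failed (neutral-row ordering)",
                n_matches, rr$n_inliers))

  # sub-pixel polish against the known patch-grid edges
  H_layout <- refine_homography_edges(rgb_to_gray(image) * 255, H_layout,
                                      chart)
  corners <- apply_homography(H_layout, chart$corners)
  if (!all(is.finite(corners)) || !quad_is_convex(corners))
    return(fail("degenerate chart quadrilateral after refinement",
                n_matches, rr$n_inliers))

  structure(list(success = TRUE, homography = H_layout,
                 corners_image = corners,
                 n_keypoint_matches = n_matches, n_inliers = rr$n_inliers,
                 inlier_ratio = rr$n_inliers / n_matches, reason = NULL),
            class = "chart_detection")
}

# model-based sub-pixel polish of a layout-to-image homography: sample
# points on the known patch/gap edges, search along each edge normal for
# the image's strongest outward-decreasing gradient (patch -> black gap),
# refine to sub-pixel by parabolic interpolation, and refit the
# homography on the snapped points with trimming
refine_homography_edges <- function(gray, H, chart, iterations = 2,
                                    search = 3, step = 0.5,
                                    min_grad = 2) {
  sp <- edge_sample_points(chart)
  ts <- seq(-search, search, by = step)
  for (it in seq_len(iterations)) {
    p_img <- apply_homography(H, sp$src)
    nvec <- apply_homography(H, sp$src + 0.5 * sp$nrm) - p_img
    len <- sqrt(rowSums(nvec^2))
    ok0 <- is.finite(len) & len > 1e-9
    nvec <- nvec / pmax(len, 1e-9)
    G <- vapply(ts, function(t)
      bilinear_gray(gray, p_img[, 1] + t * nvec[, 1],
                    p_img[, 2] + t * nvec[, 2]),
      numeric(nrow(p_img)))
    m <- ncol(G)
    D <- (G[, 3:m, drop = FALSE] - G[, 1:(m - 2), drop = FALSE]) / (2 * step)
    jst <- apply(D, 1L, which.min)
    n <- nrow(D)
    dmin <- D[cbind(seq_len(n), jst)]
    interior <- jst > 1L & jst < ncol(D)
    dl <- ifelse(interior, D[cbind(seq_len(n), pmax(jst - 1L, 1L))], NA_real_)
    dr <- ifelse(interior, D[cbind(seq_len(n), pmin(jst + 1L, ncol(D)))], NA_real_)
    denom <- dl - 2 * dmin + dr
    delta <- ifelse(is.finite(denom) & abs(denom) > 1e-9,
                    0.5 * (dl - dr) / denom, 0)
    tstar <- ts[jst + 1L] + pmin(pmax(delta, -1), 1) * step
    keep <- ok0 & interior & dmin < -min_grad & abs(tstar) < search - step
    if (sum(keep) < 12L) return(H)
    src <- sp$src[keep, , drop = FALSE]
    dst <- p_img[keep, , drop = FALSE] + tstar[keep] * nvec[keep, , drop = FALSE]
    Hn <- tryCatch(fit_homography(src, dst), error = function(e) NULL)
    if (is.null(Hn) || !all(is.finite(Hn))) return(H)
    err <- sqrt(rowSums((apply_homography(Hn, src) - dst)^2))
    good <- err < max(2 * stats::median(err), 0.5)
    if (sum(good) >= 12L) {
      Hn <- tryCatch(fit_homography(src[good, , drop = FALSE],
                                    dst[good, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(Hn) || !all(is.finite(Hn))) return(H)
    }
    H <- Hn
  }
  H
}

# layout-space sample points on the outward edges of every bright-enough
# patch cell, with outward unit normals
edge_sample_points <- function(chart) {
  ref_gray <- rowMeans(chart_reference_rgb(chart))
  half <- chart$patch_side / 2
  fr <- c(-0.3, 0, 0.3) * chart$patch_side
  src <- NULL; nrm <- NULL
  for (i in 1:24) {
    if (ref_gray[i] < 60) next  # too little contrast against the black gap
    cx <- chart$patches$cx[i]; cy <- chart$patches$cy[i]
    src <- rbind(src,
                 cbind(cx + fr, cy - half), cbind(cx + fr, cy + half),
                 cbind(cx - half, cy + fr), cbind(cx + half, cy + fr))
    nrm <- rbind(nrm,
                 matrix(c(0, -1), 3, 2, byrow = TRUE),
                 matrix(c(0, 1), 3, 2, byrow = TRUE),
                 matrix(c(-1, 0), 3, 2, byrow = TRUE),
                 matrix(c(1, 0), 3, 2, byrow = TRUE))
  }
  list(src = src, nrm = nrm)
}

# bilinear interpolation of a matrix at continuous image coordinates
# (pixel [r, c] has center (c - 0.5, r - 0.5)); clamped at borders
bilinear_gray <- function(gray, x, y) {
  h <- nrow(gray); w <- ncol(gray)
  rr <- pmin(pmax(y + 0.5, 1), h)
  cc <- pmin(pmax(x + 0.5, 1), w)
  r0 <- pmin(floor(rr), h - 1L); c0 <- pmin(floor(cc), w - 1L)
  fr <- rr - r0; fc <- cc - c0
  g00 <- gray[cbind(r0, c0)]; g01 <- gray[cbind(r0, c0 + 1L)]
  g10 <- gray[cbind(r0 + 1L, c0)]; g11 <- gray[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * ((1 - fc) * g00 + fc * g01) + fr * ((1 - fc) * g10 + fc * g11)
}

# keep matches belonging to the dominant (scale ratio, rotation) mode;
# bins of 0.5 in log2 scale ratio and 30 degrees in angle, with the
# mode's 3x3 neighbourhood retained
pose_consistent_matches <- function(kp_t, kp_i, m) {
  if (nrow(m) == 0L) return(logical(0))
  ls <- log2(kp_i[m[, "train_idx"], "size"] / kp_t[m[, "query_idx"], "size"])
  da <- (kp_i[m[, "train_idx"], "angle"] -
         kp_t[m[, "query_idx"], "angle"]) %% 360
  bs <- floor(ls / 0.5)
  ba <- floor(da / 30)
  key <- paste(bs, ba)
  tab <- table(key)
  mode_key <- names(tab)[which.max(tab)]
  parts <- as.integer(strsplit(mode_key, " ")[[1]])
  near_s <- abs(bs - parts[1]) <= 1
  near_a <- pmin((ba - parts[2]) %% 12, (parts[2] - ba) %% 12) <= 1
  near_s & near_a
}

# content verification independent of geometry: the neutral-row patches
# (19 white .. 24 black) have strictly decreasing luminance, an ordering
# preserved by any positive per-channel gain and common offset, so a
# correct homography must reproduce it in the image
# (19 white .. 24 black); additionally, each observed channel across all
# 24 patches must correlate strongly with the reference values, which a
# grid-shifted or otherwise misplaced homography cannot achieve
verify_chart_content <- function(image, H_layout, chart, min_span = 10,
                                 min_cor = 0.75) {
  d <- dim(image)
  obs <- matrix(NA_real_, 24L, 3L)
  for (i in 1:24) {
    quad <- apply_homography(H_layout, patch_layout_quad(chart, i,
                                                         shrink = 0.6))
    if (any(!is.finite(quad)) ||
        any(quad[, 1] < 0 | quad[, 1] > d[2] |
            quad[, 2] < 0 | quad[, 2] > d[1])) return(FALSE)
    v <- mean_rgb_in_polygon(image, quad)
    if (is.null(v)) return(FALSE)
    obs[i, ] <- v[1:3]
  }
  gray <- rowMeans(obs[19:24, ])
  if (!(all(diff(gray) < 0) && (gray[1] - gray[6]) > min_span)) return(FALSE)
  ref <- chart_reference_rgb(chart)
  all(vapply(1:3, function(ch) stats::cor(obs[, ch], ref[, ch]),
             numeric(1)) > min_cor)
}

# densify correspondences around an initial homography estimate and
# refit by least squares; radius in pixels around the projected position
guided_refit <- function(rr, feat_t, feat_i, params, radius = 4) {
  proj <- apply_homography(rr$H, feat_t$keypoints[, c("x", "y"), drop = FALSE])
  ikp <- feat_i$keypoints[, c("x", "y"), drop = FALSE]
  src <- NULL; dst <- NULL
  for (i in seq_len(nrow(proj))) {
    d2 <- (ikp[, 1] - proj[i, 1])^2 + (ikp[, 2] - proj[i, 2])^2
    near <- which(d2 < radius^2)
    if (!length(near)) next
    dd <- rowSums(sweep(feat_i$descriptors[near, , drop = FALSE],
                        2L, feat_t$descriptors[i, ])^2)
    j <- near[which.min(dd)]
    src <- rbind(src, feat_t$keypoints[i, c("x", "y")])
    dst <- rbind(dst, ikp[j, ])
  }
  if (is.null(src) || nrow(src) < 4L) return(rr)
  # refit cascade with tightening inlier thresholds: spurious neighbour
  # pairings sit a few pixels off while true correspondences are
  # subpixel, so shrinking the band isolates the true set
  H <- rr$H
  inl <- rep(TRUE, nrow(src))
  for (thr in c(params$ransac_threshold, 1.5, 1.0)) {
    err <- sqrt(rowSums((apply_homography(H, src) - dst)^2))
    cand <- is.finite(err) & err < thr
    if (sum(cand) < max(8L, 4L)) break
    Hn <- tryCatch(fit_homography(src[cand, , drop = FALSE],
                                  dst[cand, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(Hn) || !all(is.finite(Hn))) break
    H <- Hn
    inl <- cand
  }
  list(H = H, inliers = inl, n_inliers = sum(inl))
}

# affine mapping chart layout space onto the template's pixel frame,
# assuming the template tightly crops the full chart (with border)
layout_to_template <- function(chart, template_dim) {
  sx <- template_dim[2] / chart$physical_width
  sy <- template_dim[1] / chart$physical_height
  b <- chart$border
  matrix(c(sx, 0, sx * b,
           0, sy, sy * b,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' @export
print.chart_detection <- function(x, ...) {
  if (x$success)
    cat(sprintf("chart detected: %d matches, %d inliers (ratio %.2f)\n",
                x$n_keypoint_matches, x$n_inliers, x$inlier_ratio))
  else
    cat("chart not detected:", x$reason, "\n")
  invisible(x)
}

#' Build a detection directly from a known homography
#'
#' Wraps a ground-truth or externally estimated layout-to-image
#' homography as a `chart_detection`, e.g. for synthetic scenes where
#' the pose is known, or for manually identified corners.
#'
#' @param H 3 x 3 layout-to-image homography.
#' @param chart A `reference_chart`.
#' @return A successful `chart_detection`.
#' @export
detection_from_homography <- function(H, chart = load_reference_chart()) {
  corners <- apply_homography(H, chart$corners)
  structure(list(success = TRUE, homography = H, corners_image = corners,
                 n_keypoint_matches = NA_integer_, n_inliers = NA_integer_,
                 inlier_ratio = NA_real_, reason = NULL),
            class = "chart_detection")
}

#' Sampling polygons for the 24 patches
#'
#' Projects each patch's layout cell into image space, shrunk about its
#' center so the sampled area is `inner_area_fraction` of the full patch
#' area (linear side scale `sqrt(inner_area_fraction)`), which keeps the
#' mean clear of boundary noise and neighbouring patches.
#'
#' @param detection A successful `chart_detection`.
#' @param chart A `reference_chart`.
#' @param inner_area_fraction Fraction of each patch's area to sample,
#'   in (0, 1]; default 0.8.
#' @param image_dims Optional `c(height, width)`; when given, polygons
#'   falling outside the image raise an error naming the patches.
#' @return List of 24 `4 x 2` corner matrices, with the projected patch
#'   centers as attribute `"centers"` (24 x 2).
#' @export
locate_patches <- function(detection, chart, inner_area_fraction = 0.8,
                           image_dims = NULL) {
  stopifnot(inherits(detection, "chart_detection"))
  if (!isTRUE(detection$success))
    stop("cannot locate patches: chart detection failed (",
         detection$reason, ")")
  if (!(inner_area_fraction > 0 && inner_area_fraction <= 1))
    stop("inner_area_fraction must be in (0, 1]")
  shrink <- sqrt(inner_area_fraction)
  polys <- lapply(chart$patches$index, function(i)
    apply_homography(detection$homography,
                     patch_layout_quad(chart, i, shrink = shrink)))
  centers <- apply_homography(detection$homography,
                              as.matrix(chart$patches[, c("cx", "cy")]))
  if (!is.null(image_dims)) {
    h <- image_dims[1]; w <- image_dims[2]
    bad <- which(vapply(polys, function(p)
      any(p[, 1] < 0 | p[, 1] > w | p[, 2] < 0 | p[, 2] > h), logical(1)))
    if (length(bad))
      stop("sampling polygons outside the image for patches: ",
           paste(bad, collapse = ", "))
  }
  attr(polys, "centers") <- centers
  polys
}

#' Extract mean patch colors from a frame
#'
#' Per-patch mean RGB over all pixels whose centers fall inside the
#' sampling polygon.
#'
#' @param image RGB array (0--255).
#' @param polygons List of 24 sampling polygons from [locate_patches()].
#' @param image_id Optional identifier recorded with the observations.
#' @return A `patch_observations` object: `$patches` is a data frame
#'   with columns `index, R, G, B, n_pixels, included`; `$image_id`.
#' @export
extract_patch_colors <- function(image, polygons, image_id = NA_character_) {
  stopifnot(length(dim(image)) == 3L, length(polygons) == 24L)
  vals <- matrix(NA_real_, 24L, 4L)
  for (i in seq_along(polygons)) {
    v <- mean_rgb_in_polygon(image, polygons[[i]])
    if (is.null(v))
      stop("sampling polygon for patch ", i, " contains no pixels")
    vals[i, ] <- v
  }
  patch_observations(vals[, 1:3, drop = FALSE], n_pixels = vals[, 4],
                     image_id = image_id)
}

#' Construct a patch observation set
#'
#' @param rgb 24 x 3 matrix of per-patch mean R, G, B (0--255).
#' @param n_pixels Pixels sampled per patch (recycled).
#' @param included Logical inclusion flags (recycled); overexposure
#'   filtering later flips these via [filter_overexposed()].
#' @param image_id Source image identifier.
#' @return A `patch_observations` object.
#' @export
patch_observations <- function(rgb, n_pixels = NA_integer_, included = TRUE,
                               image_id = NA_character_) {
  rgb <- as.matrix(rgb)
  stopifnot(nrow(rgb) == 24L, ncol(rgb) == 3L)
  if (any(rgb < 0 | rgb > 255, na.rm = TRUE))
    stop("patch means must lie in [0, 255]")
  structure(list(
    patches = data.frame(index = 1:24,
                         R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                         n_pixels = rep_len(n_pixels, 24L),
                         included = rep_len(included, 24L)),
    image_id = image_id
  ), class = "patch_observations")
}

#' @export
print.patch_observations <- function(x, ...) {
  cat(sprintf("patch observations (%s): %d/24 included\n",
              x$image_id, sum(x$patches$included)))
  invisible(x)
}

#' Observed RGB matrix of included patches
#'
#' @param observations A `patch_observations`.
#' @param included_only Drop excluded (overexposed) patches.
#' @return Matrix with rownames giving patch indices.
#' @export
observed_rgb <- function(observations, included_only = TRUE) {
  p <- observations$patches
  if (included_only) p <- p[p$included, ]
  m <- as.matrix(p[, c("R", "G", "B")])
  rownames(m) <- p$index
  m
}
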