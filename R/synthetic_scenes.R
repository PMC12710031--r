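# Synthetic aerial scenes with a rendered reference chart and full ground
# truth: chart pose (homography), per-channel gains/offsets, illumination
# level, exposure settings and noise. The generator emulates what the
# correction pipeline sees in the field - a flat soil-like background,
# leaf-like foreground regions, and a 24-patch chart at an arbitrary
# in-frame pose (about 270 x 180 px at unit scale) - so detection,
# extraction and correction can be verified against known truth.

#' Construct a synthetic scene truth
#'
#' All parameters of one synthetic frame. Rendering with identity gains,
#' zero offsets, unit illumination, reference exposure and zero noise
#' reproduces the chart's reference patch colors exactly (up to 8-bit
#' quantization).
#'
#' @param homography 3 x 3 layout-to-image homography for the chart pose.
#' @param dims Frame `c(height, width)` in pixels.
#' @param gains,offsets Per-channel linear distortion: the rendered frame
#'   is `clip(gain * (illumination x ideal) + offset + noise)`.
#' @param illumination Scalar illumination multiplier.
#' @param exposure `exposure_settings`; sensor response scales with
#'   `ISO * t / N^2` relative to the reference condition.
#' @param noise_sigma Additive Gaussian noise SD (8-bit scale).
#' @param background List: `base_color` (RGB), `leaves` (data frame of
#'   ellipse parameters `cx, cy, a, b, angle, R, G, B`).
#' @param seed Integer seed controlling the noise realization.
#' @return A `scene_truth` object.
#' @export
scene_truth <- function(homography, dims = c(360L, 480L),
                        gains = c(1, 1, 1), offsets = c(0, 0, 0),
                        illumination = 1,
                        exposure = reference_exposure(),
                        noise_sigma = 0,
                        background = list(base_color = c(150, 120, 90),
                                          leaves = NULL),
                        seed = 1L) {
  stopifnot(all(dim(homography) == c(3L, 3L)), all(gains > 0),
            illumination > 0, noise_sigma >= 0)
  structure(list(homography = homography, dims = as.integer(dims),
                 gains = gains, offsets = offsets,
                 illumination = illumination, exposure = exposure,
                 noise_sigma = noise_sigma, background = background,
                 seed = as.integer(seed)),
            class = "scene_truth")
}

# relative sensor response of an exposure condition (1 at the reference):
# response scales linearly with ISO and shutter time, inversely with the
# square of the f-number
relative_exposure_gain <- function(exposure, ref = reference_exposure()) {
  (exposure$iso / ref$iso) * (exposure$shutter_s / ref$shutter_s) *
    (ref$aperture_n / exposure$aperture_n)^2
}

#' Sample a random scene truth
#'
#' Draws a chart pose (uniform rotation, scale within `scale_range` of
#' the nominal 270-px geometry, uniform in-frame position, mild
#' perspective jitter), per-channel distortion gains and offsets, and a
#' leaf-like background. When `min_uncorrected_delta_e` is set, gains
#' and offsets are redrawn until the implied uncorrected mean patch
#' ΔE00 meets the floor, guaranteeing distortions worth correcting.
#'
#' @param seed Integer seed (drives every random draw).
#' @param dims Frame `c(height, width)`.
#' @param chart A `reference_chart`.
#' @param scale_range Chart scale range relative to the nominal pose
#'   (long axis `270 * scale` px).
#' @param rotation_range Rotation range in degrees.
#' @param jitter_frac Perspective corner jitter as a fraction of chart
#'   size; default 0.05.
#' @param distort Draw random gains/offsets? If `FALSE`, identity.
#' @param gain_range,offset_range Distortion ranges (uniform draws).
#' @param noise_sigma Additive noise SD; default 1.
#' @param illumination Illumination multiplier; default 1.
#' @param exposure `exposure_settings` for the frame.
#' @param n_leaves Number of leaf-like ellipses; default 8.
#' @param min_uncorrected_delta_e Rejection floor for the uncorrected
#'   mean patch ΔE00 (`NULL` to disable; default 5 when `distort`).
#' @return A `scene_truth`.
#' @export
random_scene_truth <- function(seed, dims = c(360L, 480L),
                               chart = load_reference_chart(),
                               scale_range = c(0.5, 1.0),
                               rotation_range = c(-180, 180),
                               jitter_frac = 0.05,
                               distort = TRUE,
                               gain_range = c(0.5, 1.0),
                               offset_range = c(-10, 10),
                               noise_sigma = 1,
                               illumination = 1,
                               exposure = reference_exposure(),
                               n_leaves = 8L,
                               min_uncorrected_delta_e =
                                 if (distort) 5 else NULL) {
  set.seed(seed)
  h <- dims[1]; w <- dims[2]

  scale <- stats::runif(1, scale_range[1], scale_range[2])
  rot <- stats::runif(1, rotation_range[1], rotation_range[2])
  H <- chart_pose_homography(chart, dims, scale, rot,
                             jitter_frac = jitter_frac)

  gains <- c(1, 1, 1); offsets <- c(0, 0, 0)
  if (distort) {
    repeat {
      gains <- stats::runif(3, gain_range[1], gain_range[2])
      offsets <- stats::runif(3, offset_range[1], offset_range[2])
      if (is.null(min_uncorrected_delta_e)) break
      ref <- chart_reference_rgb(chart)
      mult <- illumination * relative_exposure_gain(exposure)
      distorted <- clip255(sweep(sweep(ref * mult, 2L, gains, `*`),
                                 2L, offsets, `+`))
      de <- mean(ciede2000(srgb_to_lab(distorted), chart_reference_lab(chart)))
      if (de >= min_uncorrected_delta_e) break
    }
  }

  leaves <- data.frame(
    cx = stats::runif(n_leaves, 0, w), cy = stats::runif(n_leaves, 0, h),
    a = stats::runif(n_leaves, 15, 50), b = stats::runif(n_leaves, 8, 30),
    angle = stats::runif(n_leaves, 0, pi),
    R = pmin(pmax(stats::rnorm(n_leaves, 70, 12), 0), 255),
    G = pmin(pmax(stats::rnorm(n_leaves, 115, 15), 0), 255),
    B = pmin(pmax(stats::rnorm(n_leaves, 50, 10), 0), 255)
  )

  scene_truth(H, dims = dims, gains = gains, offsets = offsets,
              illumination = illumination, exposure = exposure,
              noise_sigma = noise_sigma,
              background = list(base_color = c(150, 120, 90), leaves = leaves),
              seed = seed)
}

#' Homography for a chart pose
#'
#' Similarity pose (scale, rotation, center placement) with optional
#' perspective corner jitter, mapping chart layout space to image
#' pixels. At `scale = 1` the chart's long axis spans 270 px, the
#' nominal in-frame geometry. Placement keeps the chart fully inside
#' the frame for any rotation; draws come from the current RNG stream.
#'
#' @param chart A `reference_chart`.
#' @param dims Frame `c(height, width)`.
#' @param scale Chart scale (long axis `270 * scale` px).
#' @param rotation_deg Rotation in degrees.
#' @param center Optional `c(x, y)` chart center in pixels; random
#'   in-frame placement when `NULL`.
#' @param jitter_frac Perspective corner jitter fraction (0 disables).
#' @return 3 x 3 homography.
#' @export
chart_pose_homography <- function(chart, dims, scale = 1, rotation_deg = 0,
                                  center = NULL, jitter_frac = 0) {
  h <- dims[1]; w <- dims[2]
  px_per_unit <- 270 / chart$physical_width * scale
  # conservative rotation-proof half-extent of the chart, plus the
  # maximum perspective corner jitter
  half_diag <- px_per_unit *
    sqrt(chart$physical_width^2 + chart$physical_height^2) / 2
  margin <- half_diag + jitter_frac * px_per_unit * chart$physical_width + 4
  if (is.null(center)) {
    if (2 * margin >= w || 2 * margin >= h)
      stop("chart at scale ", scale, " does not fit in a ",
           h, " x ", w, " frame")
    center <- c(stats::runif(1, margin, w - margin),
                stats::runif(1, margin, h - margin))
  }
  th <- rotation_deg * pi / 180
  lay_ctr <- c((min(chart$corners[, 1]) + max(chart$corners[, 1])) / 2,
               (min(chart$corners[, 2]) + max(chart$corners[, 2])) / 2)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L, byrow = TRUE)
  src <- chart$corners
  dst <- sweep(sweep(src, 2L, lay_ctr) %*% t(R) * px_per_unit,
               2L, center, `+`)
  if (jitter_frac > 0) {
    jit <- jitter_frac * px_per_unit * chart$physical_width
    dst <- dst + matrix(stats::runif(8, -jit, jit), 4L, 2L)
  }
  fit_homography(src, dst)
}

#' Render a synthetic frame
#'
#' Paints the background and leaf ellipses, rasterizes the chart at the
#' truth homography (2 x 2 supersampling at chart edges; patch gaps and
#' border are black), then applies the radiometric model
#' `clip(gain * (m x ideal) + offset + noise)` with
#' `m = illumination x relative exposure response`, and quantizes to
#' 8-bit levels. Deterministic given `truth$seed`.
#'
#' @param truth A `scene_truth`.
#' @param chart A `reference_chart`.
#' @return RGB array `h x w x 3` (0--255, integer-valued).
#' @export
render_scene <- function(truth, chart = load_reference_chart()) {
  stopifnot(inherits(truth, "scene_truth"))
  h <- truth$dims[1]; w <- truth$dims[2]
  corners <- apply_homography(truth$homography, chart$corners)
  if (any(corners[, 1] < 0 | corners[, 1] > w |
          corners[, 2] < 0 | corners[, 2] > h))
    stop("chart pose places the chart outside the frame")

  ideal <- array(rep(truth$background$base_color, each = h * w),
                 dim = c(h, w, 3L))
  lv <- truth$background$leaves
  if (!is.null(lv) && nrow(lv)) {
    for (i in seq_len(nrow(lv)))
      ideal <- paint_ellipse(ideal, lv$cx[i], lv$cy[i], lv$a[i], lv$b[i],
                             lv$angle[i], c(lv$R[i], lv$G[i], lv$B[i]))
  }
  ideal <- paint_chart(ideal, truth$homography, chart)

  mult <- truth$illumination * relative_exposure_gain(truth$exposure)
  frame <- ideal * mult
  for (ch in 1:3)
    frame[, , ch] <- frame[, , ch] * truth$gains[ch] + truth$offsets[ch]
  if (truth$noise_sigma > 0) {
    set.seed(truth$seed + 77003L)
    frame <- frame + array(stats::rnorm(h * w * 3L, 0, truth$noise_sigma),
                           dim = c(h, w, 3L))
  }
  round(clip255(frame))
}

# fill an ellipse (center cx,cy, semi-axes a,b, rotation angle) with color
paint_ellipse <- function(image, cx, cy, a, b, angle, color) {
  d <- dim(image)
  r0 <- max(1L, floor(cy - max(a, b))); r1 <- min(d[1], ceiling(cy + max(a, b)))
  c0 <- max(1L, floor(cx - max(a, b))); c1 <- min(d[2], ceiling(cx + max(a, b)))
  if (r1 < r0 || c1 < c0) return(image)
  rows <- r0:r1; cols <- c0:c1
  x <- outer(rep(1, length(rows)), cols - 0.5) - cx
  y <- outer(rows - 0.5, rep(1, length(cols))) - cy
  u <- x * cos(angle) + y * sin(angle)
  v <- -x * sin(angle) + y * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  for (ch in 1:3) {
    sub <- image[rows, cols, ch]
    sub[inside] <- color[ch]
    image[rows, cols, ch] <- sub
  }
  image
}

# rasterize the chart into the ideal image via the inverse homography,
# with 2x2 supersampling to soften edge aliasing
paint_chart <- function(ideal, H, chart) {
  d <- dim(ideal)
  corners <- apply_homography(H, chart$corners)
  r0 <- max(1L, floor(min(corners[, 2]) - 1)); r1 <- min(d[1], ceiling(max(corners[, 2]) + 1))
  c0 <- max(1L, floor(min(corners[, 1]) - 1)); c1 <- min(d[2], ceiling(max(corners[, 1]) + 1))
  rows <- r0:r1; cols <- c0:c1
  nr <- length(rows); nc <- length(cols)
  Hi <- solve(H)

  ref <- chart_reference_rgb(chart)
  pitch <- chart$patch_side + chart$gap
  acc <- array(0, dim = c(nr, nc, 3L))
  wsum <- matrix(0, nr, nc)

  base_x <- rep(cols - 0.5, each = nr)
  base_y <- rep(rows - 0.5, times = nc)
  for (ox in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25)) {
    lay <- apply_homography(Hi, cbind(base_x + ox, base_y + oy))
    lx <- lay[, 1]; ly <- lay[, 2]
    inside <- lx >= -chart$border & lx <= chart$physical_width - chart$border &
              ly >= -chart$border & ly <= chart$physical_height - chart$border
    col_idx <- floor(lx / pitch)
    row_idx <- floor(ly / pitch)
    fx <- lx - col_idx * pitch
    fy <- ly - row_idx * pitch
    on_patch <- inside & col_idx >= 0 & col_idx <= 5 & row_idx >= 0 &
                row_idx <= 3 & fx <= chart$patch_side & fy <= chart$patch_side
    patch_no <- ifelse(on_patch, row_idx * 6 + col_idx + 1, NA_integer_)

    colv <- matrix(0, nr * nc, 3L)  # border/gap = black
    pi_ok <- which(on_patch)
    if (length(pi_ok)) colv[pi_ok, ] <- ref[patch_no[pi_ok], , drop = FALSE]

    for (ch in 1:3) {
      lay_col <- matrix(ifelse(inside, colv[, ch], NA_real_), nr, nc)
      cur <- acc[, , ch]
      cur[!is.na(lay_col)] <- cur[!is.na(lay_col)] + lay_col[!is.na(lay_col)]
      acc[, , ch] <- cur
    }
    wsum <- wsum + matrix(as.numeric(inside), nr, nc)
  }

  blend <- wsum / 4
  for (ch in 1:3) {
    bg <- ideal[rows, cols, ch]
    chart_col <- ifelse(wsum > 0, acc[, , ch] / pmax(wsum, 1), 0)
    ideal[rows, cols, ch] <- blend * chart_col + (1 - blend) * bg
  }
  ideal
}

#' Apply a random color cast
#'
#' Draws three independent channel gains uniformly from
#' `[0.5, 1.0]` (attenuation, so no channel is pushed toward
#' overexposure) and applies them multiplicatively, simulating the
#' color distortions introduced by varying imaging environments and
#' sensor responses. The applied gains are returned as ground truth.
#'
#' @param image RGB array (0--255).
#' @param seed Integer seed for the gain draw (ignored when `gains`
#'   is supplied).
#' @param gains Optional fixed gains (length 3) instead of random draws.
#' @param range Attenuation range; default `c(0.5, 1.0)`.
#' @return List: `image` (cast frame), `gains`.
#' @export
apply_color_cast <- function(image, seed = NULL, gains = NULL,
                             range = c(0.5, 1.0)) {
  if (is.null(gains)) {
    if (!is.null(seed)) set.seed(seed)
    gains <- stats::runif(3, range[1], range[2])
  }
  out <- image
  for (ch in 1:3) out[, , ch] <- out[, , ch] * gains[ch]
  list(image = clip255(out), gains = gains)
}

#' Specify a synthetic flight series
#'
#' @param n_frames Number of frames, >= 1.
#' @param profile Illumination profile across the flight: `"constant"`,
#'   `"linear"` (drift from `illum_start` to `illum_end`), or `"walk"`
#'   (seeded multiplicative random walk clipped to
#'   `[illum_end, illum_start]`).
#' @param illum_start,illum_end Illumination multipliers bounding the
#'   profile; defaults 1.0 and 0.6.
#' @param walk_step SD of the per-frame log-step for `"walk"`.
#' @param dims Frame dimensions `c(height, width)`.
#' @param scale Chart scale for every frame.
#' @param distort Per-frame random gains/offsets (as in
#'   [random_scene_truth()])?
#' @param noise_sigma Per-frame noise SD.
#' @param exposures Optional list of per-frame `exposure_settings`
#'   (recycled); default reference exposure throughout.
#' @param seed Series seed; frame f uses `seed + f`.
#' @return A `flight_series_spec`.
#' @export
flight_series_spec <- function(n_frames, profile = c("constant", "linear", "walk"),
                               illum_start = 1.0, illum_end = 0.6,
                               walk_step = 0.05,
                               dims = c(360L, 480L), scale = 0.6,
                               distort = FALSE, noise_sigma = 1,
                               exposures = NULL, seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(n_frames >= 1L, illum_start > 0, illum_end > 0)
  structure(list(n_frames = as.integer(n_frames), profile = profile,
                 illum_start = illum_start, illum_end = illum_end,
                 walk_step = walk_step, dims = as.integer(dims),
                 scale = scale, distort = distort, noise_sigma = noise_sigma,
                 exposures = exposures, seed = as.integer(seed)),
            class = "flight_series_spec")
}

#' Illumination profile of a series
#'
#' @param spec A `flight_series_spec`.
#' @return Numeric vector of per-frame illumination multipliers.
#' @export
series_illumination <- function(spec) {
  n <- spec$n_frames
  switch(spec$profile,
    constant = rep(spec$illum_start, n),
    linear = seq(spec$illum_start, spec$illum_end, length.out = n),
    walk = {
      set.seed(spec$seed + 55001L)
      lo <- min(spec$illum_start, spec$illum_end)
      hi <- max(spec$illum_start, spec$illum_end)
      x <- numeric(n)
      x[1] <- spec$illum_start
      if (n > 1) for (i in 2:n)
        x[i] <- min(hi, max(lo, x[i - 1] * exp(stats::rnorm(1, 0, spec$walk_step))))
      x
    })
}

#' Generate a synthetic flight series
#'
#' One frame per mission step, chart present in every frame (the
#' cooperative-flight geometry), illumination following the series
#' profile, with every truth parameter logged. Deterministic given the
#' spec's seed.
#'
#' @param spec A `flight_series_spec`.
#' @param chart A `reference_chart`.
#' @return List of `n_frames` elements, each `list(frame, truth)`.
#' @export
generate_flight_series <- function(spec, chart = load_reference_chart()) {
  stopifnot(inherits(spec, "flight_series_spec"))
  illum <- series_illumination(spec)
  exposures <- spec$exposures
  out <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    expo <- if (is.null(exposures)) reference_exposure()
            else exposures[[(f - 1L) %% length(exposures) + 1L]]
    truth <- random_scene_truth(
      seed = spec$seed + f, dims = spec$dims, chart = chart,
      scale_range = c(spec$scale, spec$scale),
      distort = spec$distort, noise_sigma = spec$noise_sigma,
      illumination = illum[f], exposure = expo,
      min_uncorrected_delta_e = NULL)
    out[[f]] <- list(frame = render_scene(truth, chart), truth = truth)
  }
  out
}

#' Write a truth manifest for a series
#'
#' JSON-lines log of every frame's ground truth (seed, gains, offsets,
#' illumination, exposure, homography).
#'
#' @param series Output of [generate_flight_series()].
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_series_manifest <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(series)) {
    t <- series[[f]]$truth
    line <- jsonlite::toJSON(list(
      frame = f, seed = t$seed, gains = t$gains, offsets = t$offsets,
      illumination = t$illumination,
      exposure = list(iso = t$exposure$iso, shutter_s = t$exposure$shutter_s,
                      aperture_n = t$exposure$aperture_n),
      homography = as.vector(t$homography)
    ), digits = NA, auto_unbox = TRUE)
    writeLines(line, con)
  }
  invisible(path)
}
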