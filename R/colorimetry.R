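#' Convert sRGB (0--255) to CIELAB (D65, 2 degree observer)
#'
#' Standard colorimetric path: sRGB decoding (IEC 61966-2-1 transfer
#' function) to linear RGB, linear transform to CIE XYZ with D65 white,
#' then the CIE L*a*b* functions. The white point is taken as the exact
#' image of (1,1,1) under the sRGB-to-XYZ matrix, so neutral inputs map
#' to a* = b* = 0.
#'
#' @param rgb Numeric vector of length 3, or an `n x 3` matrix, channels
#'   in `[0, 255]` (R, G, B order).
#' @return An `n x 3` matrix with columns `L`, `a`, `b` (a length-3 named
#'   vector if the input was a vector). `L` lies in `[0, 100]` for
#'   in-gamut input.
#' @export
srgb_to_lab <- function(rgb) {
  vec_in <- is.null(dim(rgb))
  m <- if (vec_in) matrix(rgb, ncol = 3L) else as.matrix(rgb)
  if (ncol(m) != 3L) stop("rgb must have 3 channels")
  if (anyNA(m) || any(m < 0) || any(m > 255))
    stop("rgb channels must be finite and within [0, 255]")
  lab <- xyz_to_lab(srgb_to_xyz(m))
  colnames(lab) <- c("L", "a", "b")
  if (vec_in) lab[1L, ] else lab
}

# sRGB (0-255) -> XYZ scaled so that Y(white) = 1
srgb_to_xyz <- function(m) {
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  lin %*% t(.srgb2xyz)
}

.srgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3L, byrow = TRUE)

# D65 white = image of RGB (1,1,1): row sums of the matrix
.white_d65 <- rowSums(.srgb2xyz)

xyz_to_lab <- function(xyz) {
  t3 <- (6 / 29)^3
  f <- function(t) ifelse(t > t3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1] / .white_d65[1])
  fy <- f(xyz[, 2] / .white_d65[2])
  fz <- f(xyz[, 3] / .white_d65[3])
  cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

#' CIEDE2000 color difference
#'
#' The full CIE 2000 color-difference formula with standard parametric
#' factors kL = kC = kH = 1, following the defining publication's
#' implementation notes (hue-angle handling, G compensation factor, and
#' the rotation term). Vectorized: `x` and `y` are recycled row-wise.
#'
#' @param x,y Lab colors: length-3 vectors or `n x 3` matrices
#'   (`L`, `a`, `b`), same illuminant convention (D65 here).
#' @return Non-negative numeric vector of ΔE00 values.
#' @export
ciede2000 <- function(x, y) {
  x <- if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
  y <- if (is.null(dim(y))) matrix(y, ncol = 3L) else as.matrix(y)
  n <- max(nrow(x), nrow(y))
  if (nrow(x) < n) x <- x[rep_len(seq_len(nrow(x)), n), , drop = FALSE]
  if (nrow(y) < n) y <- y[rep_len(seq_len(nrow(y)), n), , drop = FALSE]
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("Lab inputs must be finite")

  L1 <- x[, 1]; a1 <- x[, 2]; b1 <- x[, 3]
  L2 <- y[, 1]; a2 <- y[, 2]; b2 <- y[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  h1p <- atan2d_pos(b1, a1p)
  h2p <- atan2d_pos(b2, a2p)

  dLp <- L2 - L1
  dCp <- C2p - C1p

  dhp <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(dhp >  180, dhp - 360,
         ifelse(dhp < -180, dhp + 360, dhp)))
  dHp <- 2 * sqrt(C1p * C2p) * sin_d(dhp / 2)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  habs <- abs(h1p - h2p)
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(habs <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tt <- 1 - 0.17 * cos_d(hbp - 30) + 0.24 * cos_d(2 * hbp) +
        0.32 * cos_d(3 * hbp + 6) - 0.20 * cos_d(4 * hbp - 63)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin_d(2 * dtheta) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
       RT * (dCp / SC) * (dHp / SH))
}

atan2d_pos <- function(b, a) {
  h <- atan2(b, a) * 180 / pi
  ifelse(b == 0 & a == 0, 0, ifelse(h < 0, h + 360, h))
}
sin_d <- function(x) sin(x * pi / 180)
cos_d <- function(x) cos(x * pi / 180)

#' Exposure settings
#'
#' Camera exposure metadata used by [normalize_brightness()]: ISO
#' sensitivity, shutter (exposure) time in seconds, and the aperture
#' f-number. The reference condition for brightness normalization is
#' ISO 100, 1/100 s, f/8.
#'
#' @param iso ISO sensitivity, > 0.
#' @param shutter_s Exposure time in seconds (1/100 s is `0.01`), > 0.
#' @param aperture_n Aperture f-number, > 0.
#' @return An object of class `exposure_settings`.
#' @export
exposure_settings <- function(iso, shutter_s, aperture_n) {
  if (!all(is.finite(c(iso, shutter_s, aperture_n))) ||
      any(c(iso, shutter_s, aperture_n) <= 0))
    stop("iso, shutter_s and aperture_n must all be strictly positive")
  structure(list(iso = iso, shutter_s = shutter_s, aperture_n = aperture_n),
            class = "exposure_settings")
}

#' @export
print.exposure_settings <- function(x, ...) {
  cat(sprintf("ISO %g, %g s (1/%g s), f/%g\n",
              x$iso, x$shutter_s, 1 / x$shutter_s, x$aperture_n))
  invisible(x)
}

#' Reference exposure condition (ISO 100, 1/100 s, f/8)
#' @return An `exposure_settings` object.
#' @export
reference_exposure <- function() exposure_settings(100, 1 / 100, 8)

#' Normalize brightness to a standard exposure condition
#'
#' Rescales a brightness reading taken under arbitrary camera settings to
#' the reference condition (by default ISO 100, 1/100 s, f/8) so that
#' illumination variation can be compared across frames:
#'
#' \deqn{L_{std} = L_{raw} \cdot \frac{ISO_{ref}}{ISO_{raw}} \cdot
#'   \frac{t_{ref}}{t_{raw}} \cdot \left(\frac{N_{raw}}{N_{ref}}\right)^2}
#'
#' The aperture ratio enters squared with the raw f-number in the
#' numerator; see the methods vignette for a note on this convention.
#'
#' @param l_raw Raw brightness value (e.g. the gray-patch mean).
#' @param raw `exposure_settings` under which `l_raw` was measured.
#' @param ref Reference `exposure_settings`; default [reference_exposure()].
#' @return Normalized brightness, same scale as `l_raw`.
#' @export
normalize_brightness <- function(l_raw, raw, ref = reference_exposure()) {
  stopifnot(inherits(raw, "exposure_settings"), inherits(ref, "exposure_settings"))
  l_raw * (ref$iso / raw$iso) * (ref$shutter_s / raw$shutter_s) *
    (raw$aperture_n / ref$aperture_n)^2
}

#' Brightness of the 18% gray patch
#'
#' The per-frame illumination reference: the arithmetic mean of the R, G
#' and B channel means of the 18% gray patch (patch 22 of the chart).
#'
#' @param observations A `patch_observations` object (see
#'   [extract_patch_colors()]).
#' @param patch_index Index of the gray reference patch; default 22.
#' @return Scalar brightness on the 0--255 scale.
#' @export
brightness_of_gray_patch <- function(observations, patch_index = 22L) {
  stopifnot(inherits(observations, "patch_observations"))
  row <- observations$patches[observations$patches$index == patch_index, ]
  if (nrow(row) != 1L)
    stop("gray patch ", patch_index, " not present in observations")
  if (!row$included)
    stop("gray patch ", patch_index, " is excluded (overexposed); ",
         "brightness reference unavailable")
  mean(c(row$R, row$G, row$B))
}

#' Mean intracluster distance in LAB space
#'
#' Treats a set of LAB measurements of the same patch (one per camera or
#' frame) as a cluster and returns the mean Euclidean distance of the
#' points from the cluster centroid — the cross-sensor consistency
#' metric: lower is more consistent.
#'
#' @param cluster An `n x 3` matrix (or data frame) of Lab rows, n >= 2.
#' @return Non-negative scalar.
#' @export
intracluster_distance <- function(cluster) {
  m <- as.matrix(cluster)
  if (nrow(m) < 2L) stop("intracluster distance needs at least 2 points")
  if (ncol(m) != 3L) stop("cluster rows must be Lab triples")
  centroid <- colMeans(m)
  mean(sqrt(rowSums(sweep(m, 2L, centroid)^2)))
}

#' Read exposure settings from a sidecar table
#'
#' Loads per-image exposure metadata from a CSV with columns
#' `image_id, iso, shutter_s, aperture_n`.
#'
#' @param path CSV path.
#' @return Named list of `exposure_settings`, keyed by `image_id`.
#' @export
read_exposure_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "iso", "shutter_s", "aperture_n")
  if (!all(need %in% names(tab)))
    stop("exposure table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i)
    exposure_settings(tab$iso[i], tab$shutter_s[i], tab$aperture_n[i]))
  names(out) <- tab$image_id
  out
}
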