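#' Build a chart-occlusion mask for mosaicking
#'
#' Expands the detected chart quadrilateral about its center — in the
#' chart's own axes, via the homography, so rotated charts are masked
#' correctly — and rasterizes it. The long axis (the 6-column direction,
#' "length") is scaled by `1 + 2 * length_expand` and the short axis
#' ("width") by `1 + 2 * width_expand`; the defaults extend the length
#' by 30% and the width by 50% in each direction, covering the carrier
#' platform around the chart. Masked pixels are `TRUE`, clipped to the
#' image bounds.
#'
#' @param detection A successful `chart_detection`.
#' @param length_expand Fractional expansion per direction along the
#'   chart's long axis; default 0.3.
#' @param width_expand Fractional expansion per direction along the
#'   short axis; default 0.5.
#' @param image_dims `c(height, width)` of the frame.
#' @param chart A `reference_chart` (layout geometry).
#' @return A `mask_spec` object: `$chart_corners`, `$expanded_corners`
#'   (both 4 x 2), `$length_expand`, `$width_expand`, `$image_dims`,
#'   `$mask` (logical `h x w` raster).
#' @export
make_mask <- function(detection, length_expand = 0.3, width_expand = 0.5,
                      image_dims, chart = load_reference_chart()) {
  stopifnot(inherits(detection, "chart_detection"))
  if (!isTRUE(detection$success))
    stop("cannot build a mask: chart detection failed (", detection$reason, ")")
  if (length_expand < 0 || width_expand < 0)
    stop("expansion fractions must be >= 0")

  # expand in layout space: x is the long (length) axis, y the short axis
  ctr <- c((min(chart$corners[, 1]) + max(chart$corners[, 1])) / 2,
           (min(chart$corners[, 2]) + max(chart$corners[, 2])) / 2)
  sx <- 1 + 2 * length_expand
  sy <- 1 + 2 * width_expand
  expanded_layout <- cbind(ctr[1] + (chart$corners[, 1] - ctr[1]) * sx,
                           ctr[2] + (chart$corners[, 2] - ctr[2]) * sy)
  expanded <- apply_homography(detection$homography, expanded_layout)

  h <- image_dims[1]; w <- image_dims[2]
  structure(list(chart_corners = detection$corners_image,
                 expanded_corners = expanded,
                 length_expand = length_expand, width_expand = width_expand,
                 image_dims = c(h, w),
                 mask = polygon_to_mask(expanded, h, w)),
            class = "mask_spec")
}

#' @export
print.mask_spec <- function(x, ...) {
  cat(sprintf("chart mask: %d px masked of %d x %d (expand %.0f%%/%.0f%% per direction)\n",
              sum(x$mask), x$image_dims[1], x$image_dims[2],
              100 * x$length_expand, 100 * x$width_expand))
  invisible(x)
}

#' Flight-overlap arithmetic and mask sufficiency
#'
#' Converts forward/side overlap fractions into pixels at a given sensor
#' resolution (round half up, so 8192 x 0.8 = 6553.6 reports as 6554)
#' and checks that both overlaps strictly exceed the corresponding mask
#' extents — the condition for neighbouring frames to fill in the area
#' hidden by the chart mask.
#'
#' @param image_dims `c(width, height)` in pixels (sensor resolution).
#' @param forward_overlap,side_overlap Overlap fractions in `[0, 1)`.
#'   Forward overlap acts along the image height, side overlap along the
#'   width.
#' @param mask_forward_px,mask_side_px Mask extent (pixels) along each
#'   direction that the overlap must exceed; default 0 (no mask).
#' @return List: `forward_px`, `side_px`, `sufficient`.
#' @export
overlap_pixels <- function(image_dims, forward_overlap, side_overlap,
                           mask_forward_px = 0, mask_side_px = 0) {
  if (any(c(forward_overlap, side_overlap) < 0) ||
      any(c(forward_overlap, side_overlap) >= 1))
    stop("overlap fractions must lie in [0, 1)")
  w <- image_dims[1]; h <- image_dims[2]
  round_half_up <- function(x) floor(x + 0.5)
  forward_px <- round_half_up(h * forward_overlap)
  side_px <- round_half_up(w * side_overlap)
  list(forward_px = forward_px, side_px = side_px,
       sufficient = forward_px > mask_forward_px && side_px > mask_side_px)
}

#' Extent of a mask along the chart axes
#'
#' Side lengths of the expanded mask quadrilateral along the chart's
#' long and short axes (mean of opposite sides), in pixels.
#'
#' @param mask_spec A `mask_spec`.
#' @return Named vector `c(length_px, width_px)`.
#' @export
mask_extent <- function(mask_spec) {
  q <- mask_spec$expanded_corners
  side <- function(a, b) sqrt(sum((q[a, ] - q[b, ])^2))
  c(length_px = (side(1, 2) + side(4, 3)) / 2,
    width_px = (side(1, 4) + side(2, 3)) / 2)
}
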