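#' Load a reference color chart definition
#'
#' Returns the 24-patch ColorChecker Classic: patch identities, grid
#' layout (4 rows x 6 columns, row-major from the dark-skin patch; row 4
#' holds the neutral series so patch 19 is white, 22 the 18% gray and 24
#' black), layout-space geometry, and reference sRGB plus CIELAB (D65,
#' 2 degree) values per patch. Values are read from the packaged chart
#' definition file.
#'
#' Layout space is chart-relative: the origin is the top-left corner of
#' patch 1 (dark skin), x rightward, y downward, with a patch side of 50
#' units, 5-unit gaps and a 5-unit surrounding border. All homographies
#' in the package map this layout space into image pixel space.
#'
#' @param variant Chart variant id. Shipped: `"classic-srgb-d65"`, the
#'   widely published X-Rite Classic sRGB coordinates (pre-2014 chart
#'   edition) with Lab computed under D65.
#' @return A `reference_chart` object: `$patches` (data frame with
#'   columns `index, name, R, G, B, L, a, b, row, col, cx, cy`),
#'   `$patch_side`, `$gap`, `$border`, `$physical_width`,
#'   `$physical_height`, `$corners` (4 x 2, TL/TR/BR/BL order,
#'   including the border), `$variant`.
#' @export
load_reference_chart <- function(variant = "classic-srgb-d65") {
  available <- c("classic-srgb-d65")
  if (!variant %in% available)
    stop("unknown chart variant '", variant, "'; available: ",
         paste(available, collapse = ", "))
  path <- system.file("extdata",
                      paste0("colorchecker_", gsub("-", "_", variant), ".csv"),
                      package = "uavcolor", mustWork = TRUE)
  patches <- utils::read.csv(path, stringsAsFactors = FALSE)

  side <- 50; gap <- 5; border <- 5
  pitch <- side + gap
  patches$cx <- (patches$col - 1) * pitch + side / 2
  patches$cy <- (patches$row - 1) * pitch + side / 2

  width  <- 6 * side + 5 * gap + 2 * border
  height <- 4 * side + 3 * gap + 2 * border
  corners <- rbind(
    c(-border,              -border),
    c(width - border,       -border),
    c(width - border,  height - border),
    c(-border,         height - border)
  )

  chart <- structure(list(
    patches = patches,
    patch_side = side, gap = gap, border = border,
    physical_width = width, physical_height = height,
    corners = corners,
    variant = variant
  ), class = "reference_chart")
  validate_reference_chart(chart)
  chart
}

validate_reference_chart <- function(chart) {
  p <- chart$patches
  stopifnot(nrow(p) == 24L, identical(p$index, 1:24))
  stopifnot(all(p$row %in% 1:4), all(p$col %in% 1:6))
  rgb <- as.matrix(p[, c("R", "G", "B")])
  if (any(rgb < 0 | rgb > 255)) stop("reference sRGB values out of [0, 255]")
  if (any(p$L < 0 | p$L > 100)) stop("reference L* values out of [0, 100]")
  if (!(p$L[19] > p$L[22] && p$L[22] > p$L[24]))
    stop("neutral ordering violated: expect L*(19) > L*(22) > L*(24)")
  invisible(chart)
}

#' @export
print.reference_chart <- function(x, ...) {
  cat(sprintf("reference chart '%s': %d patches, %dx%d grid, layout %g x %g units\n",
              x$variant, nrow(x$patches), max(x$patches$row), max(x$patches$col),
              x$physical_width, x$physical_height))
  invisible(x)
}

#' Reference sRGB matrix of a chart
#'
#' @param chart A `reference_chart`.
#' @return 24 x 3 matrix of reference R, G, B values (0--255).
#' @export
chart_reference_rgb <- function(chart) {
  stopifnot(inherits(chart, "reference_chart"))
  as.matrix(chart$patches[, c("R", "G", "B")])
}

#' Reference Lab matrix of a chart
#'
#' @param chart A `reference_chart`.
#' @return 24 x 3 matrix of reference L, a, b values (D65).
#' @export
chart_reference_lab <- function(chart) {
  stopifnot(inherits(chart, "reference_chart"))
  as.matrix(chart$patches[, c("L", "a", "b")])
}

# layout-space square (4 x 2 corner matrix, TL/TR/BR/BL) of one patch cell
patch_layout_quad <- function(chart, index, shrink = 1) {
  p <- chart$patches[chart$patches$index == index, ]
  half <- chart$patch_side / 2 * shrink
  cbind(p$cx + c(-half, half, half, -half),
        p$cy + c(-half, -half, half, half))
}
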