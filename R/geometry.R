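# Planar projective geometry helpers: homography estimation (normalized
# DLT, 4-point minimal and overdetermined least squares), RANSAC, and
# polygon utilities shared by detection, masking and rendering.
#
# Convention: points are n x 2 matrices of (x, y); pixel (row r, col c)
# of an image (1-based) has continuous coordinates x = c - 0.5,
# y = r - 0.5, i.e. pixel centers sit on half-integers of a 0-based
# frame. Homographies are 3 x 3 with H[3,3] scaled to 1 when possible.

#' Apply a homography to 2-D points
#'
#' @param H 3 x 3 homography matrix.
#' @param pts `n x 2` matrix of (x, y) points.
#' @return `n x 2` matrix of transformed points.
#' @export
apply_homography <- function(H, pts) {
  pts <- matrix(pts, ncol = 2L)
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' Fit a homography by the normalized direct linear transform
#'
#' Least-squares estimate of the 3 x 3 projective transform mapping
#' `src` to `dst` (exact for 4 point pairs in general position).
#'
#' @param src,dst `n x 2` matrices of corresponding points, n >= 4.
#' @return 3 x 3 homography with `H[3,3] == 1`.
#' @export
fit_homography <- function(src, dst) {
  src <- matrix(src, ncol = 2L); dst <- matrix(dst, ncol = 2L)
  n <- nrow(src)
  if (n < 4L || nrow(dst) != n) stop("need >= 4 corresponding point pairs")
  Ts <- normalization_transform(src)
  Td <- normalization_transform(dst)
  s <- apply_homography(Ts, src)
  d <- apply_homography(Td, dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- solve(Td) %*% matrix(h, 3, 3, byrow = TRUE) %*% Ts
  if (abs(H[3, 3]) > .Machine$double.eps) H <- H / H[3, 3]
  H
}

# similarity transform moving points to centroid 0, mean distance sqrt(2)
normalization_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- mean(sqrt(rowSums(sweep(pts, 2L, ctr)^2)))
  s <- if (d > .Machine$double.eps) sqrt(2) / d else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Robustly estimate a homography with RANSAC
#'
#' Repeated 4-point minimal fits; the consensus set (reprojection error
#' below `threshold`) of the best hypothesis is refit by least squares.
#'
#' @param src,dst `n x 2` matrices of putative correspondences.
#' @param threshold Inlier reprojection threshold in destination units
#'   (pixels); default 3.
#' @param max_iter Maximum sampling iterations (adaptively reduced).
#' @param conf Confidence for adaptive termination.
#' @return List with `H`, logical `inliers`, `n_inliers`; or `NULL` when
#'   no non-degenerate consensus of >= 4 points exists.
#' @export
ransac_homography <- function(src, dst, threshold = 3, max_iter = 2000,
                              conf = 0.999) {
  src <- matrix(src, ncol = 2L); dst <- matrix(dst, ncol = 2L)
  n <- nrow(src)
  if (n < 4L) return(NULL)
  best_inl <- NULL
  best_cnt <- 3L
  iter <- 0L
  n_iter <- max_iter
  while (iter < n_iter) {
    iter <- iter + 1L
    idx <- sample.int(n, 4L)
    H <- tryCatch(fit_homography(src[idx, ], dst[idx, ]),
                  error = function(e) NULL)
    if (is.null(H) || !all(is.finite(H))) next
    proj <- apply_homography(H, src)
    err <- sqrt(rowSums((proj - dst)^2))
    inl <- is.finite(err) & err < threshold
    cnt <- sum(inl)
    if (cnt > best_cnt) {
      best_cnt <- cnt
      best_inl <- inl
      w <- cnt / n
      denom <- log(max(1 - w^4, .Machine$double.eps))
      n_iter <- min(max_iter, ceiling(log(1 - conf) / denom))
    }
  }
  if (is.null(best_inl)) return(NULL)
  H <- tryCatch(fit_homography(src[best_inl, , drop = FALSE],
                               dst[best_inl, , drop = FALSE]),
                error = function(e) NULL)
  if (is.null(H) || !all(is.finite(H))) return(NULL)
  # final consensus against the refit model
  err <- sqrt(rowSums((apply_homography(H, src) - dst)^2))
  inl <- is.finite(err) & err < threshold
  list(H = H, inliers = inl, n_inliers = sum(inl))
}

#' Is a quadrilateral convex and non-self-intersecting?
#'
#' @param quad 4 x 2 matrix of ordered corners.
#' @return Logical.
#' @export
quad_is_convex <- function(quad) {
  quad <- matrix(quad, ncol = 2L)
  if (nrow(quad) != 4L || !all(is.finite(quad))) return(FALSE)
  cr <- numeric(4)
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[i %% 4 + 1, ]; c <- quad[(i + 1) %% 4 + 1, ]
    cr[i] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }
  all(cr > 0) || all(cr < 0)
}

# shoelace area of a closed polygon given as n x 2 matrix
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# vectorized point-in-polygon (even-odd rule); px, py numeric vectors,
# poly an n x 2 matrix. Points on edges count as inside on the
# lower/left side only (half-open), so tiled polygons partition pixels.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# integer pixel (row, col) indices whose centers fall inside poly,
# restricted to an h x w image; returns a 2-column matrix
pixels_in_polygon <- function(poly, h, w) {
  r0 <- max(1L, floor(min(poly[, 2]) + 0.5))
  r1 <- min(h, ceiling(max(poly[, 2]) + 0.5))
  c0 <- max(1L, floor(min(poly[, 1]) + 0.5))
  c1 <- min(w, ceiling(max(poly[, 1]) + 0.5))
  if (r1 < r0 || c1 < c0) return(cbind(row = integer(0), col = integer(0)))
  rows <- r0:r1; cols <- c0:c1
  grid <- expand.grid(row = rows, col = cols)
  keep <- points_in_polygon(grid$col - 0.5, grid$row - 0.5, poly)
  cbind(row = grid$row[keep], col = grid$col[keep])
}

# rasterize a polygon into a logical h x w matrix
polygon_to_mask <- function(poly, h, w) {
  m <- matrix(FALSE, h, w)
  px <- pixels_in_polygon(poly, h, w)
  if (nrow(px)) m[px] <- TRUE
  m
}

# mean of image channels over the pixels inside poly
mean_rgb_in_polygon <- function(image, poly) {
  d <- dim(image)
  px <- pixels_in_polygon(poly, d[1], d[2])
  if (nrow(px) == 0L) return(NULL)
  lin <- px[, "row"] + (px[, "col"] - 1L) * d[1]
  npx <- d[1] * d[2]
  c(mean(image[lin]), mean(image[lin + npx]), mean(image[lin + 2L * npx]),
    nrow(px))
}
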