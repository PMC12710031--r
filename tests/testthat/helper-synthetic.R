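# Shared fixtures, built in code: a rendered chart template crop (as a
# user would cut from a representative frame) and its precomputed
# keypoint features, reused across detection tests.

make_chart_template <- function(scale = 0.55, chart = load_reference_chart()) {
  dims <- c(ceiling(215 * 270 / 335 * scale) + 40, ceiling(270 * scale) + 40)
  tr <- scene_truth(
    chart_pose_homography(chart, dims, scale = scale, rotation_deg = 0,
                          center = c(dims[2] / 2, dims[1] / 2)),
    dims = dims, noise_sigma = 0, seed = 1)
  fr <- render_scene(tr, chart)
  crn <- apply_homography(tr$homography, chart$corners)
  fr[ceiling(min(crn[, 2]) + 0.5):floor(max(crn[, 2]) - 0.5),
     ceiling(min(crn[, 1]) + 0.5):floor(max(crn[, 1]) - 0.5), , drop = FALSE]
}

# chart-free frame sharing the background model of a sampled scene
make_chartfree_frame <- function(seed, dims = c(480L, 640L)) {
  tr <- random_scene_truth(seed = seed, dims = dims, distort = TRUE)
  lv <- tr$background$leaves
  frame <- array(rep(tr$background$base_color, each = prod(dims)),
                 c(dims, 3L))
  for (i in seq_len(nrow(lv)))
    frame <- uavcolor:::paint_ellipse(frame, lv$cx[i], lv$cy[i], lv$a[i],
                                      lv$b[i], lv$angle[i],
                                      c(lv$R[i], lv$G[i], lv$B[i]))
  set.seed(seed)
  pmin(pmax(round(frame + array(stats::rnorm(prod(dims) * 3), c(dims, 3L))),
            0), 255)
}

the_chart <- load_reference_chart()
the_template <- make_chart_template()
the_template_features <- detect_keypoints(the_template)

# independent point-in-convex-quad test (cross-product signs), used as
# an enumeration oracle against the package's polygon sampling
quad_contains <- function(quad, x, y) {
  s <- rep(TRUE, length(x))
  pos <- NULL
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[i %% 4 + 1, ]
    cr <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
    if (is.null(pos)) pos <- cr >= 0
    s <- s & ((cr >= 0) == pos)
  }
  s
}
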