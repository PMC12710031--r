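test_that("delta-E map behaves as a per-pixel metric", {
  ref <- unname(srgb_to_lab(c(80, 120, 60)))
  img <- array(rep(c(80, 120, 60), each = 12), c(3, 4, 3))
  m <- delta_e_map(img, ref)
  expect_equal(m, matrix(0, 3, 4), tolerance = 1e-9)
  # two-color image: exactly two values, matching the scalar metric
  img2 <- img
  img2[1:2, 1:2, 1] <- 200
  m2 <- delta_e_map(img2, ref)
  vals <- sort(unique(round(as.vector(m2), 10)))
  expect_length(vals, 2)
  expect_equal(max(m2), unname(
    ciede2000(srgb_to_lab(c(200, 120, 60)), ref)), tolerance = 1e-9)
  # translation invariance of the value multiset
  img3 <- img2[, c(2:4, 1), ]
  expect_equal(sort(as.vector(delta_e_map(img3, ref))),
               sort(as.vector(m2)))
})

test_that("threshold segmentation uses a strict comparison", {
  dm <- matrix(c(5, 15, 5, 10), 2, 2)
  seg <- segment_by_threshold(dm, 10)
  expect_equal(seg$map, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  expect_equal(seg$n_selected, 2L)
  all0 <- segment_by_threshold(matrix(0, 4, 4), 10)
  expect_equal(all0$n_selected, 16L)
  # enumeration oracle on a synthetic map
  set.seed(15)
  dm2 <- matrix(runif(500, 0, 20), 20, 25)
  seg2 <- segment_by_threshold(dm2, 10)
  expect_equal(seg2$n_selected, sum(dm2 < 10))
})

test_that("overlap ratio matches hand counts and is monotone", {
  truth <- matrix(FALSE, 10, 20)
  truth[3:7, 4:13] <- TRUE  # 50 px... constructed: 5 x 10 = 50
  pred <- matrix(FALSE, 10, 20)
  expect_equal(overlap_ratio(truth, truth), 1.0)
  expect_equal(overlap_ratio(pred, truth), 0.0)
  pred[3:7, 4:6] <- TRUE  # covers 15 of 50
  expect_equal(overlap_ratio(pred, truth), 15 / 50)
  pred2 <- pred; pred2[3:7, 7] <- TRUE
  expect_gte(overlap_ratio(pred2, truth), overlap_ratio(pred, truth))
  expect_error(overlap_ratio(pred, matrix(FALSE, 10, 20)), "empty")
})

test_that("camera consistency reduces to zero for identical observations", {
  chart <- the_chart
  obs <- patch_observations(chart_reference_rgb(chart))
  rep3 <- list(a = obs, b = obs, c = obs)
  rpt <- camera_consistency_report(rep3, chart)
  # reference Lab is stored to 4 decimals, so "zero" is ~2e-3 here
  expect_lt(rpt$summary$mean_delta_e_original, 0.01)
  expect_equal(rpt$summary$mean_intracluster_original, 0, tolerance = 1e-9)
  expect_equal(rpt$summary$mean_intracluster_corrected, 0, tolerance = 1e-9)
  expect_error(camera_consistency_report(list(a = obs)), "2 cameras")
})

test_that("correction tightens the cross-camera clusters", {
  chart <- the_chart
  ref <- chart_reference_rgb(chart)
  set.seed(19)
  cams <- lapply(1:4, function(i) {
    g <- runif(3, 0.55, 0.95); o <- runif(3, -8, 8)
    patch_observations(pmin(pmax(sweep(sweep(ref, 2, g, `*`), 2, o, `+`) +
                                 matrix(rnorm(72, 0, 1), 24, 3), 0), 255),
                       image_id = paste0("cam", i))
  })
  names(cams) <- paste0("cam", 1:4)
  rpt <- camera_consistency_report(cams, chart)
  expect_lt(rpt$summary$mean_delta_e_corrected,
            rpt$summary$mean_delta_e_original)
  expect_lt(rpt$summary$mean_intracluster_corrected,
            rpt$summary$mean_intracluster_original)
  expect_true(all(rpt$per_patch$intracluster_corrected >= 0))
})

test_that("two-camera intracluster distances equal direct arithmetic", {
  chart <- the_chart
  ref <- chart_reference_rgb(chart)
  obs1 <- patch_observations(ref * 0.9)
  obs2 <- patch_observations(ref * 0.7)
  rpt <- camera_consistency_report(list(a = obs1, b = obs2), chart)
  lab1 <- srgb_to_lab(ref * 0.9)
  lab2 <- srgb_to_lab(ref * 0.7)
  # for two points the intracluster distance is half their separation
  expected <- sqrt(rowSums((lab1 - lab2)^2)) / 2
  expect_equal(rpt$per_patch$intracluster_original, unname(expected),
               tolerance = 1e-9)
})

test_that("plot color summary computes the chromaticity index", {
  img <- array(100, c(10, 10, 3))
  mask <- matrix(TRUE, 10, 10)
  s <- plot_color_summary(img, mask, "p1")
  expect_equal(s$normalized_r_plus_b, 2 / 3, tolerance = 1e-12)
  # pure green region: index 0
  img_g <- array(0, c(10, 10, 3)); img_g[, , 2] <- 180
  expect_equal(plot_color_summary(img_g, mask)$normalized_r_plus_b, 0)
  # two-tone region against brute-force pixel averaging
  img2 <- img
  img2[1:5, , 1] <- 240; img2[1:5, , 3] <- 20
  poly <- rbind(c(1.3, 1.3), c(8.3, 1.3), c(8.3, 8.3), c(1.3, 8.3))
  s2 <- plot_color_summary(img2, poly)
  grid <- expand.grid(row = 1:10, col = 1:10)
  inside <- quad_contains(poly, grid$col - 0.5, grid$row - 0.5)
  idx <- cbind(grid$row[inside], grid$col[inside])
  expect_equal(unname(s2$mean_rgb),
               c(mean(img2[cbind(idx, 1)]), mean(img2[cbind(idx, 2)]),
                 mean(img2[cbind(idx, 3)])))
  expect_equal(s2$n_pixels, sum(inside))
  # brightness-scale invariance of the index
  s_half <- plot_color_summary(img2 * 0.5, poly)
  expect_equal(s_half$normalized_r_plus_b, s2$normalized_r_plus_b,
               tolerance = 1e-12)
  expect_error(plot_color_summary(img, matrix(FALSE, 10, 10)), "no pixels")
})

test_that("maturity regression reports R-squared and p value", {
  set.seed(8)
  x <- runif(18, 0.3, 0.5)
  y <- 200 + 150 * x + rnorm(18, 0, 2)
  fit <- maturity_color_regression(y, x)
  expect_gt(fit$r_squared, 0.8)
  expect_lt(fit$p_value, 0.001)
})

test_that("constant-illumination series: strategies agree within noise", {
  sc <- flight_series_spec(6, profile = "constant", illum_start = 0.9,
                           distort = FALSE, noise_sigma = 1, seed = 21)
  series <- generate_flight_series(sc)
  res <- compare_fixed_vs_inflight(series, reference_frame_indices = c(1, 3))
  s <- res$summary
  de_in <- s$mean_delta_e[s$strategy == "in-flight"]
  for (fx in s$mean_delta_e[s$strategy != "in-flight"])
    expect_lt(abs(fx - de_in), 0.5)
})

test_that("drifting series: in-flight beats every fixed reference", {
  sc <- flight_series_spec(10, profile = "linear", illum_start = 1.0,
                           illum_end = 0.6, distort = FALSE,
                           noise_sigma = 1, seed = 22)
  series <- generate_flight_series(sc)
  res <- compare_fixed_vs_inflight(series,
                                   reference_frame_indices = c(1, 5, 10))
  s <- res$summary
  de_in <- s$mean_delta_e[s$strategy == "in-flight"]
  fixed <- s[s$strategy != "in-flight", ]
  expect_true(all(de_in <= fixed$mean_delta_e))
  # the reference nearest the series-mean illumination does best
  illum <- series_illumination(sc)
  best_ref <- c(1, 5, 10)[which.min(abs(illum[c(1, 5, 10)] - mean(illum)))]
  expect_equal(fixed$strategy[which.min(fixed$mean_delta_e)],
               paste0("fixed#", best_ref))
})
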