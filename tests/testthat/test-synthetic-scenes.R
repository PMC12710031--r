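test_that("undistorted render reproduces reference patch colors", {
  chart <- the_chart
  truth <- scene_truth(
    chart_pose_homography(chart, c(360L, 480L), scale = 0.8,
                          rotation_deg = 40, center = c(240, 180)),
    dims = c(360L, 480L), noise_sigma = 0, seed = 5)
  fr <- render_scene(truth, chart)
  det <- detection_from_homography(truth$homography, chart)
  obs <- extract_patch_colors(fr, locate_patches(det, chart, 0.8))
  err <- abs(observed_rgb(obs) - chart_reference_rgb(chart))
  expect_lt(max(err), 1)  # 8-bit quantization only
})

test_that("rendering is deterministic given the seed", {
  truth <- random_scene_truth(seed = 99, distort = TRUE, noise_sigma = 2)
  f1 <- render_scene(truth)
  f2 <- render_scene(truth)
  expect_identical(f1, f2)
  # and the sampled truth itself is reproducible
  t2 <- random_scene_truth(seed = 99, distort = TRUE, noise_sigma = 2)
  expect_identical(truth$homography, t2$homography)
  expect_identical(truth$gains, t2$gains)
})

test_that("channel gains shift rendered patch colors as pure arithmetic", {
  chart <- the_chart
  gains <- c(0.8, 1.0, 0.9)
  truth <- scene_truth(
    chart_pose_homography(chart, c(360L, 480L), scale = 0.8,
                          rotation_deg = 0, center = c(240, 180)),
    dims = c(360L, 480L), gains = gains, noise_sigma = 0, seed = 6)
  fr <- render_scene(truth, chart)
  det <- detection_from_homography(truth$homography, chart)
  obs <- extract_patch_colors(fr, locate_patches(det, chart, 0.8))
  expected <- sweep(chart_reference_rgb(chart), 2, gains, `*`)
  expect_lt(max(abs(observed_rgb(obs) - expected)), 1)
})

test_that("render refuses a chart outside the frame", {
  chart <- the_chart
  H <- chart_pose_homography(chart, c(1000L, 1000L), scale = 0.8,
                             rotation_deg = 0, center = c(500, 500))
  truth <- scene_truth(H, dims = c(200L, 200L), seed = 1)
  expect_error(render_scene(truth, chart), "outside the frame")
})

test_that("color cast draws attenuations in [0.5, 1] and is invertible", {
  img <- array(runif(300, 0, 250), c(10, 10, 3))
  # unit gains leave the image unchanged
  same <- apply_color_cast(img, gains = c(1, 1, 1))
  expect_equal(same$image, img)
  # 1000 seeded draws stay within the attenuation range
  set.seed(1)
  g <- replicate(1000, apply_color_cast(img[1:2, 1:2, , drop = FALSE])$gains)
  expect_true(all(g >= 0.5 & g <= 1.0))
  # end-to-end recovery: cast the rendered chart, correct, compare
  chart <- the_chart
  truth <- scene_truth(
    chart_pose_homography(chart, c(360L, 480L), scale = 0.8,
                          rotation_deg = 15, center = c(240, 180)),
    dims = c(360L, 480L), noise_sigma = 0, seed = 8)
  fr <- render_scene(truth, chart)
  cast <- apply_color_cast(fr, seed = 12)
  det <- detection_from_homography(truth$homography, chart)
  obs <- filter_overexposed(extract_patch_colors(cast$image,
                                                 locate_patches(det, chart)))
  ccm <- fit_ccm(obs, chart)
  de <- ciede2000(srgb_to_lab(correct_observations(obs, ccm)),
                  chart_reference_lab(chart))
  expect_lt(mean(de), 1)
})

test_that("rejection sampling guarantees distortions worth correcting", {
  chart <- the_chart
  for (s in 1:10) {
    truth <- random_scene_truth(seed = 40 + s, distort = TRUE,
                                min_uncorrected_delta_e = 5)
    distorted <- pmin(pmax(sweep(sweep(
      chart_reference_rgb(chart), 2, truth$gains, `*`),
      2, truth$offsets, `+`), 0), 255)
    de <- mean(ciede2000(srgb_to_lab(distorted),
                         chart_reference_lab(chart)))
    expect_gte(de, 5)
    expect_true(all(truth$gains >= 0.5 & truth$gains <= 1.0))
    expect_true(all(abs(truth$offsets) <= 10))
  }
})

test_that("flight series follows its illumination profile", {
  chart <- the_chart
  # constant profile: gray-patch brightness equal across frames
  sc <- flight_series_spec(4, profile = "constant", illum_start = 0.9,
                           distort = FALSE, noise_sigma = 0, seed = 2)
  series <- generate_flight_series(sc, chart)
  b <- vapply(series, function(fr) {
    det <- detection_from_homography(fr$truth$homography, chart)
    brightness_of_gray_patch(
      extract_patch_colors(fr$frame, locate_patches(det, chart)))
  }, numeric(1))
  expect_lt(max(b) - min(b), 1)
  # linear drift: noiseless brightness sequence strictly decreasing
  sl <- flight_series_spec(6, profile = "linear", illum_start = 1.0,
                           illum_end = 0.5, distort = FALSE,
                           noise_sigma = 0, seed = 3)
  series_l <- generate_flight_series(sl, chart)
  bl <- vapply(series_l, function(fr) {
    det <- detection_from_homography(fr$truth$homography, chart)
    brightness_of_gray_patch(
      extract_patch_colors(fr$frame, locate_patches(det, chart)))
  }, numeric(1))
  expect_true(all(diff(bl) < 0))
  # stochastic walk: reproducible bit-exactly
  sw <- flight_series_spec(5, profile = "walk", seed = 4)
  expect_identical(series_illumination(sw), series_illumination(sw))
  s1 <- generate_flight_series(sw, chart)
  s2 <- generate_flight_series(sw, chart)
  expect_identical(s1[[5]]$frame, s2[[5]]$frame)
})

test_that("exposure settings scale brightness per the sensor model", {
  chart <- the_chart
  exposures <- list(exposure_settings(100, 1 / 100, 8),
                    exposure_settings(150, 1 / 100, 8))
  sc <- flight_series_spec(2, profile = "constant", illum_start = 0.8,
                           distort = FALSE, noise_sigma = 0,
                           exposures = exposures, seed = 9)
  series <- generate_flight_series(sc, chart)
  raw <- vapply(seq_along(series), function(f) {
    det <- detection_from_homography(series[[f]]$truth$homography, chart)
    brightness_of_gray_patch(
      extract_patch_colors(series[[f]]$frame, locate_patches(det, chart)))
  }, numeric(1))
  # the ISO 150 frame is 1.5x brighter raw; normalization equalizes them
  expect_equal(raw[2] / raw[1], 1.5, tolerance = 0.05)
  norm <- vapply(seq_along(series), function(f)
    normalize_brightness(raw[f], series[[f]]$truth$exposure), numeric(1))
  expect_equal(norm[1], norm[2], tolerance = norm[1] * 0.02)
})

test_that("series manifest logs every frame truth", {
  sc <- flight_series_spec(3, profile = "linear", seed = 6)
  series <- generate_flight_series(sc)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_series_manifest(series, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[2])
  expect_equal(rec$frame, 2)
  expect_equal(rec$illumination, series[[2]]$truth$illumination)
  expect_equal(matrix(rec$homography, 3, 3), series[[2]]$truth$homography,
               tolerance = 1e-12)
})
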