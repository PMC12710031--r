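# Expected Lab values frozen from an independent reference conversion
# (scikit-image rgb2lab, D65/2deg).
skimage_lab <- rbind(
  c(119, 119, 119, 50.034439, -0.001398, 0.002649),
  c(255, 0, 0, 53.240588, 80.092308, 67.202751),
  c(0, 128, 255, 54.714539, 18.773464, -70.913764),
  c(10, 200, 30, 70.500132, -70.513831, 64.940840)
)

test_that("sRGB to Lab conversion handles the anchor colors", {
  w <- srgb_to_lab(c(255, 255, 255))
  expect_equal(unname(w["L"]), 100, tolerance = 1e-6)
  expect_lt(abs(w["a"]), 0.01)
  expect_lt(abs(w["b"]), 0.01)
  expect_equal(unname(srgb_to_lab(c(0, 0, 0))), c(0, 0, 0), tolerance = 1e-8)
  for (i in seq_len(nrow(skimage_lab))) {
    lab <- srgb_to_lab(skimage_lab[i, 1:3])
    expect_equal(unname(lab), skimage_lab[i, 4:6], tolerance = 0.01)
  }
})

test_that("sRGB to Lab rejects out-of-range input and is monotone on grays", {
  expect_error(srgb_to_lab(c(-1, 0, 0)), "within")
  expect_error(srgb_to_lab(c(0, 0, 256)), "within")
  g <- seq(0, 255, by = 5)
  L <- srgb_to_lab(cbind(g, g, g))[, "L"]
  expect_true(all(diff(L) > 0))
})

# The full published CIEDE2000 worked-example set (34 Lab pairs with
# reference dE00 to 4 decimals).
ciede2000_pairs <- matrix(c(
  50.0000,2.6772,-79.7751,50.0000,0.0000,-82.7485,2.0425,
  50.0000,3.1571,-77.2803,50.0000,0.0000,-82.7485,2.8615,
  50.0000,2.8361,-74.0200,50.0000,0.0000,-82.7485,3.4412,
  50.0000,-1.3802,-84.2814,50.0000,0.0000,-82.7485,1.0000,
  50.0000,-1.1848,-84.8006,50.0000,0.0000,-82.7485,1.0000,
  50.0000,-0.9009,-85.5211,50.0000,0.0000,-82.7485,1.0000,
  50.0000,0.0000,0.0000,50.0000,-1.0000,2.0000,2.3669,
  50.0000,-1.0000,2.0000,50.0000,0.0000,0.0000,2.3669,
  50.0000,2.4900,-0.0010,50.0000,-2.4900,0.0009,7.1792,
  50.0000,2.4900,-0.0010,50.0000,-2.4900,0.0010,7.1792,
  50.0000,2.4900,-0.0010,50.0000,-2.4900,0.0011,7.2195,
  50.0000,2.4900,-0.0010,50.0000,-2.4900,0.0012,7.2195,
  50.0000,-0.0010,2.4900,50.0000,0.0009,-2.4900,4.8045,
  50.0000,-0.0010,2.4900,50.0000,0.0010,-2.4900,4.8045,
  50.0000,-0.0010,2.4900,50.0000,0.0011,-2.4900,4.7461,
  50.0000,2.5000,0.0000,50.0000,0.0000,-2.5000,4.3065,
  50.0000,2.5000,0.0000,73.0000,25.0000,-18.0000,27.1492,
  50.0000,2.5000,0.0000,61.0000,-5.0000,29.0000,22.8977,
  50.0000,2.5000,0.0000,56.0000,-27.0000,-3.0000,31.9030,
  50.0000,2.5000,0.0000,58.0000,24.0000,15.0000,19.4535,
  50.0000,2.5000,0.0000,50.0000,3.1736,0.5854,1.0000,
  50.0000,2.5000,0.0000,50.0000,3.2972,0.0000,1.0000,
  50.0000,2.5000,0.0000,50.0000,1.8634,0.5757,1.0000,
  50.0000,2.5000,0.0000,50.0000,3.2592,0.3350,1.0000,
  60.2574,-34.0099,36.2677,60.4626,-34.1751,39.4387,1.2644,
  63.0109,-31.0961,-5.8663,62.8187,-29.7946,-4.0864,1.2630,
  61.2901,3.7196,-5.3901,61.4292,2.2480,-4.9620,1.8731,
  35.0831,-44.1164,3.7933,35.0232,-40.0716,1.5901,1.8645,
  22.7233,20.0904,-46.6940,23.0331,14.9730,-42.5619,2.0373,
  36.4612,47.8580,18.3852,36.2715,50.5065,21.2231,1.4146,
  90.8027,-2.0831,1.4410,91.1528,-1.6435,0.0447,1.4441,
  90.9257,-0.5406,-0.9208,88.6381,-0.8985,-0.7239,1.5381,
  6.7747,-0.2908,-2.4247,5.8714,-0.0985,-2.2286,0.6377,
  2.0776,0.0795,-1.1350,0.9033,-0.0636,-0.5514,0.9082
), ncol = 7, byrow = TRUE)

test_that("CIEDE2000 reproduces the published worked examples to 4 decimals", {
  got <- ciede2000(ciede2000_pairs[, 1:3], ciede2000_pairs[, 4:6])
  expect_equal(round(got, 4), ciede2000_pairs[, 7])
})

test_that("CIEDE2000 is symmetric, non-negative, and zero only at identity", {
  set.seed(42)
  x <- cbind(runif(200, 0, 100), runif(200, -80, 80), runif(200, -80, 80))
  y <- cbind(runif(200, 0, 100), runif(200, -80, 80), runif(200, -80, 80))
  expect_equal(ciede2000(x, y), ciede2000(y, x), tolerance = 1e-12)
  expect_true(all(ciede2000(x, y) > 0))
  expect_equal(ciede2000(x, x), rep(0, 200))
})

test_that("CIEDE2000 agrees with an independent implementation", {
  skip_if_not_installed("farver")
  set.seed(7)
  x <- cbind(runif(50, 0, 100), runif(50, -60, 60), runif(50, -60, 60))
  y <- cbind(runif(50, 0, 100), runif(50, -60, 60), runif(50, -60, 60))
  colnames(x) <- colnames(y) <- c("l", "a", "b")
  ref <- diag(farver::compare_colour(x, y, from_space = "lab",
                                     method = "cie2000"))
  expect_equal(ciede2000(x, y), unname(ref), tolerance = 1e-6)
})

test_that("brightness normalization follows the exposure formula", {
  ref <- reference_exposure()
  expect_equal(normalize_brightness(120, ref), 120)
  # ISO 400 at reference shutter/aperture quarters the value
  expect_equal(normalize_brightness(120, exposure_settings(400, 1 / 100, 8)),
               30)
  # ISO 200 with 1/200 s cancels exactly
  expect_equal(normalize_brightness(87.5, exposure_settings(200, 1 / 200, 8)),
               87.5)
  # multiplicative in each factor independently
  base <- normalize_brightness(100, exposure_settings(100, 0.01, 8))
  expect_equal(normalize_brightness(100, exposure_settings(200, 0.01, 8)),
               base / 2)
  expect_equal(normalize_brightness(100, exposure_settings(100, 0.02, 8)),
               base / 2)
  expect_equal(normalize_brightness(100, exposure_settings(100, 0.01, 16)),
               base * 4)
  expect_error(exposure_settings(0, 0.01, 8), "positive")
  expect_error(exposure_settings(100, -1, 8), "positive")
})

test_that("gray-patch brightness is the mean of patch 22 channels", {
  rgb <- matrix(rep(c(10, 20, 30), each = 24), 24, 3)
  rgb[22, ] <- c(100, 110, 120)
  obs <- patch_observations(rgb)
  expect_equal(brightness_of_gray_patch(obs), 110)
  rgb[22, ] <- c(88, 88, 88)
  expect_equal(brightness_of_gray_patch(patch_observations(rgb)), 88)
  obs_excl <- patch_observations(rgb)
  obs_excl$patches$included[22] <- FALSE
  expect_error(brightness_of_gray_patch(obs_excl), "overexposed")
})

test_that("intracluster distance matches closed forms and brute force", {
  expect_equal(intracluster_distance(matrix(5, 4, 3)), 0)
  # two points distance d apart: each d/2 from the midpoint centroid
  a <- c(10, 4, -3); b <- c(40, -8, 9)
  d <- sqrt(sum((a - b)^2))
  expect_equal(intracluster_distance(rbind(a, b)), d / 2)
  set.seed(11)
  cl <- matrix(rnorm(18, sd = 20), 6, 3)
  ctr <- colMeans(cl)
  brute <- mean(apply(cl, 1, function(p) sqrt(sum((p - ctr)^2))))
  expect_equal(intracluster_distance(cl), brute, tolerance = 1e-12)
  expect_error(intracluster_distance(matrix(1, 1, 3)), "at least 2")
})

test_that("intracluster distance is translation invariant and scales linearly", {
  set.seed(3)
  cl <- matrix(rnorm(15, sd = 10), 5, 3)
  d0 <- intracluster_distance(cl)
  expect_equal(intracluster_distance(sweep(cl, 2, c(30, -12, 7), `+`)), d0,
               tolerance = 1e-12)
  ctr <- colMeans(cl)
  scaled <- sweep(sweep(cl, 2, ctr) * 2.5, 2, ctr, `+`)
  expect_equal(intracluster_distance(scaled), 2.5 * d0, tolerance = 1e-12)
})

test_that("exposure sidecar table round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(image_id = c("a", "b"), iso = c(100, 400),
                       shutter_s = c(0.01, 0.002), aperture_n = c(8, 5.6)),
            path, row.names = FALSE)
  tab <- read_exposure_table(path)
  expect_named(tab, c("a", "b"))
  expect_equal(tab$b$iso, 400)
  expect_equal(tab$b$shutter_s, 0.002)
})
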