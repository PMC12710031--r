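ref_rgb <- chart_reference_rgb(load_reference_chart())

test_that("overexposure filtering uses a strict threshold per channel", {
  rgb <- matrix(100, 24, 3)
  rgb[3, ] <- c(255, 120, 80)    # one channel over
  rgb[7, ] <- c(250, 250, 250)   # exactly at the threshold
  obs <- filter_overexposed(patch_observations(rgb), threshold = 250)
  expect_false(obs$patches$included[3])
  expect_true(obs$patches$included[7])
  expect_equal(sum(!obs$patches$included), 1L)
  # nothing over: all retained
  obs2 <- filter_overexposed(patch_observations(matrix(100, 24, 3)))
  expect_true(all(obs2$patches$included))
  expect_error(filter_overexposed(obs, threshold = 0), "threshold")
})

test_that("CCM fit solves the exact cases in closed form", {
  chart <- load_reference_chart()
  # observations equal the reference: identity mapping, zero bias
  obs <- patch_observations(ref_rgb)
  ccm <- fit_ccm(obs, chart)
  expect_equal(ccm$M, rbind(diag(3), 0), tolerance = 1e-9)
  expect_equal(ccm$fit_residual_rms, 0, tolerance = 1e-9)
  expect_equal(ccm$patches_used, 1:24)
  # observations at half the reference: gain of 2, zero bias
  ccm2 <- fit_ccm(patch_observations(ref_rgb * 0.5), chart)
  expect_equal(ccm2$M, rbind(2 * diag(3), 0), tolerance = 1e-9)
})

test_that("CCM fit matches the normal-equations formula on random data", {
  chart <- load_reference_chart()
  set.seed(13)
  A_rgb <- matrix(runif(72, 10, 240), 24, 3)
  ccm <- fit_ccm(patch_observations(A_rgb), chart)
  # independent oracle: the textbook normal-equations solution
  A <- cbind(A_rgb, 1)
  C <- ref_rgb
  M_oracle <- solve(t(A) %*% A) %*% t(A) %*% C
  expect_equal(ccm$M, unname(M_oracle), tolerance = 1e-8)
})

test_that("CCM fit enforces patch count and rank requirements", {
  chart <- load_reference_chart()
  obs <- patch_observations(ref_rgb)
  obs$patches$included[1:20] <- FALSE
  expect_error(fit_ccm(obs, chart), "at least 6")
  obs2 <- patch_observations(ref_rgb)
  obs2$patches$included[1:17] <- FALSE
  expect_warning(fit_ccm(obs2, chart), ">= 9")
  # collinear observations: rank deficient
  gray <- matrix(rep(seq(20, 230, length.out = 24), 3), 24, 3)
  expect_error(suppressWarnings(fit_ccm(patch_observations(gray), chart)),
               "rank deficient")
})

test_that("applying a CCM equals brute-force per-pixel arithmetic", {
  M <- rbind(c(1.1, 0.02, -0.03),
             c(-0.05, 0.95, 0.1),
             c(0.01, -0.02, 1.2),
             c(4, -6, 2))
  set.seed(21)
  img <- array(runif(27, 0, 230), c(3, 3, 3))
  out <- apply_ccm(img, M)
  for (r in 1:3) for (c in 1:3) {
    px <- c(img[r, c, ], 1)
    expect_equal(out[r, c, ], pmin(pmax(as.vector(px %*% M), 0), 255),
                 tolerance = 1e-12)
  }
  # identity matrix leaves the image unchanged
  expect_equal(apply_ccm(img, rbind(diag(3), 0)), img)
  # out-of-gamut values clip to [0, 255]
  M_neg <- rbind(diag(3), c(-300, 0, 0))
  expect_true(all(apply_ccm(img, M_neg)[, , 1] == 0))
  expect_error(apply_ccm(img / 255, M), "0-1 scale")
  expect_error(apply_ccm(img, matrix(NaN, 4, 3)), "finite")
})

test_that("fit and apply recover gain/offset distortions of the chart", {
  chart <- load_reference_chart()
  set.seed(31)
  for (rep in 1:5) {
    G <- diag(runif(3, 0.5, 0.92))
    G[1, 2] <- runif(1, -0.03, 0.03)  # mild channel mixing
    o <- runif(3, -3, 8)
    distorted <- sweep(ref_rgb %*% G, 2, o, `+`)
    expect_true(all(distorted >= 0 & distorted <= 255))  # no clipping
    obs <- patch_observations(distorted)
    ccm <- fit_ccm(obs, chart)
    corrected <- correct_observations(obs, ccm)
    de <- ciede2000(srgb_to_lab(corrected), chart_reference_lab(chart))
    expect_lt(mean(de), 0.5)
    expect_lt(max(de), 0.5)
  }
})

test_that("correcting an already-corrected chart gives an identity CCM", {
  chart <- load_reference_chart()
  obs <- patch_observations(ref_rgb * 0.7)
  ccm <- fit_ccm(obs, chart)
  corrected <- correct_observations(obs, ccm)
  ccm2 <- fit_ccm(patch_observations(corrected), chart)
  expect_equal(ccm2$M, rbind(diag(3), 0), tolerance = 1e-6)
})

test_that("excluding a few patches barely moves the corrected colors", {
  chart <- load_reference_chart()
  set.seed(17)
  distorted <- sweep(ref_rgb %*% diag(c(0.8, 0.9, 0.7)), 2, c(5, -3, 8), `+`)
  obs_full <- patch_observations(distorted)
  de_full <- ciede2000(srgb_to_lab(correct_observations(
    obs_full, fit_ccm(obs_full, chart))), chart_reference_lab(chart))
  for (rep in 1:5) {
    obs_k <- patch_observations(distorted)
    obs_k$patches$included[sample(24, 3)] <- FALSE
    de_k <- ciede2000(srgb_to_lab(correct_observations(
      obs_k, fit_ccm(obs_k, chart))), chart_reference_lab(chart))
    expect_lt(max(abs(de_k - de_full)), 0.5)
  }
})

test_that("patch-count sensitivity reduces to the full fit at n = 24", {
  chart <- load_reference_chart()
  set.seed(23)
  distorted <- pmin(pmax(
    sweep(ref_rgb %*% diag(c(0.7, 0.85, 0.6)), 2, c(4, -2, 7), `+`) +
      matrix(rnorm(72, 0, 1.5), 24, 3), 0), 255)
  obs <- patch_observations(distorted)
  sens <- patch_count_sensitivity(obs, chart, counts = c(6, 12, 24),
                                  replicates = 5, seed = 2)
  baseline <- mean_patch_delta_e(obs, chart, fit_ccm(obs, chart))
  expect_equal(sens$mean_delta_e[sens$n_patches == 24], baseline,
               tolerance = 1e-9)
  # undistorted chart: nothing to correct at any count
  sens0 <- suppressWarnings(patch_count_sensitivity(
    patch_observations(ref_rgb), chart, counts = c(6, 12, 24),
    replicates = 3, seed = 3))
  expect_true(all(sens0$mean_delta_e < 0.01))
  expect_warning(
    patch_count_sensitivity(obs, chart, counts = c(3, 24), replicates = 2),
    "skipping")
})

test_that("CCM JSON serialization round-trips", {
  chart <- load_reference_chart()
  ccm <- fit_ccm(patch_observations(ref_rgb * 0.8, image_id = "img1"), chart)
  path <- withr::local_tempfile(fileext = ".json")
  write_ccm_json(ccm, path)
  back <- read_ccm_json(path)
  expect_equal(back$M, ccm$M, tolerance = 1e-12)
  expect_equal(back$patches_used, ccm$patches_used)
  expect_equal(back$fit_residual_rms, ccm$fit_residual_rms, tolerance = 1e-12)
})
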