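test_that("a uniform noise-free ring is recovered within 2% by 63-ray profiling", {
  for (radius in c(10, 17.5)) {
    p <- make_ring_plane(nr = 80, nc = 80, r0 = 40.3, c0 = 39.6,
                         radius = radius, sigma = 1.5, amplitude = 1000)
    rec <- radial_membrane_intensity(p, fake_detection(40.3, 39.6, radius))
    expect_equal(rec$n_rays_used, 63L)
    expect_equal(rec$mean_membrane_intensity, 1000, tolerance = 0.02)
  }
})

test_that("profiling is invariant to a 90-degree rotation at matched angles", {
  p <- make_ring_plane(r0 = 30, c0 = 34, radius = 11, sigma = 1.5)
  angles <- 2 * pi * (0:62) / 63
  rec <- radial_membrane_intensity(p, fake_detection(30, 34, 11),
                                   angles = angles)
  n <- nrow(unclass(p))
  rot <- image_plane(t(unclass(p))[, n:1], 1)  # (r, c) -> (c, n + 1 - r)
  rec_rot <- radial_membrane_intensity(rot, fake_detection(34, n + 1 - 30, 11),
                                       angles = angles - pi / 2)
  expect_equal(rec_rot$per_ray_max, rec$per_ray_max, tolerance = 1e-6)
})

test_that("per-ray maxima scale exactly and shift exactly with the image", {
  p <- make_ring_plane(radius = 9, sigma = 1.2)
  det <- fake_detection(32, 32, 9)
  base <- radial_membrane_intensity(p, det)
  scaled <- radial_membrane_intensity(image_plane(unclass(p) * 3.5, 1), det)
  expect_equal(scaled$per_ray_max, 3.5 * base$per_ray_max, tolerance = 1e-12)
  shifted <- radial_membrane_intensity(image_plane(unclass(p) + 250, 1), det)
  expect_equal(shifted$per_ray_max, base$per_ray_max + 250, tolerance = 1e-9)
})

test_that("angularly modulated rings agree with an exhaustive annulus oracle within 3%", {
  nr <- 96; nc <- 96; r0 <- 48; c0 <- 48; radius <- 16; sigma <- 1.5
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((rows - r0)^2 + (cols - c0)^2)
  theta <- atan2(rows - r0, cols - c0)
  for (mphase in c(0, 1)) {
    amp <- 1000 * (1 + 0.3 * sin(3 * theta + mphase))
    p <- image_plane(amp * exp(-(d - radius)^2 / (2 * sigma^2)), 1)
    rec <- radial_membrane_intensity(p, fake_detection(r0, c0, radius))
    ref <- oracle_sector_max(unclass(p), r0, c0, radius, 3 * sigma, 63L)
    expect_equal(rec$mean_membrane_intensity, mean(ref), tolerance = 0.03)
    # per-ray max statistic dominates the annulus mean
    annulus <- abs(d - radius) <= 3 * sigma
    expect_gte(rec$mean_membrane_intensity, mean(unclass(p)[annulus]))
  }
})

test_that("rays leaving the image are dropped and counted; losing all rays errors", {
  p <- make_ring_plane(nr = 48, nc = 48, r0 = 24, c0 = 6, radius = 8,
                       sigma = 1)
  rec <- radial_membrane_intensity(p, fake_detection(24, 6, 8))
  expect_lt(rec$n_rays_used, 63L)
  expect_gt(rec$n_rays_used, 0L)
  expect_error(radial_membrane_intensity(p, fake_detection(24, 6, 100)),
               "all rays exit")
  expect_error(radial_membrane_intensity(p, fake_detection(24, 6, 8),
                                         n_angles = 2L), "n_angles")
})

test_that("measured membrane intensity tracks generator truth with unit slope", {
  truth <- c(); meas <- c()
  for (s in 1:3) {
    out <- generate_vesicle_image(image_spec(
      height_px = 400L, width_px = 400L, n_vesicles = 12L,
      reporter_enriched_fraction = 1, psf_sigma_um = 0,
      read_noise_sigma = 20, shot_noise = FALSE, seed = 30 + s))
    det <- detect_lumina(out$membrane)
    prof <- profile_detections(out$reporter, det)
    for (i in seq_len(nrow(det))) {
      j <- which.min((out$truth$centroid_row_px - det$centroid_row_px[i])^2 +
                       (out$truth$centroid_col_px - det$centroid_col_px[i])^2)
      truth <- c(truth, out$truth$true_membrane_reporter_intensity[j])
      meas <- c(meas, prof$mean_membrane_intensity[i])
    }
  }
  expect_gte(length(truth), 30)
  slope <- coef(lm(meas ~ truth))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)
})

test_that("line profiles interpolate exactly on constants and integer pixels", {
  p <- image_plane(matrix(7.5, 32, 32), 0.2)
  prof <- extract_line_profile(p, c(5, 5), c(28, 20))
  expect_equal(prof$intensity, rep(7.5, nrow(prof)), tolerance = 1e-12)
  expect_equal(prof$position_um[1], 0)
  expect_true(all(diff(prof$position_um) > 0))

  set.seed(3)
  q <- image_plane(matrix(runif(32 * 32), 32, 32), 1)
  # horizontal profile with unit step lands on integer pixels: raw values
  prof <- extract_line_profile(q, c(10, 3), c(10, 30), step_px = 1)
  expect_equal(prof$intensity, unclass(q)[10, 3:30], tolerance = 1e-12)
  expect_error(extract_line_profile(q, c(5, 5), c(5, 5)), "zero-length")
})

test_that("a profile through a ring center is symmetric with two maxima", {
  p <- make_ring_plane(r0 = 32, c0 = 32, radius = 10, sigma = 1.5,
                       amplitude = 500, background = 20)
  prof <- extract_line_profile(p, c(32, 12), c(32, 52), step_px = 0.5)
  res <- two_peak_membrane_intensity(prof, min_prominence = 100)
  expect_true(res$accepted)
  expect_equal(res$mean_peak_intensity, 520, tolerance = 0.02)
  expect_equal(abs(mean(res$peak_positions_um) - 20), 0, tolerance = 0.6)
})

test_that("two-peak selection returns the mean of exactly two peaks, else a verdict", {
  pos <- seq(0, 20, by = 0.1)
  two <- 100 * exp(-(pos - 6)^2 / 0.5) + 120 * exp(-(pos - 14)^2 / 0.5)
  res <- two_peak_membrane_intensity(
    data.frame(position_um = pos, intensity = two), min_prominence = 10)
  expect_true(res$accepted)
  expect_equal(res$mean_peak_intensity, 110, tolerance = 1e-3)

  flat <- data.frame(position_um = pos, intensity = rep(5, length(pos)))
  res0 <- two_peak_membrane_intensity(flat, min_prominence = 1)
  expect_false(res0$accepted)
  expect_equal(res0$n_peaks, 0L)
  expect_match(res0$reason, "found 0")

  three <- two + 90 * exp(-(pos - 10)^2 / 0.5)
  res3 <- two_peak_membrane_intensity(
    data.frame(position_um = pos, intensity = three), min_prominence = 10)
  expect_false(res3$accepted)
  expect_gte(res3$n_peaks, 3L)

  # separation suppression: twin sub-peaks closer than the minimum
  # separation collapse onto the higher one
  twin <- 100 * exp(-(pos - 6)^2 / 0.5) + 95 * exp(-(pos - 7.2)^2 / 0.5) +
    120 * exp(-(pos - 14)^2 / 0.5)
  res_sep <- two_peak_membrane_intensity(
    data.frame(position_um = pos, intensity = twin),
    min_prominence = 5, min_separation_um = 3)
  expect_true(res_sep$accepted)
})
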