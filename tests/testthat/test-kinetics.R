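test_that("a noiseless logistic is recovered to 1e-4 with max rate A*k/4", {
  t <- seq(0, 960, by = 30)
  y <- logistic4(t, 100, 400, 0.02, 180)
  f <- fit_sigmoid(t, y)
  expect_true(f$converged)
  expect_true(f$responder)
  truth <- c(baseline = 100, amplitude = 400, k = 0.02, t0 = 180)
  expect_true(all(abs(coef(f) - truth) / truth < 1e-4))
  expect_equal(f$max_rate, 2, tolerance = 1e-4)
  expect_equal(f$plateau_time_h, (180 + log(19) / 0.02) / 60, tolerance = 1e-4)
  expect_lt(f$residual_rms, 1e-6)
})

test_that("a flat trace is not a responder", {
  t <- seq(0, 600, by = 30)
  set.seed(5)
  f <- fit_sigmoid(t, rnorm(length(t), 100, 3))
  expect_false(f$responder)
})

test_that("fit object methods are mutually consistent", {
  t <- seq(0, 900, by = 20)
  y <- logistic4(t, 50, 300, 0.03, 400) + sin(t / 50)
  f <- fit_sigmoid(t, y, vesicle_id = 7L)
  expect_equal(fitted(f), predict(f, t))
  expect_equal(residuals(f), y - fitted(f))
  expect_equal(f$residual_rms, sqrt(mean(residuals(f)^2)))
  expect_equal(f$vesicle_id, 7L)
  expect_output(print(f), "responder")
})

test_that("rescaling time rescales rate and plateau inversely (noiseless)", {
  t <- seq(0, 960, by = 15)
  y <- logistic4(t, 80, 350, 0.025, 300)
  f1 <- fit_sigmoid(t, y)
  f2 <- fit_sigmoid(t * 3, y)
  expect_equal(f2$max_rate, f1$max_rate / 3, tolerance = 1e-4)
  expect_equal(f2$plateau_time_h, f1$plateau_time_h * 3, tolerance = 1e-4)
})

test_that("affine intensity transforms map baseline, amplitude and rate linearly", {
  t <- seq(0, 960, by = 15)
  y <- logistic4(t, 80, 350, 0.025, 300)
  f1 <- fit_sigmoid(t, y)
  f2 <- fit_sigmoid(t, 2.5 * y + 40)
  expect_equal(coef(f2)[["baseline"]], 2.5 * coef(f1)[["baseline"]] + 40,
               tolerance = 1e-4)
  expect_equal(coef(f2)[["amplitude"]], 2.5 * coef(f1)[["amplitude"]],
               tolerance = 1e-4)
  expect_equal(f2$max_rate, 2.5 * f1$max_rate, tolerance = 1e-4)
})

test_that("cohort fitting recovers rates on a small noisy cohort", {
  gen <- generate_kinetic_traces(trace_spec(n_liposomes = 12L,
                                            trace_noise_sigma = 20,
                                            nonresponder_fraction = 0,
                                            seed = 3))
  fits <- fit_sigmoid_cohort(gen$traces)
  m <- merge(fits, gen$truth, by = "vesicle_id")
  rel <- abs(m$max_rate_au_per_min.x - m$max_rate_au_per_min.y) /
    m$max_rate_au_per_min.y
  expect_lt(median(rel), 0.15)
  expect_true(all(fits$converged))
})

test_that("fitted kinetic parameters show no artefactual dependence on vesicle radius", {
  # radius-independent truth: any fitted rate-vs-radius slope must be
  # consistent with zero
  gen <- generate_kinetic_traces(trace_spec(n_liposomes = 40L,
                                            trace_noise_sigma = 20,
                                            nonresponder_fraction = 0,
                                            seed = 14))
  fits <- fit_sigmoid_cohort(gen$traces)
  set.seed(15)
  radius <- runif(40, 2, 6)   # apparent radii 2-6 um, unrelated to kinetics
  sm <- summary(lm(fits$max_rate_au_per_min ~ radius))$coefficients
  expect_gt(sm["radius", "Pr(>|t|)"], 0.01)
})

test_that("trace validation errors are informative and non-convergence is not an exception", {
  expect_error(fit_sigmoid(c(1, 2, 3), c(1, 2, 3)), ">= 5")
  expect_error(fit_sigmoid(c(3, 2, 1, 4, 5), rep(1, 5)), "increasing")
})

test_that("radius change uses first/last time points and 0.25-um bins centered on 0", {
  radii <- data.frame(vesicle_id = rep(1:3, each = 3),
                      time_min = rep(c(0, 480, 960), 3),
                      apparent_radius_um = c(3, 3.1, 3,      # no change
                                             4, 4.2, 4.6,    # +0.6 um
                                             5, NA, NA))     # missing endpoint
  rc <- radius_change(radii)
  expect_equal(nrow(rc$delta_r), 2L)
  expect_equal(rc$delta_r$delta_r_um[rc$delta_r$vesicle_id == 1], 0)
  expect_equal(rc$delta_r$delta_r_um[rc$delta_r$vesicle_id == 2], 0.6)
  expect_equal(rc$skipped$vesicle_id, 3)
  expect_equal(sum(rc$histogram$mass), 1)
  # bin centers are multiples of 0.25 and include 0
  expect_true(all(abs(rc$histogram$bin_center_um / 0.25 -
                        round(rc$histogram$bin_center_um / 0.25)) < 1e-9))
  center_bin <- which(abs(rc$histogram$bin_center_um) < 1e-9)
  expect_equal(rc$histogram$mass[center_bin], 0.5)
  # +0.6 falls within one bin of +0.6
  hit <- rc$histogram$bin_center_um[rc$histogram$mass > 0]
  expect_true(any(abs(hit - 0.6) <= 0.25 + 1e-9))
})

test_that("time-point linking is mutual-nearest with a shift cap", {
  det_a <- data.frame(id = 1:3, centroid_row_px = c(10, 40, 70),
                      centroid_col_px = c(10, 40, 70))
  ident <- link_timepoints(det_a, det_a, max_shift_um = 1, pixel_size_um = 0.2)
  expect_equal(ident$matches$id_a, ident$matches$id_b)
  expect_length(ident$unmatched_a, 0L)

  det_b <- det_a
  det_b$centroid_row_px <- det_b$centroid_row_px + 0.5  # 0.1 um shift
  shifted <- link_timepoints(det_a, det_b, max_shift_um = 1,
                             pixel_size_um = 0.2)
  expect_equal(shifted$matches$id_a, shifted$matches$id_b)

  decoy <- rbind(det_b, data.frame(id = 9L, centroid_row_px = 200,
                                   centroid_col_px = 200))
  with_decoy <- link_timepoints(det_a, decoy, max_shift_um = 1,
                                pixel_size_um = 0.2)
  expect_equal(nrow(with_decoy$matches), 3L)
  expect_equal(with_decoy$unmatched_b, 9L)
})
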