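test_that("a single noise-free ring yields one detection at the true center and radius", {
  out <- generate_vesicle_image(noise_free_spec(
    height_px = 64L, width_px = 64L, pixel_size_um = 1, n_vesicles = 1L,
    radius_range_um = c(10, 10), ring_sigma_um = 0.5, seed = 6))
  det <- detect_lumina(out$membrane, segmentation_params())
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$centroid_row_px - out$truth$centroid_row_px), 1)
  expect_lt(abs(det$centroid_col_px - out$truth$centroid_col_px), 1)
  expect_lt(abs(det$radius_px - 10), 1)
  expect_gt(det$circularity, 0.85)
})

test_that("blank and all-zero images give an empty detection table, not an error", {
  blank <- image_plane(matrix(0, 32, 32), 1)
  det <- detect_lumina(blank, segmentation_params(threshold_method = "fixed",
                                                  fixed_threshold = 10))
  expect_equal(nrow(det), 0L)
  expect_named(det, c("id", "centroid_row_px", "centroid_col_px", "area_px2",
                      "perimeter_px", "radius_px", "apparent_radius_um",
                      "circularity", "touches_border"))
})

test_that("non-finite pixels are rejected as an input error", {
  bad <- matrix(1, 16, 16); bad[3, 3] <- NA
  expect_error(detect_lumina(bad, pixel_size_um = 1), "non-finite")
})

test_that("a ring inside the border margin is excluded", {
  p <- matrix(0, 48, 48)
  p <- render_ring(p, 10, 10, 9, 0.8, 1000)  # lumen bbox reaches the margin
  det <- detect_lumina(image_plane(p, 1),
                       segmentation_params(threshold_method = "fixed",
                                           fixed_threshold = 500,
                                           min_area_px = 10L,
                                           border_margin_px = 4L))
  expect_equal(nrow(det), 0L)
})

test_that("flood-fill lumen labelling matches a brute-force BFS oracle on small images", {
  for (s in 1:4) {
    out <- generate_vesicle_image(noise_free_spec(
      height_px = 64L, width_px = 64L, pixel_size_um = 1, n_vesicles = 2L,
      radius_range_um = c(6, 9), ring_sigma_um = 0.8, seed = 100 + s))
    thr <- 500
    ref <- oracle_lumen_labels(unclass(out$membrane), thr)
    det <- detect_lumina(out$membrane,
                         segmentation_params(threshold_method = "fixed",
                                             fixed_threshold = thr,
                                             min_area_px = 1L,
                                             circularity_min = 0.01,
                                             border_margin_px = 0L))
    ref_areas <- sort(as.integer(table(ref[ref > 0])))
    expect_equal(sort(det$area_px2), as.numeric(ref_areas))
    expect_equal(nrow(det), max(ref))
    # centroids agree pairwise
    for (l in seq_len(max(ref))) {
      px <- which(ref == l, arr.ind = TRUE)
      i <- which.min((det$centroid_row_px - mean(px[, 1]))^2 +
                       (det$centroid_col_px - mean(px[, 2]))^2)
      expect_equal(det$centroid_row_px[i], mean(px[, 1]))
      expect_equal(det$centroid_col_px[i], mean(px[, 2]))
    }
  }
})

test_that("the internal Otsu threshold agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(7)
  # well-separated modes with an empty valley: any Otsu maximizer lies in
  # the valley, so the induced binarization is the meaningful comparison
  x <- c(rnorm(4000, 0.15, 0.02), rnorm(1000, 0.8, 0.02))
  x <- pmin(pmax(x, 0), 1)
  img <- matrix(x, 50, 100)
  ours <- vesiquant:::otsu_threshold(img, n_bins = 256L)
  ref <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  expect_identical(img >= ours, img >= ref)
  # and ours maximizes the between-class variance over its own binning
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(x, edges, all.inside = TRUE), 256)
  pr <- h / sum(h)
  centers <- (edges[-1] + edges[-257]) / 2
  bc <- vapply(1:255, function(k) {
    w0 <- sum(pr[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    mu0 <- sum(pr[1:k] * centers[1:k]) / w0
    mu1 <- sum(pr[(k + 1):256] * centers[(k + 1):256]) / w1
    w0 * w1 * (mu0 - mu1)^2
  }, numeric(1))
  expect_equal(ours, centers[which.max(bc)])
})

test_that("apparent radius follows the perfect-circle identity, with its documented bias", {
  expect_equal(apparent_radius(62.831853, 1), 10, tolerance = 1e-7)
  expect_equal(apparent_radius(2 * pi, 0.2), 0.2, tolerance = 1e-12)
  # a square lumen of side s has perimeter 4 s, so the perfect-circle
  # assumption reports 2 s / pi instead of the true half-diagonal
  s <- 7
  expect_equal(apparent_radius(4 * s, 1), 2 * s / pi)
  expect_error(apparent_radius(0, 1), "positive")
})

test_that("circularity separates discs from elongated regions and matches a pixel-counting oracle", {
  # perfect disc: kept at the stringent cutoff
  p <- matrix(1000, 48, 48)
  p[disc_mask(48, 48, 24, 24, 12)] <- 0
  det <- detect_lumina(image_plane(p, 1),
                       segmentation_params(threshold_method = "fixed",
                                           fixed_threshold = 500))
  expect_equal(nrow(det), 1L)
  expect_gt(det$circularity, 0.85)

  # 1 x N line-like region: discarded at any reasonable cutoff
  p <- matrix(1000, 32, 32)
  p[16, 5:28] <- 0
  det_all <- detect_lumina(image_plane(p, 1),
                           segmentation_params(threshold_method = "fixed",
                                               fixed_threshold = 500,
                                               min_area_px = 5L,
                                               circularity_min = 0.01))
  expect_equal(nrow(det_all), 1L)
  expect_lt(det_all$circularity, 0.5)

  # rasterised 2:1 ellipse: circularity equals the brute-force
  # perimeter/area recomputation
  m <- ellipse_mask(96, 96, 48, 48, 20, 40)
  p <- matrix(1000, 96, 96); p[m] <- 0
  det <- detect_lumina(image_plane(p, 1),
                       segmentation_params(threshold_method = "fixed",
                                           fixed_threshold = 500,
                                           circularity_min = 0.01,
                                           border_margin_px = 0L))
  expect_equal(nrow(det), 1L)
  per_ref <- oracle_perimeter(m)
  circ_ref <- 4 * pi * sum(m) / per_ref^2
  expect_equal(det$circularity, circ_ref, tolerance = 1e-6)
})

test_that("raising the circularity cutoff never increases the kept count", {
  out <- generate_vesicle_image(image_spec(n_vesicles = 12L,
                                           height_px = 400L, width_px = 400L,
                                           seed = 13))
  det <- detect_lumina(out$membrane,
                       segmentation_params(circularity_min = 0.01))
  kept <- vapply(seq(0.1, 1, by = 0.1),
                 function(cm) nrow(circularity_filter(det, cm)$kept),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
  # and the partition is exhaustive and order-preserving
  parts <- circularity_filter(det, 0.9)
  expect_equal(nrow(parts$kept) + nrow(parts$discarded), nrow(det))
  expect_true(!is.unsorted(parts$kept$id))
  expect_true(!is.unsorted(parts$discarded$id))
})

test_that("rotating the field by 90 degrees permutes detections with mapped centroids", {
  out <- generate_vesicle_image(noise_free_spec(
    height_px = 96L, width_px = 96L, pixel_size_um = 1, n_vesicles = 3L,
    radius_range_um = c(6, 10), ring_sigma_um = 0.8, seed = 17))
  par <- segmentation_params(threshold_method = "fixed", fixed_threshold = 500)
  det <- detect_lumina(out$membrane, par)
  n <- nrow(unclass(out$membrane))
  rot <- image_plane(t(unclass(out$membrane))[, n:1], 1)  # 90 deg CCW... (r,c)->(c, n+1-r)
  det_rot <- detect_lumina(rot, par)
  expect_equal(nrow(det_rot), nrow(det))
  mapped_row <- det$centroid_col_px
  mapped_col <- n + 1 - det$centroid_row_px
  for (i in seq_len(nrow(det))) {
    j <- which.min((det_rot$centroid_row_px - mapped_row[i])^2 +
                     (det_rot$centroid_col_px - mapped_col[i])^2)
    expect_lt(abs(det_rot$centroid_row_px[j] - mapped_row[i]), 1e-9)
    expect_lt(abs(det_rot$radius_px[j] - det$radius_px[i]), 0.5)
  }
})

test_that("nested lumina keep only the outermost region", {
  p <- matrix(0, 80, 80)
  p <- render_ring(p, 40, 40, 25, 0.8, 1000)  # outer membrane
  p <- render_ring(p, 40, 40, 12, 0.8, 1000)  # inner membrane (multilamellar look)
  det <- detect_lumina(image_plane(p, 1),
                       segmentation_params(threshold_method = "fixed",
                                           fixed_threshold = 500,
                                           min_area_px = 10L,
                                           circularity_min = 0.01))
  # annulus between the rings is the outermost lumen; the inner disc is nested
  expect_equal(nrow(det), 1L)
  expect_gt(det$area_px2, pi * 12^2)
})
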