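# Small programmatic fixtures.

make_ring_plane <- function(nr = 64, nc = 64, r0 = 32, c0 = 32, radius = 10,
                            sigma = 1.5, amplitude = 1000, background = 0,
                            pixel_size_um = 1) {
  p <- matrix(background, nr, nc)
  p <- render_ring(p, r0, c0, radius, sigma, amplitude)
  image_plane(p, pixel_size_um)
}

disc_mask <- function(nr, nc, r0, c0, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - r0)^2 + (cols - c0)^2 <= radius^2
}

ellipse_mask <- function(nr, nc, r0, c0, a_row, a_col) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rows - r0) / a_row)^2 + ((cols - c0) / a_col)^2 <= 1
}

# membrane image whose rings sit exactly on a binary mask boundary is not
# needed; for segmentation tests a bright ring with dark lumen suffices
noise_free_spec <- function(...) {
  image_spec(psf_sigma_um = 0, read_noise_sigma = 0, shot_noise = FALSE, ...)
}

# detections table row for a known circle (for profiling tests)
fake_detection <- function(row, col, radius_px, id = 1L) {
  data.frame(id = id, centroid_row_px = row, centroid_col_px = col,
             radius_px = radius_px)
}
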