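#' Specification for a synthetic two-channel vesicle image
#'
#' Describes a field of equatorially sectioned giant unilamellar vesicles:
#' each vesicle appears as a ring whose radial cross-section is Gaussian,
#' `I(d) = A exp(-(d - r)^2 / (2 sigma^2))`, the profile of a thin bilayer
#' convolved with the microscope point-spread function. The membrane-dye
#' channel shows every ring at `membrane_peak_intensity`; the reporter
#' channel shows the same rings scaled per vesicle. A configurable fraction
#' of vesicles is "enriched": their reporter ring amplitude is drawn from a
#' lognormal distribution (matching the wide, right-skewed single-vesicle
#' intensity distributions seen for heterogeneous in-liposome synthesis);
#' the rest sit at the reporter background level.
#'
#' @param height_px,width_px Image size in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param n_vesicles Number of vesicles to place (may be 0).
#' @param radius_range_um Length-2 vector, min/max vesicle radius (um).
#' @param ring_sigma_um Gaussian cross-section width of the ring (um).
#' @param membrane_peak_intensity Ring peak amplitude in the membrane
#'   channel (a.u.).
#' @param reporter_enriched_fraction Probability a vesicle is enriched.
#' @param reporter_lognormal_mu,reporter_lognormal_sigma Log-scale mean and
#'   SD of the enriched reporter ring amplitude.
#' @param reporter_background_intensity Uniform reporter background (a.u.);
#'   also the ring amplitude of non-enriched vesicles.
#' @param psf_sigma_um Gaussian PSF blur applied to both channels (um);
#'   0 disables.
#' @param read_noise_sigma Additive Gaussian read noise SD (a.u.); 0 disables.
#' @param shot_noise Logical; apply Poisson shot noise to the signal.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An `image_spec` list.
#' @seealso [generate_vesicle_image()]
#' @export
image_spec <- function(height_px = 256L, width_px = 256L,
                       pixel_size_um = 0.2, n_vesicles = 20L,
                       radius_range_um = c(2, 6), ring_sigma_um = 0.3,
                       membrane_peak_intensity = 3000,
                       reporter_enriched_fraction = 0.5,
                       reporter_lognormal_mu = log(800),
                       reporter_lognormal_sigma = 0.8,
                       reporter_background_intensity = 100,
                       psf_sigma_um = 0, read_noise_sigma = 20,
                       shot_noise = TRUE, seed = 1L) {
  spec <- list(height_px = as.integer(height_px),
               width_px = as.integer(width_px),
               pixel_size_um = pixel_size_um, n_vesicles = as.integer(n_vesicles),
               radius_range_um = as.numeric(radius_range_um),
               ring_sigma_um = ring_sigma_um,
               membrane_peak_intensity = membrane_peak_intensity,
               reporter_enriched_fraction = reporter_enriched_fraction,
               reporter_lognormal_mu = reporter_lognormal_mu,
               reporter_lognormal_sigma = reporter_lognormal_sigma,
               reporter_background_intensity = reporter_background_intensity,
               psf_sigma_um = psf_sigma_um,
               read_noise_sigma = read_noise_sigma,
               shot_noise = isTRUE(shot_noise), seed = as.integer(seed))
  validate_image_spec(spec)
  class(spec) <- "image_spec"
  spec
}

validate_image_spec <- function(s) {
  .assert(s$height_px >= 1 && s$width_px >= 1, "image size must be positive")
  .assert(.is_num1(s$pixel_size_um) && s$pixel_size_um > 0,
          "pixel_size_um must be positive")
  .assert(s$n_vesicles >= 0, "n_vesicles must be >= 0")
  .assert(length(s$radius_range_um) == 2 && all(s$radius_range_um > 0) &&
            s$radius_range_um[1] <= s$radius_range_um[2],
          "radius_range_um must be (min, max) with 0 < min <= max")
  .assert(s$ring_sigma_um > 0, "ring_sigma_um must be positive")
  .assert(s$radius_range_um[1] >= 2 * s$ring_sigma_um,
          "minimum radius must be at least 2x ring_sigma_um")
  .assert(s$membrane_peak_intensity > 0, "membrane_peak_intensity must be positive")
  .assert(s$reporter_enriched_fraction >= 0 && s$reporter_enriched_fraction <= 1,
          "reporter_enriched_fraction must lie in [0, 1]")
  .assert(s$reporter_background_intensity >= 0,
          "reporter_background_intensity must be >= 0")
  .assert(s$psf_sigma_um >= 0, "psf_sigma_um must be >= 0")
  .assert(s$read_noise_sigma >= 0, "read_noise_sigma must be >= 0")
  invisible(s)
}

#' Render a Gaussian-profile ring into a matrix
#'
#' Adds `amplitude * exp(-(d - radius_px)^2 / (2 sigma_px^2))` to `plane`,
#' where `d` is the distance of each pixel center from `(center_row,
#' center_col)`. Contributions beyond 5 sigma from the ring are dropped.
#'
#' @param plane Numeric matrix to add into.
#' @param center_row,center_col Ring center (pixels, 1-based).
#' @param radius_px Ring radius in pixels.
#' @param sigma_px Radial Gaussian width in pixels.
#' @param amplitude Peak amplitude (a.u.).
#' @return The matrix with the ring added.
#' @export
render_ring <- function(plane, center_row, center_col, radius_px, sigma_px,
                        amplitude) {
  pad <- ceiling(radius_px + 5 * sigma_px)
  r1 <- max(1L, floor(center_row - pad)); r2 <- min(nrow(plane), ceiling(center_row + pad))
  c1 <- max(1L, floor(center_col - pad)); c2 <- min(ncol(plane), ceiling(center_col + pad))
  if (r1 > r2 || c1 > c2) return(plane)
  rows <- matrix(r1:r2, r2 - r1 + 1L, c2 - c1 + 1L)
  cols <- matrix(c1:c2, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
  d <- sqrt((rows - center_row)^2 + (cols - center_col)^2)
  plane[r1:r2, c1:c2] <- plane[r1:r2, c1:c2] +
    amplitude * exp(-(d - radius_px)^2 / (2 * sigma_px^2))
  plane
}

#' Generate a synthetic two-channel vesicle image with ground truth
#'
#' Places non-overlapping vesicles (rejection sampling; centers at least
#' `radius + 3 ring_sigma` from every border, rings pairwise separated by
#' at least `6 ring_sigma`), renders Gaussian-profile rings into a
#' membrane-dye channel and a reporter channel, then optionally applies a
#' Gaussian PSF blur followed by Poisson shot noise and Gaussian read noise.
#' Vesicle centers are snapped to pixel centers. Identical specs (seed
#' included) give identical output.
#'
#' @param spec An [image_spec()].
#' @param max_attempts Rejection-sampling attempts per vesicle before a
#'   placement error is raised.
#' @return A list with elements `membrane` and `reporter` (both
#'   [image_plane()]) and `truth`, a data frame with one row per vesicle:
#'   `id`, `centroid_row_px`, `centroid_col_px`, `radius_um`,
#'   `true_membrane_reporter_intensity` (reporter ring amplitude, a.u.) and
#'   `enriched`.
#' @examples
#' out <- generate_vesicle_image(image_spec(n_vesicles = 3, seed = 7))
#' out$truth
#' @export
generate_vesicle_image <- function(spec, max_attempts = 5000L) {
  validate_image_spec(spec)
  ps <- spec$pixel_size_um
  sig <- spec$ring_sigma_um / ps
  with_preserved_seed(spec$seed, {
    n <- spec$n_vesicles
    rows <- cols <- r_px <- numeric(0)
    if (n > 0) {
      r_um <- stats::runif(n, spec$radius_range_um[1], spec$radius_range_um[2])
      r_px <- r_um / ps
      for (i in seq_len(n)) {
        margin <- r_px[i] + 3 * sig
        lo_r <- 1 + margin; hi_r <- spec$height_px - margin
        lo_c <- 1 + margin; hi_c <- spec$width_px - margin
        .assert(hi_r > lo_r && hi_c > lo_c,
                sprintf("vesicle placement impossible: radius %.1f px plus 3-sigma margin exceeds the image", r_px[i]))
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          cr <- round(stats::runif(1, lo_r, hi_r))
          cc <- round(stats::runif(1, lo_c, hi_c))
          if (i == 1L || all(sqrt((rows - cr)^2 + (cols - cc)^2) >=
                               r_px[seq_len(i - 1L)] + r_px[i] + 6 * sig)) {
            rows <- c(rows, cr); cols <- c(cols, cc)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop(sprintf(paste0("vesicle placement failed after %d attempts: ",
                              "non-overlap constraint (ring separation >= 6 ring_sigma) ",
                              "cannot be satisfied for vesicle %d"),
                       max_attempts, i), call. = FALSE)
      }
      enriched <- stats::runif(n) < spec$reporter_enriched_fraction
      rep_int <- ifelse(enriched,
                        stats::rlnorm(n, spec$reporter_lognormal_mu,
                                      spec$reporter_lognormal_sigma),
                        spec$reporter_background_intensity)
    } else {
      enriched <- logical(0); rep_int <- numeric(0)
      r_um <- numeric(0)
    }

    membrane <- matrix(0, spec$height_px, spec$width_px)
    reporter <- matrix(spec$reporter_background_intensity,
                       spec$height_px, spec$width_px)
    for (i in seq_len(n)) {
      membrane <- render_ring(membrane, rows[i], cols[i], r_px[i], sig,
                              spec$membrane_peak_intensity)
      reporter <- render_ring(reporter, rows[i], cols[i], r_px[i], sig,
                              rep_int[i])
    }

    psf_px <- spec$psf_sigma_um / ps
    if (psf_px > 0) {
      membrane <- gaussian_blur(membrane, psf_px)
      reporter <- gaussian_blur(reporter, psf_px)
    }
    membrane <- .apply_camera_noise(membrane, spec)
    reporter <- .apply_camera_noise(reporter, spec)

    truth <- data.frame(id = seq_len(n),
                        centroid_row_px = rows, centroid_col_px = cols,
                        radius_um = r_px * ps,
                        true_membrane_reporter_intensity = rep_int,
                        enriched = enriched)
    list(membrane = image_plane(membrane, ps),
         reporter = image_plane(reporter, ps),
         truth = truth)
  })
}

.apply_camera_noise <- function(x, spec) {
  if (spec$shot_noise)
    x <- matrix(as.numeric(stats::rpois(length(x), lambda = x)),
                nrow(x), ncol(x))
  if (spec$read_noise_sigma > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, spec$read_noise_sigma),
                    nrow(x), ncol(x))
  pmax(x, 0)
}
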