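#' Fit a four-parameter logistic to a single-liposome kinetic trace
#'
#' Least-squares fit of `I(t) = baseline + amplitude / (1 + exp(-k (t -
#' t0)))` (Levenberg-Marquardt, via \pkg{minpack.lm}) from a deterministic
#' grid of 8 starting points spanning steepness and midpoint, keeping the
#' converged fit with the lowest residual sum of squares. Derived
#' quantities: `max_rate` is the maximum slope of the fitted curve,
#' `amplitude * k / 4`, in a.u. per minute; `plateau_time_h` is the
#' earliest time at which the fitted curve reaches 95% of its amplitude
#' above baseline, `t0 + log(19)/k`, in hours. A trace is a `responder`
#' when the fit converged and its amplitude exceeds 3 times the residual
#' RMS. Non-convergence of every start yields `converged = FALSE` with
#' `NA` parameters, not an error.
#'
#' @param times_min Strictly increasing times (minutes), >= 5 points.
#' @param intensities Intensities (a.u.), same length.
#' @param vesicle_id Optional identifier carried into the result.
#' @return An object of class `sigmoid_fit` with components
#'   `coefficients` (`baseline`, `amplitude`, `k`, `t0`), `max_rate`,
#'   `midpoint_min`, `plateau_time_h`, `residual_rms`, `converged`,
#'   `responder`, and the data. Methods: `print`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' t <- seq(0, 960, by = 30)
#' y <- logistic4(t, 100, 400, 0.02, 180)
#' fit <- fit_sigmoid(t, y)
#' coef(fit); fit$max_rate
#' @export
fit_sigmoid <- function(times_min, intensities, vesicle_id = NA_integer_) {
  t <- as.numeric(times_min); y <- as.numeric(intensities)
  .assert(length(t) == length(y), "times and intensities must have equal length")
  .assert(length(t) >= 5, "need >= 5 time points for fitting")
  .assert(all(diff(t) > 0), "times must be strictly increasing")
  .assert(all(is.finite(t)) && all(is.finite(y)), "values must be finite")

  span <- diff(range(t))
  b0 <- min(y); a0 <- max(0, max(y) - min(y))
  starts <- expand.grid(k = c(2, 8, 20, 60) / span,
                        t0 = stats::quantile(t, c(1 / 3, 2 / 3), names = FALSE))
  dat <- data.frame(t = t, y = y)
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ baseline + amplitude / (1 + exp(-k * (t - t0))),
        data = dat,
        start = list(baseline = b0, amplitude = a0,
                     k = starts$k[i], t0 = starts$t0[i]),
        lower = c(baseline = -Inf, amplitude = 0, k = 1e-8,
                  t0 = min(t) - 2 * span),
        upper = c(baseline = Inf, amplitude = Inf, k = 1e3,
                  t0 = max(t) + 2 * span),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }

  if (is.null(best)) {
    out <- list(coefficients = c(baseline = NA_real_, amplitude = NA_real_,
                                 k = NA_real_, t0 = NA_real_),
                max_rate = NA_real_, midpoint_min = NA_real_,
                plateau_time_h = NA_real_, residual_rms = NA_real_,
                converged = FALSE, responder = FALSE,
                vesicle_id = vesicle_id, times_min = t, intensities = y)
    class(out) <- "sigmoid_fit"
    return(out)
  }

  cf <- stats::coef(best)
  rms <- sqrt(mean(stats::residuals(best)^2))
  out <- list(coefficients = cf,
              max_rate = unname(cf["amplitude"] * cf["k"] / 4),
              midpoint_min = unname(cf["t0"]),
              plateau_time_h = unname((cf["t0"] + log(19) / cf["k"]) / 60),
              residual_rms = rms,
              converged = TRUE,
              responder = unname(cf["amplitude"] > 3 * rms),
              vesicle_id = vesicle_id, times_min = t, intensities = y)
  class(out) <- "sigmoid_fit"
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid_fit> did not converge\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf(paste0("<sigmoid_fit> baseline %.4g, amplitude %.4g a.u., ",
                     "k %.4g /min, t0 %.4g min\n",
                     "  max rate %.4g a.u./min, plateau %.3g h, ",
                     "residual RMS %.3g, responder: %s\n"),
              cf["baseline"], cf["amplitude"], cf["k"], cf["t0"],
              x$max_rate, x$plateau_time_h, x$residual_rms, x$responder))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times_min
  else if (is.list(newdata)) newdata$times_min else as.numeric(newdata)
  cf <- object$coefficients
  logistic4(t, cf["baseline"], cf["amplitude"], cf["k"], cf["t0"])
}

#' @export
fitted.sigmoid_fit <- function(object, ...) predict(object)

#' @export
residuals.sigmoid_fit <- function(object, ...)
  object$intensities - predict(object)

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$times_min, x$intensities, xlab = "time (min)",
                 ylab = "intensity (a.u.)", ...)
  if (x$converged) {
    tt <- seq(min(x$times_min), max(x$times_min), length.out = 200)
    graphics::lines(tt, predict(x, tt))
  }
  invisible(x)
}

#' Fit sigmoid kinetics to a cohort of traces
#'
#' @param traces Long data frame with `vesicle_id`, `time_min`,
#'   `intensity` (as produced by [generate_kinetic_traces()]).
#' @return Data frame with one row per vesicle: the logistic coefficients,
#'   `max_rate_au_per_min`, `midpoint_min`, `plateau_time_h`,
#'   `residual_rms`, `converged`, `responder`.
#' @export
fit_sigmoid_cohort <- function(traces) {
  .assert(all(c("vesicle_id", "time_min", "intensity") %in% names(traces)),
          "traces must have vesicle_id, time_min, intensity")
  out <- lapply(split(traces, traces$vesicle_id), function(tr) {
    f <- fit_sigmoid(tr$time_min, tr$intensity, vesicle_id = tr$vesicle_id[1])
    data.frame(vesicle_id = tr$vesicle_id[1],
               baseline = f$coefficients["baseline"],
               amplitude = f$coefficients["amplitude"],
               k_per_min = f$coefficients["k"],
               midpoint_min = f$midpoint_min,
               max_rate_au_per_min = f$max_rate,
               plateau_time_h = f$plateau_time_h,
               residual_rms = f$residual_rms,
               converged = f$converged, responder = f$responder)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$vesicle_id), ]
  rownames(out) <- NULL
  out
}

#' Apparent-radius change between first and last time point
#'
#' For each vesicle, `delta_r = r(t_last) - r(t_first)` in micrometres,
#' plus a probability-normalised histogram with 0.25-um bins centered on 0
#' (the bin width used for reporting radius-change distributions). Vesicles
#' missing a radius at either endpoint are skipped, with the reason
#' recorded.
#'
#' @param radii Data frame with `vesicle_id`, `time_min` (or any ordered
#'   time column named `time_min`), `apparent_radius_um`.
#' @param bin_width_um Histogram bin width; default 0.25 um.
#' @return A list with `delta_r` (data frame `vesicle_id`, `delta_r_um`),
#'   `histogram` (data frame `bin_center_um`, `mass`, summing to 1), and
#'   `skipped` (data frame `vesicle_id`, `reason`).
#' @export
radius_change <- function(radii, bin_width_um = 0.25) {
  .assert(all(c("vesicle_id", "time_min", "apparent_radius_um") %in%
                names(radii)),
          "radii must have vesicle_id, time_min, apparent_radius_um")
  per <- split(radii, radii$vesicle_id)
  dr <- numeric(0); ids <- c(); skip_id <- c(); skip_reason <- character(0)
  for (v in per) {
    v <- v[order(v$time_min), ]
    r_first <- v$apparent_radius_um[1L]
    r_last <- v$apparent_radius_um[nrow(v)]
    if (is.na(r_first) || is.na(r_last)) {
      skip_id <- c(skip_id, v$vesicle_id[1L])
      skip_reason <- c(skip_reason, "missing radius at an endpoint")
    } else {
      ids <- c(ids, v$vesicle_id[1L])
      dr <- c(dr, r_last - r_first)
    }
  }
  .assert(length(dr) >= 1, "no vesicle has radii at both endpoints")
  half <- bin_width_um / 2
  m <- ceiling((max(abs(dr)) - half) / bin_width_um)
  m <- max(m, 0)
  edges <- seq(-(m + 0.5) * bin_width_um, (m + 0.5) * bin_width_um,
               by = bin_width_um)
  counts <- tabulate(findInterval(dr, edges, all.inside = TRUE),
                     length(edges) - 1L)
  list(delta_r = data.frame(vesicle_id = ids, delta_r_um = dr),
       histogram = data.frame(
         bin_center_um = (edges[-1L] + edges[-length(edges)]) / 2,
         mass = counts / sum(counts)),
       skipped = data.frame(vesicle_id = skip_id, reason = skip_reason))
}

#' Match detections across two time points by mutual nearest centroid
#'
#' Vesicles are immobilized during time-lapse imaging, so the same vesicle
#' is found near the same position in every frame; detections are linked
#' when each is the other's nearest centroid and the shift does not exceed
#' `max_shift_um`.
#'
#' @param det_a,det_b Detection data frames ([detect_lumina()]) from the
#'   same field of view.
#' @param max_shift_um Maximum allowed centroid displacement (um).
#' @param pixel_size_um Pixel size of the images.
#' @return A list with `matches` (data frame `id_a`, `id_b`, `shift_um`),
#'   `unmatched_a`, `unmatched_b` (id vectors).
#' @export
link_timepoints <- function(det_a, det_b, max_shift_um, pixel_size_um) {
  .assert(.is_num1(max_shift_um) && max_shift_um >= 0,
          "max_shift_um must be a non-negative scalar")
  if (nrow(det_a) == 0L || nrow(det_b) == 0L)
    return(list(matches = data.frame(id_a = integer(0), id_b = integer(0),
                                     shift_um = numeric(0)),
                unmatched_a = det_a$id, unmatched_b = det_b$id))
  d <- outer(seq_len(nrow(det_a)), seq_len(nrow(det_b)),
             function(i, j) sqrt((det_a$centroid_row_px[i] - det_b$centroid_row_px[j])^2 +
                                   (det_a$centroid_col_px[i] - det_b$centroid_col_px[j])^2)) *
    pixel_size_um
  nn_ab <- apply(d, 1L, which.min)
  nn_ba <- apply(d, 2L, which.min)
  ia <- which(nn_ba[nn_ab] == seq_len(nrow(det_a)) &
                d[cbind(seq_len(nrow(det_a)), nn_ab)] <= max_shift_um)
  matches <- data.frame(id_a = det_a$id[ia], id_b = det_b$id[nn_ab[ia]],
                        shift_um = d[cbind(ia, nn_ab[ia])])
  list(matches = matches,
       unmatched_a = setdiff(det_a$id, matches$id_a),
       unmatched_b = setdiff(det_b$id, matches$id_b))
}
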