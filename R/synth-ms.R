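#' Specification for synthetic targeted-MS peak tables
#'
#' Emulates a targeted (MRM) lipidomics run: integrated peak counts are
#' linear in analyte concentration, `counts = slope * conc + intercept`,
#' multiplied by lognormal noise with a stated coefficient of variation
#' (unit mean). Every (sample, transition) is injected
#' `injections_per_sample` times, and a calibration dilution series of
#' standards is emitted twice, as a `pre` block and a `post` block,
#' bracketing the samples.
#'
#' @param species Character vector of transition / species identifiers.
#' @param true_concentrations_uM Named list: one numeric vector per sample
#'   (named by species, uM), or a matrix with samples in rows and species
#'   in columns.
#' @param calibration_levels_uM Dilution-series concentrations (>= 2
#'   distinct values).
#' @param calibration_slope_counts_per_uM,calibration_intercept_counts
#'   Calibration line; scalars or named per-species vectors.
#' @param injections_per_sample Replicate injections per (sample,
#'   transition); default 2.
#' @param count_noise_cv Multiplicative noise CV (>= 0).
#' @param seed Integer seed.
#' @return An `ms_spec` list.
#' @seealso [generate_ms_tables()]
#' @export
ms_spec <- function(species,
                    true_concentrations_uM,
                    calibration_levels_uM = c(0.5, 1, 2, 5, 10, 20),
                    calibration_slope_counts_per_uM = 1000,
                    calibration_intercept_counts = 0,
                    injections_per_sample = 2L,
                    count_noise_cv = 0.05, seed = 1L) {
  if (is.matrix(true_concentrations_uM))
    true_concentrations_uM <- lapply(seq_len(nrow(true_concentrations_uM)),
                                     function(i) true_concentrations_uM[i, ])
  true_concentrations_uM <- lapply(true_concentrations_uM, unlist)
  if (is.null(names(true_concentrations_uM)))
    names(true_concentrations_uM) <-
      sprintf("sample_%02d", seq_along(true_concentrations_uM))
  spec <- list(species = as.character(species),
               true_concentrations_uM = true_concentrations_uM,
               calibration_levels_uM = as.numeric(calibration_levels_uM),
               calibration_slope_counts_per_uM = calibration_slope_counts_per_uM,
               calibration_intercept_counts = calibration_intercept_counts,
               injections_per_sample = as.integer(injections_per_sample),
               count_noise_cv = count_noise_cv, seed = as.integer(seed))
  .assert(length(spec$species) >= 1, "at least one species required")
  .assert(length(unique(spec$calibration_levels_uM)) >= 2,
          "calibration needs >= 2 distinct levels")
  .assert(all(spec$calibration_levels_uM >= 0), "calibration levels must be >= 0")
  .assert(all(unlist(spec$true_concentrations_uM) >= 0),
          "concentrations must be >= 0")
  .assert(spec$injections_per_sample >= 1, "injections_per_sample must be >= 1")
  .assert(spec$count_noise_cv >= 0, "count_noise_cv must be >= 0")
  for (s in names(spec$true_concentrations_uM)) {
    v <- spec$true_concentrations_uM[[s]]
    .assert(!is.null(names(v)) && all(names(v) %in% spec$species),
            "per-sample concentrations must be named by species")
  }
  class(spec) <- "ms_spec"
  spec
}

.per_species <- function(x, species) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(species)), species))
  .assert(all(species %in% names(x)), "per-species parameter missing a species")
  stats::setNames(as.numeric(x[species]), species)
}

# lognormal factor with unit mean and given CV
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic calibration and sample peak tables
#'
#' @param spec An [ms_spec()].
#' @return A list of three data frames: `calibration` (columns `sample_id`
#'   = `cal_<level>`, `transition_id`, `injection`, `counts`, `block` in
#'   `pre`/`post`, plus `concentration_uM`), `samples` (same columns,
#'   `block = "sample"`, no concentration), and `truth` (`sample_id`,
#'   `transition_id`, `concentration_uM`).
#' @examples
#' sp <- ms_spec(c("DOPE", "DOPG"),
#'               list(a = c(DOPE = 5, DOPG = 3)), count_noise_cv = 0)
#' generate_ms_tables(sp)$samples
#' @export
generate_ms_tables <- function(spec) {
  .assert(inherits(spec, "ms_spec"), "`spec` must be an ms_spec")
  slope <- .per_species(spec$calibration_slope_counts_per_uM, spec$species)
  icept <- .per_species(spec$calibration_intercept_counts, spec$species)
  with_preserved_seed(spec$seed, {
    cal <- expand.grid(block = c("pre", "post"),
                       concentration_uM = spec$calibration_levels_uM,
                       transition_id = spec$species,
                       injection = seq_len(spec$injections_per_sample),
                       stringsAsFactors = FALSE)
    cal <- cal[order(cal$block, cal$transition_id, cal$concentration_uM,
                     cal$injection), ]
    mu <- slope[cal$transition_id] * cal$concentration_uM + icept[cal$transition_id]
    cal$counts <- pmax(mu * .ln_noise(nrow(cal), spec$count_noise_cv), 0)
    cal$sample_id <- sprintf("cal_%g", cal$concentration_uM)
    cal <- cal[, c("sample_id", "transition_id", "injection", "counts",
                   "block", "concentration_uM")]

    truth <- do.call(rbind, lapply(names(spec$true_concentrations_uM),
      function(s) {
        v <- spec$true_concentrations_uM[[s]]
        data.frame(sample_id = s, transition_id = names(v),
                   concentration_uM = as.numeric(v))
      }))
    smp <- truth[rep(seq_len(nrow(truth)),
                     each = spec$injections_per_sample), ]
    smp$injection <- rep(seq_len(spec$injections_per_sample), nrow(truth))
    mu <- slope[smp$transition_id] * smp$concentration_uM +
      icept[smp$transition_id]
    smp$counts <- pmax(mu * .ln_noise(nrow(smp), spec$count_noise_cv), 0)
    smp$block <- "sample"
    smp <- smp[, c("sample_id", "transition_id", "injection", "counts", "block")]
    rownames(smp) <- rownames(cal) <- rownames(truth) <- NULL
    list(calibration = cal, samples = smp, truth = truth)
  })
}
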