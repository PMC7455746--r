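#' Built-in lipid species metadata
#'
#' Species of the reconstituted E. coli phospholipid synthesis (Kennedy)
#' pathway and its products, with acyl-chain composition and the number of
#' glycerol-3-phosphate-derived moieties per molecule. G3P enters a
#' phospholipid once through the acylation backbone; PG-class species
#' (PG and its phosphorylated precursor PGP) carry a second G3P-derived
#' glycerol in the headgroup, so heavy-labelled G3P shifts their mass
#' twice as much.
#'
#' @return Data frame with columns `id`, `headgroup_class`, `chain1`,
#'   `chain2` (`"16:0"`, `"18:1"` or `"none"`), `n_acyl_chains`,
#'   `n_g3p_moieties`, `is_end_product`.
#' @export
lipid_species <- function() {
  sp <- rbind(
    c("DOPE",    "PE",      "18:1", "18:1", 2L, 1L, TRUE),
    c("POPE",    "PE",      "16:0", "18:1", 2L, 1L, TRUE),
    c("DPPE",    "PE",      "16:0", "16:0", 2L, 1L, TRUE),
    c("DOPG",    "PG",      "18:1", "18:1", 2L, 2L, TRUE),
    c("POPG",    "PG",      "16:0", "18:1", 2L, 2L, TRUE),
    c("DPPG",    "PG",      "16:0", "16:0", 2L, 2L, TRUE),
    c("DOPS",    "PS",      "18:1", "18:1", 2L, 1L, TRUE),
    c("DOPA",    "PA",      "18:1", "18:1", 2L, 1L, FALSE),
    c("POPA",    "PA",      "16:0", "18:1", 2L, 1L, FALSE),
    c("DPPA",    "PA",      "16:0", "16:0", 2L, 1L, FALSE),
    c("LPA",     "LPA",     "16:0", "none", 1L, 1L, FALSE),
    c("CDP-DAG", "CDP-DAG", "18:1", "18:1", 2L, 1L, FALSE),
    c("PGP",     "PGP",     "18:1", "18:1", 2L, 2L, FALSE))
  data.frame(id = sp[, 1], headgroup_class = sp[, 2], chain1 = sp[, 3],
             chain2 = sp[, 4], n_acyl_chains = as.integer(sp[, 5]),
             n_g3p_moieties = as.integer(sp[, 6]),
             is_end_product = as.logical(sp[, 7]))
}

#' Average replicate injections of a peak table
#'
#' Arithmetic mean of integrated counts over the replicate injections of
#' each (sample, transition, block) group, recording how many injections
#' contributed; single injections pass through flagged `n_injections = 1`.
#'
#' @param table Peak table: data frame with `sample_id`, `transition_id`,
#'   `injection`, `counts` and optionally `block`.
#' @return Data frame with one row per group and columns `sample_id`,
#'   `transition_id`, `block` (if present), `counts`, `n_injections`.
#' @examples
#' tab <- data.frame(sample_id = "a", transition_id = "DOPE",
#'                   injection = 1:2, counts = c(1000, 1200))
#' average_injections(tab)
#' @export
average_injections <- function(table) {
  .assert(is.data.frame(table) &&
            all(c("sample_id", "transition_id", "counts") %in% names(table)),
          "peak table must have sample_id, transition_id, counts")
  .assert(all(is.finite(table$counts)) && all(table$counts >= 0),
          "counts must be finite and >= 0")
  keys <- c("sample_id", "transition_id",
            if ("block" %in% names(table)) "block")
  grp <- interaction(table[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(table)), grp)
  out <- do.call(rbind, lapply(idx, function(i) {
    row <- table[i[1L], keys, drop = FALSE]
    row$counts <- mean(table$counts[i])
    row$n_injections <- length(i)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of integrated counts on standard concentration,
#' pooling the pre- and post-acquisition dilution-series blocks into one
#' fit. The intercept is retained (the calibration is linear, not forced
#' through the origin).
#'
#' @param concentration_uM Standard concentrations (>= 2 distinct values).
#' @param counts Integrated counts at those concentrations.
#' @param species_id Optional species identifier stored in the fit.
#' @return An object of class `calibration_fit`: `species_id`, `slope`
#'   (counts/uM), `intercept` (counts), `r_squared`, `levels` (distinct
#'   concentrations used). Methods: `print`, `coef`, `predict`.
#' @examples
#' fit <- fit_calibration(c(1, 2, 5, 10), 1000 * c(1, 2, 5, 10))
#' coef(fit)
#' @export
fit_calibration <- function(concentration_uM, counts, species_id = NA_character_) {
  x <- as.numeric(concentration_uM); y <- as.numeric(counts)
  .assert(length(x) == length(y), "concentration and counts must have equal length")
  .assert(length(unique(x)) >= 2,
          "calibration error: need >= 2 distinct concentration levels")
  .assert(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(species_id = species_id,
                 slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 r_squared = r2, levels = sort(unique(x))),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %s: counts = %.6g * conc + %.6g (R^2 = %.6g, %d levels)\n",
              x$species_id, x$slope, x$intercept, x$r_squared,
              length(x$levels)))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.calibration_fit <- function(object, newdata, ...) {
  conc <- if (is.list(newdata)) newdata$concentration_uM else as.numeric(newdata)
  object$slope * conc + object$intercept
}

#' Convert integrated counts to concentration
#'
#' Inverts the calibration line: `(counts - intercept) / slope`. Negative
#' back-calculated concentrations (sub-blank signals at trace level) are
#' clamped to 0; the returned vector carries a logical `clamped`
#' attribute marking them.
#'
#' @param counts Integrated counts (averaged over injections).
#' @param fit A [fit_calibration()] result with positive slope.
#' @return Concentrations in uM, with attribute `clamped`.
#' @export
counts_to_concentration <- function(counts, fit) {
  .assert(inherits(fit, "calibration_fit"), "`fit` must be a calibration_fit")
  .assert(is.finite(fit$slope) && fit$slope > 0,
          "invalid calibration: slope must be positive")
  conc <- (as.numeric(counts) - fit$intercept) / fit$slope
  clamped <- conc < 0
  conc[clamped] <- 0
  attr(conc, "clamped") <- clamped
  conc
}

#' Normalize peptide counts to a reference peptide
#'
#' Ratio of a peptide's counts to the counts of a constitutive reference
#' peptide from the same run (expression-level normalization, e.g. to an
#' EF-Tu peptide).
#'
#' @param peptide_counts Counts of the peptide(s) of interest.
#' @param reference_counts Positive counts of the reference peptide
#'   (scalar or same length).
#' @return `peptide_counts / reference_counts`.
#' @export
normalize_to_reference_peptide <- function(peptide_counts, reference_counts) {
  .assert(is.numeric(reference_counts) && length(reference_counts) >= 1 &&
            all(is.finite(reference_counts)) && all(reference_counts > 0),
          "normalization error: reference counts must be positive")
  as.numeric(peptide_counts) / as.numeric(reference_counts)
}

#' Heavy-isotope mass shift of a labelled lipid
#'
#' Mass shift of a de novo synthesized lipid built from uniformly
#' 13C-labelled (three-carbon) glycerol-3-phosphate, relative to the
#' unlabelled species: `n_g3p_moieties * heavy_atoms_per_moiety` heavy
#' carbons. In `"nominal"` mode each heavy carbon adds 1 Da (the shift as
#' conventionally quoted: +3 Da for single-G3P lipids such as PE or PS,
#' +6 Da for PG); `"exact"` mode uses the 13C-12C mass difference.
#'
#' @param species_id Species identifier present in `species`.
#' @param heavy_atoms_per_moiety Heavy atoms per labelled G3P (3 for
#'   uniformly 13C-labelled glycerol).
#' @param mode `"nominal"` (default) or `"exact"`.
#' @param mass_increment_per_atom Da per heavy atom in exact mode
#'   (13C-12C difference, 1.003355 Da).
#' @param species Species metadata, default [lipid_species()].
#' @return Mass shift in Da.
#' @examples
#' isotope_mass_shift("DOPE")  # 3
#' isotope_mass_shift("DOPG")  # 6
#' @export
isotope_mass_shift <- function(species_id, heavy_atoms_per_moiety = 3L,
                               mode = c("nominal", "exact"),
                               mass_increment_per_atom = 1.003355,
                               species = lipid_species()) {
  mode <- match.arg(mode)
  .assert(.is_count(heavy_atoms_per_moiety) && heavy_atoms_per_moiety >= 0,
          "heavy_atoms_per_moiety must be a non-negative integer")
  i <- match(species_id, species$id)
  .assert(!anyNA(i), sprintf("unknown species: %s",
                             paste(species_id[is.na(i)], collapse = ", ")))
  n_heavy <- species$n_g3p_moieties[i] * heavy_atoms_per_moiety
  if (mode == "nominal") n_heavy * 1 else n_heavy * mass_increment_per_atom
}

#' Acyl-chain composition fractions and the random-incorporation null
#'
#' Classifies each end-product species by its chain pair — DP
#' (dipalmitoyl, 16:0/16:0), DO (dioleoyl, 18:1/18:1) or PO (mixed,
#' 16:0/18:1) — and reports the percentage of the total end-product
#' concentration in each class, together with the null expectation if the
#' two chains were drawn independently from the precursor pool: with a
#' 16:0 precursor fraction `p`, `DP = 100 p^2`, `DO = 100 (1-p)^2`,
#' `PO = 100 * 2 p (1-p)` (50% mixed at equimolar precursors).
#'
#' @param concentrations_uM Named numeric vector (names = species ids),
#'   not all zero.
#' @param p_palmitoyl Fraction of 16:0 in the acyl-CoA precursor pool.
#' @param species Species metadata, default [lipid_species()].
#' @return A list with `observed_percent` and `null_percent`, each a named
#'   vector `c(DP, PO, DO)` summing to 100.
#' @examples
#' chain_composition_fractions(c(POPE = 8, DOPE = 1, DPPE = 1))
#' @export
chain_composition_fractions <- function(concentrations_uM, p_palmitoyl = 0.5,
                                        species = lipid_species()) {
  conc <- concentrations_uM
  .assert(!is.null(names(conc)), "concentrations must be named by species")
  .assert(all(is.finite(conc)) && all(conc >= 0), "concentrations must be >= 0")
  .assert(sum(conc) > 0, "total end-product concentration is zero")
  .assert(.is_num1(p_palmitoyl) && p_palmitoyl >= 0 && p_palmitoyl <= 1,
          "p_palmitoyl must lie in [0, 1]")
  i <- match(names(conc), species$id)
  .assert(!anyNA(i), sprintf("unknown species: %s",
                             paste(names(conc)[is.na(i)], collapse = ", ")))
  chains <- cbind(species$chain1[i], species$chain2[i])
  .assert(all(chains != "none"), "chain composition needs diacyl species")
  class_of <- ifelse(chains[, 1] == chains[, 2],
                     ifelse(chains[, 1] == "16:0", "DP", "DO"), "PO")
  tot <- sum(conc)
  obs <- vapply(c(DP = "DP", PO = "PO", DO = "DO"),
                function(cl) 100 * sum(conc[class_of == cl]) / tot,
                numeric(1))
  list(observed_percent = obs,
       null_percent = random_chain_null(p_palmitoyl))
}

#' @rdname chain_composition_fractions
#' @export
random_chain_null <- function(p_palmitoyl = 0.5) {
  p <- p_palmitoyl
  c(DP = 100 * p^2, PO = 100 * 2 * p * (1 - p), DO = 100 * (1 - p)^2)
}

#' Acyl-CoA conversion yield
#'
#' Percentage of the supplied acyl-CoA precursor incorporated into
#' phospholipid products, counting the acyl chains each product consumes:
#' `100 * sum(conc_i * n_acyl_chains_i) / precursor_acyl_coa_uM`. A
#' diacyl end-product pool of 20 uM from 100 uM acyl-CoA is a 40% yield.
#'
#' @param concentrations_uM Named numeric vector of product
#'   concentrations (names = species ids).
#' @param precursor_acyl_coa_uM Total acyl-CoA supplied (> 0, uM).
#' @param species Species metadata, default [lipid_species()].
#' @return Yield in percent.
#' @examples
#' conversion_yield(c(DOPE = 12, DOPG = 8), 100)  # 40
#' @export
conversion_yield <- function(concentrations_uM, precursor_acyl_coa_uM,
                             species = lipid_species()) {
  conc <- concentrations_uM
  .assert(!is.null(names(conc)), "concentrations must be named by species")
  .assert(all(is.finite(conc)) && all(conc >= 0), "concentrations must be >= 0")
  .assert(.is_num1(precursor_acyl_coa_uM) && precursor_acyl_coa_uM > 0,
          "precursor concentration must be positive")
  i <- match(names(conc), species$id)
  .assert(!anyNA(i), sprintf("unknown species: %s",
                             paste(names(conc)[is.na(i)], collapse = ", ")))
  100 * sum(conc * species$n_acyl_chains[i]) / precursor_acyl_coa_uM
}

#' Quantify an MS run end to end
#'
#' Convenience wrapper: averages injections, fits one pooled (pre + post)
#' calibration per transition, and back-calculates sample concentrations.
#'
#' @param calibration Calibration peak table with `concentration_uM`
#'   column (as generated by [generate_ms_tables()]).
#' @param samples Sample peak table.
#' @return A list with `fits` (named list of [fit_calibration()] objects)
#'   and `concentrations` (data frame `sample_id`, `transition_id`,
#'   `concentration_uM`, `clamped`).
#' @export
quantify_ms_run <- function(calibration, samples) {
  .assert("concentration_uM" %in% names(calibration),
          "calibration table must carry concentration_uM")
  cal_avg <- average_injections(calibration[, c("sample_id", "transition_id",
                                                "injection", "counts", "block")])
  conc_key <- unique(calibration[, c("sample_id", "transition_id",
                                     "concentration_uM")])
  cal_avg <- merge(cal_avg, conc_key, by = c("sample_id", "transition_id"),
                   sort = FALSE)
  fits <- lapply(split(cal_avg, cal_avg$transition_id), function(d)
    fit_calibration(d$concentration_uM, d$counts,
                    species_id = d$transition_id[1L]))
  smp_avg <- average_injections(samples)
  conc <- vapply(seq_len(nrow(smp_avg)), function(r) {
    f <- fits[[smp_avg$transition_id[r]]]
    .assert(!is.null(f), sprintf("no calibration for transition %s",
                                 smp_avg$transition_id[r]))
    counts_to_concentration(smp_avg$counts[r], f)
  }, numeric(1))
  out <- data.frame(sample_id = smp_avg$sample_id,
                    transition_id = smp_avg$transition_id,
                    concentration_uM = as.numeric(conc),
                    clamped = conc == 0 & smp_avg$counts <
                      vapply(smp_avg$transition_id,
                             function(s) fits[[s]]$intercept, numeric(1)))
  list(fits = fits, concentrations = out)
}
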