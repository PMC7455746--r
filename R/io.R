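# File IO: 16-bit multi-page TIFF for images, CSV with fixed schemas for
# tables. Pixel size travels in a JSON sidecar (<image>.json) because the
# TIFF writer used here does not persist resolution tags.

.schemas <- list(
  ground_truth = c("id", "centroid_row_px", "centroid_col_px", "radius_um",
                   "true_membrane_reporter_intensity", "enriched"),
  detections = c("id", "centroid_row_px", "centroid_col_px", "area_px2",
                 "perimeter_px", "radius_px", "apparent_radius_um",
                 "circularity", "touches_border"),
  membrane_intensity = c("vesicle_id", "mean_membrane_intensity",
                         "n_rays_used"),
  traces = c("vesicle_id", "time_min", "intensity"),
  trace_truth = c("vesicle_id", "responder", "baseline", "amplitude",
                  "k_per_min", "midpoint_min", "max_rate_au_per_min",
                  "plateau_time_h"),
  kinetic_fits = c("vesicle_id", "baseline", "amplitude", "k_per_min",
                   "midpoint_min", "max_rate_au_per_min", "plateau_time_h",
                   "residual_rms", "converged", "responder"),
  peaks = c("sample_id", "transition_id", "injection", "counts", "block"),
  concentrations = c("sample_id", "transition_id", "concentration_uM"),
  species = c("id", "headgroup_class", "chain1", "chain2", "n_acyl_chains",
              "n_g3p_moieties", "is_end_product"))

#' Table schemas used by the pipeline
#'
#' Column names of every CSV artifact the pipeline reads or writes, keyed
#' by schema name.
#' @return Named list of character vectors.
#' @export
table_schemas <- function() .schemas

#' Write / read a multi-page 16-bit TIFF image
#'
#' Planes are stored as pages of one 16-bit unsigned TIFF (page 1 =
#' membrane, page 2 = reporter for two-channel stills; time-lapse stacks
#' append one two-page block per time point). Intensities are rounded to
#' integers on write; values above 65535 error. Pixel size (and plane
#' names) are stored in a JSON sidecar next to the image, so the physical
#' scale survives a round trip through `write_image()`/`read_image()`.
#'
#' @param planes A single [image_plane()]/matrix or a list of them.
#' @param path Output `.tif` path.
#' @param pixel_size_um Pixel size; taken from the first `image_plane` if
#'   omitted.
#' @return `write_image()` returns `path` invisibly; `read_image()` a list
#'   with `planes` (list of [image_plane()]) and `pixel_size_um`.
#' @export
write_image <- function(planes, path, pixel_size_um = NULL) {
  if (!is.list(planes)) planes <- list(planes)
  if (is.null(pixel_size_um)) pixel_size_um <- pixel_size(planes[[1L]])
  .assert(.is_num1(pixel_size_um) && pixel_size_um > 0,
          "pixel_size_um must be a positive scalar")
  pages <- lapply(planes, function(p) {
    v <- round(unclass(p))
    .assert(all(v >= 0) && all(v <= 65535),
            "intensities must lie in [0, 65535] for 16-bit storage")
    v / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = pixel_size_um, n_pages = length(pages),
               page_names = names(planes))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  .assert(file.exists(path), sprintf("image not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("format error reading %s: %s", path,
                                   conditionMessage(e)), call. = FALSE))
  sidecar <- paste0(path, ".json")
  if (is.null(pixel_size_um)) {
    .assert(file.exists(sidecar),
            "pixel size unknown: no sidecar metadata; pass pixel_size_um")
    meta <- jsonlite::read_json(sidecar)
    pixel_size_um <- as.numeric(meta$pixel_size_um)
    if (!is.null(meta$page_names) && length(meta$page_names) == length(pages))
      names(pages) <- unlist(meta$page_names)
  }
  list(planes = lapply(pages, function(p)
    image_plane(matrix(as.numeric(p), nrow(p), ncol(p)), pixel_size_um)),
    pixel_size_um = pixel_size_um)
}

#' Write / read a schema-checked CSV table
#'
#' Plain CSV with a header row. On read and on write the column set is
#' checked against the named schema; a missing column raises a schema
#' error naming it. Extra columns are preserved.
#'
#' @param table Data frame.
#' @param path CSV path.
#' @param schema Schema name, one of `names(table_schemas())`, or `NULL`
#'   to skip checking.
#' @return `write_table()` returns `path` invisibly; `read_table()` the
#'   data frame.
#' @export
write_table <- function(table, path, schema = NULL) {
  if (!is.null(schema)) .check_schema(table, schema, path)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema = NULL) {
  .assert(file.exists(path), sprintf("table not found: %s", path))
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) .check_schema(out, schema, path)
  out
}

.check_schema <- function(table, schema, path) {
  .assert(schema %in% names(.schemas),
          sprintf("unknown schema '%s'", schema))
  missing <- setdiff(.schemas[[schema]], names(table))
  .assert(length(missing) == 0,
          sprintf("schema error in %s: missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  invisible(table)
}
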