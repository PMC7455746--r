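#' Image plane with physical pixel size
#'
#' A single fluorescence channel: a matrix of non-negative intensities
#' (arbitrary units) indexed `[row, col]` with 1-based pixel-center
#' coordinates, carrying the pixel size in micrometres per pixel.
#'
#' @param values Numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um Positive scalar, micrometres per pixel.
#' @return An `image_plane`: the matrix with a `pixel_size_um` attribute.
#' @examples
#' p <- image_plane(matrix(0, 8, 8), pixel_size_um = 0.2)
#' pixel_size(p)
#' @export
image_plane <- function(values, pixel_size_um) {
  .assert(is.matrix(values) && is.numeric(values),
          "`values` must be a numeric matrix")
  .assert(all(is.finite(values)), "image contains non-finite pixels")
  .assert(all(values >= 0), "image contains negative intensities")
  .assert(.is_num1(pixel_size_um) && pixel_size_um > 0,
          "`pixel_size_um` must be a positive scalar")
  structure(values, pixel_size_um = as.numeric(pixel_size_um),
            class = c("image_plane", class(matrix())))
}

#' @rdname image_plane
#' @param x An `image_plane` (or plain matrix, in which case `NULL`).
#' @export
pixel_size <- function(x) attr(x, "pixel_size_um", exact = TRUE)

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), pixel_size(x), min(x), max(x)))
  invisible(x)
}

# Accept either an image_plane or matrix + explicit pixel size; returns
# list(values, pixel_size_um). Internal.
.as_plane <- function(plane, pixel_size_um = NULL) {
  ps <- pixel_size(plane)
  if (is.null(ps)) ps <- pixel_size_um
  .assert(!is.null(ps), "pixel size missing: supply an image_plane or pixel_size_um")
  .assert(all(is.finite(plane)), "image contains non-finite pixels")
  list(values = unclass(plane), pixel_size_um = ps)
}
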