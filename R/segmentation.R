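#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Required when `threshold_method = "fixed"`;
#'   intensity (a.u.) separating membrane signal from background.
#' @param min_area_px Minimum lumen area in pixels.
#' @param circularity_min Circularity cutoff in (0, 1] applied by
#'   [detect_lumina()] via [circularity_filter()]. The stringent default of
#'   0.85 keeps near-spherical vesicles only; it is a configuration choice,
#'   not a measured value.
#' @param border_margin_px Lumina whose bounding box comes within this many
#'   pixels of the image border are discarded (a cut-off vesicle cannot be
#'   an enclosed lumen).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area_px = 50L,
                                circularity_min = 0.85,
                                border_margin_px = 2L) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed")
    .assert(.is_num1(fixed_threshold), "fixed_threshold required when threshold_method = 'fixed'")
  else
    .assert(is.null(fixed_threshold), "fixed_threshold is only meaningful with threshold_method = 'fixed'")
  .assert(.is_count(min_area_px) && min_area_px >= 1, "min_area_px must be a positive integer")
  .assert(.is_num1(circularity_min) && circularity_min > 0 && circularity_min <= 1,
          "circularity_min must lie in (0, 1]")
  .assert(.is_count(border_margin_px) && border_margin_px >= 0,
          "border_margin_px must be a non-negative integer")
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px = as.integer(min_area_px),
                 circularity_min = circularity_min,
                 border_margin_px = as.integer(border_margin_px)),
            class = "segmentation_params")
}

# Vectorised BFS flood fill over a logical mask from a set of seed linear
# indices; connectivity 4 or 8. Returns a logical matrix of reached pixels.
flood_fill_mask <- function(mask, seeds, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  reached <- matrix(FALSE, nr, nc)
  seeds <- seeds[mask[seeds]]
  if (length(seeds) == 0L) return(reached)
  reached[seeds] <- TRUE
  frontier <- seeds
  offs <- if (connectivity == 4L) list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
            c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  while (length(frontier) > 0L) {
    fr <- ((frontier - 1L) %% nr) + 1L
    fc <- ((frontier - 1L) %/% nr) + 1L
    nxt <- integer(0)
    for (o in offs) {
      r <- fr + o[1L]; c <- fc + o[2L]
      ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
      idx <- (c[ok] - 1L) * nr + r[ok]
      idx <- idx[mask[idx] & !reached[idx]]
      if (length(idx)) {
        reached[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  reached
}

# Label connected components of a logical mask (BFS per component).
# Returns an integer matrix, 0 = background, components numbered in scan
# (column-major) order of their first pixel.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  remaining <- mask
  lab <- 0L
  repeat {
    seed <- which(remaining)
    if (length(seed) == 0L) break
    seed <- seed[1L]
    comp <- flood_fill_mask(remaining, seed, connectivity)
    lab <- lab + 1L
    labels[comp] <- lab
    remaining[comp] <- FALSE
  }
  labels
}

# Moore-neighbour boundary tracing of the outer contour of one 8-connected
# region (logical mask), clockwise, with Jacob's stopping criterion.
# Returns an n x 2 matrix of (row, col) boundary pixels in traversal order.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  start_r <- ((idx[1L] - 1L) %% nr) + 1L
  start_c <- ((idx[1L] - 1L) %/% nr) + 1L
  # clockwise: N, NE, E, SE, S, SW, W, NW
  dirs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  on <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  path_r <- start_r; path_c <- start_c
  cur_r <- start_r; cur_c <- start_c
  # column-major scan order makes N and W of the start background pixels,
  # so scanning clockwise from N is a valid initial backtrack
  d <- 1L
  first_dir <- NA_integer_
  moves <- 0L
  max_moves <- 4L * length(idx) + 8L
  repeat {
    found_dir <- 0L
    for (k in 0:7) {
      dd <- ((d + k - 1L) %% 8L) + 1L
      if (on(cur_r + dirs[dd, 1L], cur_c + dirs[dd, 2L])) { found_dir <- dd; break }
    }
    if (found_dir == 0L) break  # isolated pixel
    if (moves > 0L && cur_r == start_r && cur_c == start_c &&
        found_dir == first_dir) break
    if (is.na(first_dir)) first_dir <- found_dir
    cur_r <- cur_r + dirs[found_dir, 1L]
    cur_c <- cur_c + dirs[found_dir, 2L]
    path_r <- c(path_r, cur_r); path_c <- c(path_c, cur_c)
    d <- ((found_dir - 1L + 6L) %% 8L) + 1L  # re-aim scan at the backtrack side
    moves <- moves + 1L
    if (moves > max_moves) break
  }
  cbind(row = path_r, col = path_c)
}

# Chain-code perimeter of one region: sum of step lengths (1 axial, sqrt(2)
# diagonal) along the closed outer boundary through pixel centers.
# Degenerate regions (single pixel / zero-length trace) get the perimeter of
# a unit square.
region_perimeter <- function(mask) {
  if (sum(mask) == 1L) return(4)
  b <- trace_boundary(mask)
  if (nrow(b) >= 2L && all(b[nrow(b), ] == b[1L, ]))
    b <- b[-nrow(b), , drop = FALSE]
  if (nrow(b) < 2L) return(4)
  closed <- rbind(b, b[1L, ])
  steps <- sqrt(rowSums((closed[-1L, , drop = FALSE] -
                           closed[-nrow(closed), , drop = FALSE])^2))
  p <- sum(steps)
  if (p <= 0) 4 else p
}

#' Detect liposome lumina by flood fill of the membrane-dye channel
#'
#' Binarizes the membrane signal (Otsu or fixed threshold), flood-fills the
#' below-threshold background inward from the image border (4-connectivity)
#' and labels the remaining enclosed dark regions (8-connectivity) as
#' candidate lumina: the interior of a closed membrane ring is dark but
#' unreachable from outside. Candidates smaller than `min_area_px`, within
#' `border_margin_px` of the border, nested inside another lumen
#' (multilamellar appearance; the outermost lumen is kept), or below
#' `circularity_min` are discarded.
#'
#' @param membrane An [image_plane()] (or matrix plus `pixel_size_um`) of
#'   the membrane-dye channel.
#' @param params A [segmentation_params()].
#' @param pixel_size_um Pixel size when `membrane` is a bare matrix.
#' @return A data frame of detections sorted by scan order, columns `id`,
#'   `centroid_row_px`, `centroid_col_px`, `area_px2`, `perimeter_px`
#'   (chain-code length through boundary pixel centers), `radius_px`
#'   (equivalent-area radius `sqrt(area/pi)`, used for ray extents),
#'   `apparent_radius_um` (perimeter-based, see [apparent_radius()]),
#'   `circularity` (`4 pi area / perimeter^2`) and `touches_border`. An
#'   all-background image yields zero rows.
#' @examples
#' img <- generate_vesicle_image(image_spec(n_vesicles = 2, psf_sigma_um = 0,
#'                                          read_noise_sigma = 0,
#'                                          shot_noise = FALSE, seed = 3))
#' detect_lumina(img$membrane, segmentation_params())
#' @export
detect_lumina <- function(membrane, params = segmentation_params(),
                          pixel_size_um = NULL) {
  .assert(inherits(params, "segmentation_params"),
          "`params` must come from segmentation_params()")
  pl <- .as_plane(membrane, pixel_size_um)
  v <- pl$values
  .assert(length(v) > 0, "empty image")
  thr <- switch(params$threshold_method,
                otsu = otsu_threshold(v),
                fixed = params$fixed_threshold)
  below <- v < thr
  nr <- nrow(v); nc <- ncol(v)
  border <- unique(c(seq_len(nr), (nc - 1L) * nr + seq_len(nr),
                     (seq_len(nc) - 1L) * nr + 1L, (seq_len(nc) - 1L) * nr + nr))
  background <- flood_fill_mask(below, border, connectivity = 4L)
  lumen_mask <- below & !background
  labels <- label_components(lumen_mask, connectivity = 8L)
  n_lab <- max(labels)
  if (n_lab == 0L) return(.empty_detections())

  stats_list <- lapply(seq_len(n_lab), function(l) {
    idx <- which(labels == l)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    area <- length(idx)
    comp <- matrix(FALSE, nr, nc); comp[idx] <- TRUE
    per <- region_perimeter(comp)
    list(first_idx = min(idx), area = area, per = per,
         centroid_row = mean(rows), centroid_col = mean(cols),
         bbox = c(min(rows), max(rows), min(cols), max(cols)))
  })

  m <- params$border_margin_px
  keep <- vapply(stats_list, function(s) {
    s$area >= params$min_area_px &&
      s$bbox[1L] > m && s$bbox[3L] > m &&
      s$bbox[2L] <= nr - m && s$bbox[4L] <= nc - m
  }, logical(1))

  # nested lumina (multilamellar appearance): drop any kept region whose
  # bounding box lies strictly inside another kept region's bounding box
  if (sum(keep) > 1L) {
    ki <- which(keep)
    for (i in ki) for (j in ki) {
      if (i == j) next
      bi <- stats_list[[i]]$bbox; bj <- stats_list[[j]]$bbox
      if (bi[1L] > bj[1L] && bi[2L] < bj[2L] &&
          bi[3L] > bj[3L] && bi[4L] < bj[4L]) keep[i] <- FALSE
    }
  }

  stats_list <- stats_list[keep]
  if (length(stats_list) == 0L) return(.empty_detections())
  ord <- order(vapply(stats_list, `[[`, numeric(1), "first_idx"))
  stats_list <- stats_list[ord]
  det <- data.frame(
    id = seq_along(stats_list),
    centroid_row_px = vapply(stats_list, `[[`, numeric(1), "centroid_row"),
    centroid_col_px = vapply(stats_list, `[[`, numeric(1), "centroid_col"),
    area_px2 = vapply(stats_list, `[[`, numeric(1), "area"),
    perimeter_px = vapply(stats_list, `[[`, numeric(1), "per"))
  det$radius_px <- sqrt(det$area_px2 / pi)
  det$apparent_radius_um <- apparent_radius(det$perimeter_px, pl$pixel_size_um)
  det$circularity <- 4 * pi * det$area_px2 / det$perimeter_px^2
  det$touches_border <- FALSE
  circ <- circularity_filter(det, params$circularity_min)
  det <- circ$kept
  det$id <- seq_len(nrow(det))
  rownames(det) <- NULL
  det
}

.empty_detections <- function() {
  data.frame(id = integer(0), centroid_row_px = numeric(0),
             centroid_col_px = numeric(0), area_px2 = numeric(0),
             perimeter_px = numeric(0), radius_px = numeric(0),
             apparent_radius_um = numeric(0), circularity = numeric(0),
             touches_border = logical(0))
}

#' Apparent radius from an outline perimeter
#'
#' `perimeter / (2 pi)` converted to micrometres: the radius the vesicle
#' would have if its outline were a perfect circle. For a non-circular
#' outline this is biased upward (a square lumen of side `s` has perimeter
#' `4 s`, hence apparent radius `2 s / pi` instead of the half-diagonal).
#'
#' @param perimeter_px Positive perimeter(s) in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @return Apparent radius in micrometres.
#' @examples
#' apparent_radius(2 * pi * 10, 1)  # 10 um
#' @export
apparent_radius <- function(perimeter_px, pixel_size_um) {
  .assert(is.numeric(perimeter_px) && all(is.finite(perimeter_px)) &&
            all(perimeter_px > 0), "perimeter must be positive")
  .assert(.is_num1(pixel_size_um) && pixel_size_um > 0,
          "pixel_size_um must be positive")
  perimeter_px / (2 * pi) * pixel_size_um
}

#' Partition detections by a circularity cutoff
#'
#' @param detections Data frame carrying a `circularity` column.
#' @param circularity_min Cutoff; detections with
#'   `circularity >= circularity_min` are kept. Order is preserved in both
#'   partitions.
#' @return A list with `kept` and `discarded` data frames.
#' @export
circularity_filter <- function(detections, circularity_min) {
  .assert(is.data.frame(detections) && "circularity" %in% names(detections),
          "`detections` must carry a circularity column")
  .assert(.is_num1(circularity_min), "circularity_min must be a scalar")
  keep <- detections$circularity >= circularity_min
  list(kept = detections[keep, , drop = FALSE],
       discarded = detections[!keep, , drop = FALSE])
}
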