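#' Protein intensity image
#'
#' A single-channel intensity grid in the same micrometre frame as the
#' cell coordinates. `intensity[i, j]` covers the pixel whose center is
#' `origin + ((i, j) - 0.5) * pixel_size_um` (i indexes x, j indexes y).
#'
#' @param intensity non-negative numeric matrix.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param channel channel name.
#' @param origin length-2 offset of the grid in micrometres.
#' @return object of class `protein_image`.
#' @export
protein_image <- function(intensity, pixel_size_um, channel = "protein",
                          origin = c(0, 0)) {
  if (pixel_size_um <= 0) stop_glom("glomscape_parameter_error", "pixel_size_um must be > 0")
  if (!all(is.finite(intensity))) {
    stop_glom("glomscape_validation_error", "intensity grid must be finite")
  }
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um,
                 channel = channel, origin = origin),
            class = "protein_image")
}

#' @export
print.protein_image <- function(x, ...) {
  cat(sprintf("protein_image '%s': %d x %d pixels at %g um/px, origin (%g, %g)\n",
              x$channel, nrow(x$intensity), ncol(x$intensity), x$pixel_size_um,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Write / read a protein image
#'
#' TIFF (32-bit float) with a JSON sidecar carrying the pixel size, origin
#' and channel name; `<path>.json` next to the image.
#'
#' @param image a `protein_image`.
#' @param path TIFF output (input) path.
#' @return `write_protein_image` the path invisibly; `read_protein_image`
#'   the image.
#' @export
write_protein_image <- function(image, path) {
  m <- image$intensity
  scale <- max(m, 1e-12)
  tiff::writeTIFF(t(m) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um,
                            origin = image$origin, channel = image$channel,
                            scale = scale),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_protein_image
#' @export
read_protein_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  protein_image(t(m) * meta$scale, meta$pixel_size_um, channel = meta$channel,
                origin = meta$origin)
}

#' Sum protein intensity inside cell polygons
#'
#' For each cell polygon, sums the intensities of all pixels whose centers
#' lie inside or on the boundary of the polygon (pixel-center membership;
#' pixels shared by overlapping polygons count for each polygon). An
#' optional affine transform maps polygon coordinates into the image frame
#' when the image was registered externally.
#'
#' @param image a `protein_image`.
#' @param polygons named list (cell id -> two-column vertex matrix).
#' @param affine optional list(`A` = 2x2 matrix, `b` = length-2 shift)
#'   applied to polygon vertices.
#' @return data.frame: cell_id, intensity (pixel sum), n_pixels,
#'   mean_intensity, outside (TRUE when no pixel center fell inside).
#' @export
aggregate_protein <- function(image, polygons, affine = NULL) {
  if (!length(polygons)) {
    return(data.frame(cell_id = character(0), intensity = numeric(0),
                      n_pixels = integer(0), mean_intensity = numeric(0),
                      outside = logical(0)))
  }
  px <- image$pixel_size_um
  cx <- image$origin[1] + (seq_len(nrow(image$intensity)) - 0.5) * px
  cy <- image$origin[2] + (seq_len(ncol(image$intensity)) - 0.5) * px
  out <- data.frame(cell_id = names(polygons), intensity = 0,
                    n_pixels = 0L, mean_intensity = NA_real_, outside = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(polygons)) {
    poly <- polygons[[k]]
    if (!is.null(affine)) {
      poly <- sweep(poly %*% t(affine$A), 2, -affine$b)
    }
    xi <- which(cx >= min(poly[, 1]) - px & cx <= max(poly[, 1]) + px)
    yi <- which(cy >= min(poly[, 2]) - px & cy <= max(poly[, 2]) + px)
    if (!length(xi) || !length(yi)) { out$outside[k] <- TRUE; next }
    gx <- rep(cx[xi], times = length(yi))
    gy <- rep(cy[yi], each = length(xi))
    inside <- points_in_polygon(gx, gy, poly)
    n <- sum(inside)
    if (n == 0) { out$outside[k] <- TRUE; next }
    ix <- rep(xi, times = length(yi))[inside]
    iy <- rep(yi, each = length(xi))[inside]
    s <- sum(image$intensity[cbind(ix, iy)])
    out$intensity[k] <- s
    out$n_pixels[k] <- n
    out$mean_intensity[k] <- s / n
  }
  out
}

#' Protein positivity along the crescent trajectory
#'
#' Flags a cell positive when its mean in-polygon intensity exceeds a
#' threshold (default: Otsu split of the per-cell mean intensities of the
#' target type; alternatively a fixed quantile), computes the positive
#' fraction among target-type cells per ROI, and fits the quadratic trend
#' of the fraction against PC1.
#'
#' @param protein_table output of [aggregate_protein()].
#' @param cell_types per-cell labels aligned to `protein_table` rows.
#' @param target_type type whose positivity is tracked (e.g. `"PEC"`).
#' @param roi_ids per-cell ROI ids (NA outside ROIs).
#' @param pc1_per_roi named vector ROI id -> PC1.
#' @param threshold optional fixed intensity threshold.
#' @param threshold_quantile optional quantile rule instead of Otsu.
#' @return list: `threshold`, `per_cell` (positivity), `per_roi`
#'   (roi, pc1, n, positive_fraction, flag), `trend` (quadratic fit of
#'   fraction on PC1, `NULL` when fewer than 4 ROIs).
#' @export
positivity_along_trajectory <- function(protein_table, cell_types, target_type,
                                        roi_ids, pc1_per_roi, threshold = NULL,
                                        threshold_quantile = NULL) {
  stopifnot(nrow(protein_table) == length(cell_types))
  tgt <- which(cell_types == target_type)
  vals <- protein_table$mean_intensity[tgt]
  vals[is.na(vals)] <- 0
  if (is.null(threshold)) {
    threshold <- if (!is.null(threshold_quantile)) {
      quantile(vals, threshold_quantile, names = FALSE)
    } else if (all(vals == 0)) Inf else otsu_threshold(vals)
  }
  positive <- rep(NA, nrow(protein_table))
  positive[tgt] <- vals > threshold
  rois <- sort(unique(roi_ids[tgt][!is.na(roi_ids[tgt])]))
  per_roi <- do.call(rbind, lapply(rois, function(r) {
    sel <- tgt[which(roi_ids[tgt] == r)]
    data.frame(roi_id = r,
               pc1 = unname(pc1_per_roi[as.character(r)]),
               n = length(sel),
               positive_fraction = mean(positive[sel]),
               flag = if (length(sel)) "ok" else "no_target_cells")
  }))
  trend <- NULL
  if (!is.null(per_roi) && sum(!is.na(per_roi$pc1)) >= 4) {
    ok <- !is.na(per_roi$pc1)
    trend <- trend_along_trajectory(per_roi$positive_fraction[ok],
                                    rep(target_type, sum(ok)), target_type,
                                    per_roi$roi_id[ok],
                                    setNames(per_roi$pc1[ok],
                                             as.character(per_roi$roi_id[ok])))
  }
  list(threshold = threshold, per_cell = positive, per_roi = per_roi,
       trend = trend)
}
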