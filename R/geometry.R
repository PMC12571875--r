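#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting, vectorized over query points, with an explicit
#' on-boundary check so points lying on an edge count as inside.
#'
#' @param px,py query point coordinates.
#' @param poly two-column matrix of polygon vertices (closed implicitly).
#' @param eps boundary tolerance.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # distance from point to segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    ex <- xi + t * dx - px
    ey <- yi + t * dy - py
    on_edge <- on_edge | (ex * ex + ey * ey <= eps * eps)
    j <- i
  }
  inside | on_edge
}

#' Regular-hexagon boundary polygons around cell centroids
#'
#' @param table a `spatial_cell_table`.
#' @param radius_um hexagon circumradius in micrometres.
#' @return named list (by cell id) of 6 x 2 vertex matrices.
#' @export
cell_hexagons <- function(table, radius_um = 4) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ux <- cos(ang) * radius_um
  uy <- sin(ang) * radius_um
  out <- lapply(seq_len(n_cells(table)), function(i) {
    m <- cbind(x_um = table$cells$x_um[i] + ux, y_um = table$cells$y_um[i] + uy)
    m
  })
  names(out) <- table$cells$cell_id
  out
}
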