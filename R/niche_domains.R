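#' Annotate spatial expression domains
#'
#' Per sample: builds a k-nearest-neighbour spatial graph (Euclidean,
#' within slide/sample only), replaces each cell's expression by the mean
#' of itself and its spatial neighbours, reduces the aggregated profiles by
#' PCA, and partitions cells by Leiden community detection on a kNN graph
#' in PC space. Cluster ids are unique across samples.
#'
#' @param table a `spatial_cell_table`.
#' @param normalized optional normalized expression (defaults to
#'   [normalize_log1p()] of the counts at target 1,000).
#' @param k_neighbors spatial neighbours per cell (0 = self only).
#' @param n_pcs principal components kept.
#' @param resolution Leiden modularity resolution.
#' @param seed integer seed (community detection is seeded).
#' @return data.frame `cell_id`, `sample_id`, `domain_cluster`.
#' @export
annotate_spatial_domains <- function(table, normalized = NULL, k_neighbors = 15L,
                                     n_pcs = 20L, resolution = 0.5, seed = 1L) {
  if (is.null(normalized)) normalized <- normalize_log1p(table$counts, 1000)
  out <- data.frame(cell_id = table$cells$cell_id,
                    sample_id = table$cells$sample_id,
                    domain_cluster = NA_integer_, stringsAsFactors = FALSE)
  offset <- 0L
  for (sid in unique(table$cells$sample_id)) {
    idx <- which(table$cells$sample_id == sid)
    n <- length(idx)
    if (n <= k_neighbors) {
      warning(sprintf("sample %s has %d cells (<= k_neighbors); skipped", sid, n))
      next
    }
    x <- table$cells$x_um[idx]; y <- table$cells$y_um[idx]
    feats <- normalized[idx, , drop = FALSE]
    if (k_neighbors > 0) {
      nn <- .knn_brute(x, y, as.integer(k_neighbors))
      adj <- Matrix::sparseMatrix(
        i = c(seq_len(n), rep(seq_len(n), ncol(nn))),
        j = c(seq_len(n), as.integer(nn)),
        x = 1, dims = c(n, n))
      adj <- adj / Matrix::rowSums(adj)
      feats <- adj %*% feats
    }
    feats <- as.matrix(feats)
    ctr <- colMeans(feats)
    fc <- sweep(feats, 2, ctr)
    npc <- min(n_pcs, ncol(fc), n - 1L)
    eg <- eigen(crossprod(fc) / (n - 1), symmetric = TRUE)
    scores <- fc %*% eg$vectors[, seq_len(npc), drop = FALSE]
    kg <- min(15L, n - 1L)   # community graph size, independent of spatial k
    nn_pc <- .knn_brute_nd(scores, as.integer(kg))
    g <- igraph::graph_from_edgelist(
      cbind(rep(seq_len(n), ncol(nn_pc)), as.integer(nn_pc)), directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(derive_seed(seed, 3L))
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10L)
    memb <- igraph::membership(cl)
    out$domain_cluster[idx] <- offset + as.integer(memb)
    offset <- offset + max(memb)
  }
  out
}

#' Select glomerular domain clusters by podocyte-marker score
#'
#' Scores every cell for a podocyte marker set, averages per domain
#' cluster within each sample, and splits cluster scores into two classes
#' with a natural-breaks (exact 1-D Otsu) cut; the upper class is called
#' glomerular when the split explains more than `min_separation` of the
#' score variance. A mean-plus-one-SD rule is available as an alternative.
#'
#' @param table a `spatial_cell_table`.
#' @param domains output of [annotate_spatial_domains()].
#' @param normalized optional normalized expression (target 1,000 default).
#' @param marker_genes podocyte marker genes (intersected with the panel).
#' @param rule `"breaks"` (default) or `"mean_sd"`.
#' @param min_separation minimum goodness-of-variance-fit for `"breaks"`.
#' @param boundary_erosion_um erosion depth applied to the mask boundary:
#'   mask cells within this distance of a non-mask cell are dropped.
#'   Neighbourhood aggregation blurs the domain boundary outward by about
#'   the aggregation radius; eroding by a comparable depth re-centres the
#'   boundary and, being purely geometric, does not bias the cell-type
#'   composition of the retained niche. Set to 0 to disable.
#' @return logical per-cell glomerular mask (aligned to `table`).
#' @export
select_glomerular_clusters <- function(table, domains, normalized = NULL,
                                       marker_genes = c("PODXL", "NPHS2", "PTPRQ"),
                                       rule = c("breaks", "mean_sd"),
                                       min_separation = 0.5,
                                       boundary_erosion_um = 18) {
  rule <- match.arg(rule)
  if (is.null(normalized)) normalized <- normalize_log1p(table$counts, 1000)
  score <- score_gene_set(normalized, marker_genes)$score
  mask <- rep(FALSE, n_cells(table))
  for (sid in unique(table$cells$sample_id)) {
    idx <- which(table$cells$sample_id == sid)
    cl <- domains$domain_cluster[idx]
    if (all(is.na(cl))) next
    ok <- !is.na(cl)
    med <- tapply(score[idx][ok], cl[ok], mean)
    if (length(med) < 2) next
    if (rule == "mean_sd") {
      glom_clusters <- as.integer(names(med)[med > mean(med) + sd(med)])
    } else {
      br <- jenks_breaks(as.numeric(med), 2)
      if (br$gvf < min_separation) next
      glom_clusters <- as.integer(names(med)[br$class == 2])
    }
    mask[idx] <- cl %in% glom_clusters
  }
  if (boundary_erosion_um > 0) mask <- erode_mask(table, mask, boundary_erosion_um)
  mask
}

# geometric erosion: drop mask cells within `depth` of a non-mask cell
erode_mask <- function(table, mask, depth) {
  out <- mask
  for (sid in unique(table$cells$sample_id)) {
    idx <- which(table$cells$sample_id == sid)
    m <- mask[idx]
    if (!any(m) || all(m)) next
    nd <- .nearest_ref_dist(table$cells$x_um[idx][m], table$cells$y_um[idx][m],
                            table$cells$x_um[idx][!m], table$cells$y_um[idx][!m])
    out[idx[m][nd$dist <= depth]] <- FALSE
  }
  out
}

#' Instance individual glomeruli
#'
#' Single-linkage connected components over glomerular-masked cells (edges
#' up to `link_distance_um`, within sample only); components smaller than
#' `min_cells` are discarded (their cells revert to tubulointerstitial).
#' Instance ids are assigned in decreasing component size.
#'
#' @param table a `spatial_cell_table`.
#' @param glomerular_mask logical per-cell mask.
#' @param link_distance_um linkage distance.
#' @param min_cells minimum component size.
#' @return integer per-cell glomerulus id (NA outside glomeruli).
#' @export
instance_glomeruli <- function(table, glomerular_mask, link_distance_um = 30,
                               min_cells = 15L) {
  ids <- rep(NA_integer_, n_cells(table))
  comp_key <- 0L
  raw <- rep(NA_integer_, n_cells(table))
  for (sid in unique(table$cells$sample_id)) {
    idx <- which(table$cells$sample_id == sid & glomerular_mask)
    if (!length(idx)) next
    comp <- .link_components(table$cells$x_um[idx], table$cells$y_um[idx],
                             link_distance_um)
    raw[idx] <- comp_key + comp
    comp_key <- comp_key + max(comp)
  }
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_cells]
  sizes <- sort(sizes[keep], decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  hit <- !is.na(raw) & as.character(raw) %in% keep
  ids[hit] <- as.integer(relabel[as.character(raw[hit])])
  ids
}

#' Assign glomerular / periglomerular / tubulointerstitial compartments
#'
#' Cells carrying a glomerulus instance are glomerular. Every other cell
#' whose distance to the nearest glomerular cell (same sample) is at most
#' `perimeter_um` becomes periglomerular, attached to the glomerulus owning
#' that nearest cell (distance ties resolve to the lower glomerulus id);
#' the rest is tubulointerstitial. ROIs are glomerulus plus its ring.
#'
#' @param table a `spatial_cell_table`.
#' @param glomerulus_ids per-cell instance ids from [instance_glomeruli()].
#' @param perimeter_um ring width (default 100).
#' @return data.frame `cell_id`, `sample_id`, `condition`, `compartment`,
#'   `glomerulus_id`, `roi_id`.
#' @export
assign_compartments <- function(table, glomerulus_ids, perimeter_um = 100) {
  if (perimeter_um <= 0) stop_glom("glomscape_parameter_error", "perimeter_um must be > 0")
  n <- n_cells(table)
  compartment <- rep("tubulointerstitial", n)
  glom_id <- glomerulus_ids
  compartment[!is.na(glomerulus_ids)] <- "glomerular"
  for (sid in unique(table$cells$sample_id)) {
    in_s <- table$cells$sample_id == sid
    ref <- which(in_s & !is.na(glomerulus_ids))
    qry <- which(in_s & is.na(glomerulus_ids))
    if (!length(ref) || !length(qry)) next
    ref <- ref[order(glomerulus_ids[ref])]   # ties go to the lower id
    nd <- .nearest_ref_dist(table$cells$x_um[qry], table$cells$y_um[qry],
                            table$cells$x_um[ref], table$cells$y_um[ref])
    peri <- nd$dist <= perimeter_um
    compartment[qry[peri]] <- "periglomerular"
    glom_id[qry[peri]] <- glomerulus_ids[ref[nd$index[peri]]]
  }
  data.frame(cell_id = table$cells$cell_id, sample_id = table$cells$sample_id,
             condition = table$cells$condition, compartment = compartment,
             glomerulus_id = glom_id,
             roi_id = ifelse(compartment == "tubulointerstitial", NA_integer_, glom_id),
             stringsAsFactors = FALSE)
}

#' Cell-type composition per ROI compartment and per condition
#'
#' Fractions of each cell type among the cells of every (ROI, compartment),
#' plus tubulointerstitial fractions per sample, and condition-level
#' medians across ROIs (samples for tubulointerstitial).
#'
#' @param labeling output of [assign_compartments()].
#' @param cell_types per-cell type labels aligned to the labeling rows.
#' @return list: `per_roi` (long data.frame: unit, compartment, condition,
#'   cell_type, fraction) and `condition_medians`.
#' @export
compartment_composition <- function(labeling, cell_types) {
  stopifnot(length(cell_types) == nrow(labeling))
  dt <- data.table::data.table(
    unit = ifelse(labeling$compartment == "tubulointerstitial",
                  labeling$sample_id, paste0("roi_", labeling$roi_id)),
    compartment = labeling$compartment,
    condition = labeling$condition,
    cell_type = as.character(cell_types))
  counts <- dt[, .N, by = .(unit, compartment, condition, cell_type)]
  totals <- counts[, .(total = sum(N)), by = .(unit, compartment)]
  counts <- merge(counts, totals, by = c("unit", "compartment"))
  # complete missing (unit, type) combinations with zero fractions
  units <- unique(counts[, .(unit, compartment, condition, total)])
  grid <- units[, .(cell_type = unique(dt$cell_type)), by = .(unit, compartment, condition, total)]
  per_roi <- merge(grid, counts[, .(unit, compartment, cell_type, N)],
                   by = c("unit", "compartment", "cell_type"), all.x = TRUE)
  per_roi[is.na(N), N := 0L]
  per_roi[, fraction := N / total]
  cond_med <- per_roi[, .(median_fraction = median(fraction)),
                      by = .(condition, compartment, cell_type)]
  list(per_roi = as.data.frame(per_roi[order(unit, compartment, cell_type)]),
       condition_medians = as.data.frame(cond_med))
}
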