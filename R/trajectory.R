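#' Pseudo-bulk expression per ROI
#'
#' Sums the raw counts of each ROI's member cells (glomerulus plus its
#' periglomerular ring), then normalizes each ROI profile to a total of
#' 10,000 with a log(1+x) transform.
#'
#' @param table a `spatial_cell_table`.
#' @param labeling output of [assign_compartments()].
#' @param target_sum pseudo-bulk normalization total (default 10,000).
#' @return list: `raw` (ROI x gene integer matrix), `normalized`
#'   (same shape, normalized log counts), `roi_info` (roi_id, sample_id,
#'   patient_id, condition, n_cells).
#' @export
pseudobulk_rois <- function(table, labeling, target_sum = 10000) {
  member <- !is.na(labeling$roi_id)
  if (!any(member)) stop_glom("glomscape_parameter_error", "no ROI members in labeling")
  roi <- labeling$roi_id[member]
  idx <- which(member)
  rois <- sort(unique(roi))
  grp <- Matrix::sparseMatrix(i = match(roi, rois), j = seq_along(idx), x = 1,
                              dims = c(length(rois), length(idx)))
  raw <- as.matrix(grp %*% table$counts[idx, , drop = FALSE])
  rownames(raw) <- paste0("roi_", rois)
  empty <- Matrix::rowSums(raw) == 0
  if (any(empty)) {
    warning(sprintf("excluding %d ROI(s) with zero counts", sum(empty)))
    raw <- raw[!empty, , drop = FALSE]
    rois <- rois[!empty]
  }
  first <- match(rois, labeling$roi_id)
  info <- data.frame(roi_id = rois,
                     sample_id = labeling$sample_id[first],
                     condition = labeling$condition[first],
                     n_cells = as.integer(table(roi)[as.character(rois)]),
                     stringsAsFactors = FALSE)
  if (!is.null(table$cells$patient_id)) {
    info$patient_id <- table$cells$patient_id[match(info$sample_id, table$cells$sample_id)]
  }
  norm <- as.matrix(normalize_log1p(raw, target_sum))
  rownames(norm) <- rownames(raw)
  list(raw = raw, normalized = norm, roi_info = info)
}

#' Fit the crescent-formation trajectory (ROI PCA)
#'
#' Centered PCA of normalized ROI pseudo-bulk profiles. The sign of PC1 is
#' fixed so that control ROIs sit at the low end (median PC1 of control
#' ROIs does not exceed the median of the rest), making PC1 the
#' healthy-to-crescentic axis.
#'
#' @param pseudobulk_norm normalized ROI x gene matrix.
#' @param conditions per-ROI condition labels.
#' @param n_pcs components returned.
#' @param control_label label of the control condition.
#' @return list: `scores` (ROI x n_pcs), `pc1`, `loadings`, `sdev`.
#' @export
fit_crescent_trajectory <- function(pseudobulk_norm, conditions, n_pcs = 10L,
                                    control_label = "control") {
  if (nrow(pseudobulk_norm) < 3) stop_glom("glomscape_parameter_error", "need >= 3 ROIs")
  if (length(unique(conditions)) < 2) {
    stop_glom("glomscape_parameter_error", "need >= 2 conditions")
  }
  if (all(apply(pseudobulk_norm, 2, var) < 1e-12)) {
    stop_glom("glomscape_degenerate_error", "pseudo-bulk matrix has no variance")
  }
  n_pcs <- min(n_pcs, nrow(pseudobulk_norm) - 1L, ncol(pseudobulk_norm))
  pc <- prcomp(pseudobulk_norm, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  loadings <- pc$rotation
  ctrl <- conditions == control_label
  if (any(ctrl) && any(!ctrl) &&
      median(scores[ctrl, 1]) > median(scores[!ctrl, 1])) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  list(scores = scores, pc1 = scores[, 1], loadings = loadings, sdev = pc$sdev)
}

#' Cluster ROIs along the trajectory
#'
#' K-means in PC space with the number of clusters chosen by the elbow of
#' the within-cluster sum of squares; clusters in which the control
#' fraction exceeds `merge_control_fraction` are merged into one; final
#' clusters are renamed C1..Cn in order of ascending median PC1.
#'
#' @param pc_scores ROI x PC matrix (column 1 = oriented PC1).
#' @param conditions per-ROI condition labels.
#' @param k_max largest k for the elbow scan.
#' @param merge_control_fraction control-dominance threshold for merging.
#' @param control_label label of the control condition.
#' @param seed integer seed.
#' @return list: `cluster` (factor C1..Cn per ROI), `k_selected`, `wss`.
#' @export
cluster_rois <- function(pc_scores, conditions, k_max = 10L,
                         merge_control_fraction = 0.6,
                         control_label = "control", seed = 1L) {
  pc_scores <- as.matrix(pc_scores)
  if (nrow(pc_scores) < k_max) {
    warning(sprintf("only %d ROIs; lowering k_max", nrow(pc_scores)))
    k_max <- max(3L, nrow(pc_scores) - 1L)
  }
  el <- kmeans_elbow(pc_scores, k_max = k_max, seed = seed)
  memb <- el$fits[[el$k]]$cluster
  ctrl_frac <- tapply(conditions == control_label, memb, mean)
  merge_ids <- as.integer(names(ctrl_frac)[ctrl_frac > merge_control_fraction])
  if (length(merge_ids) > 1) {
    memb[memb %in% merge_ids] <- merge_ids[1]
  }
  med_pc1 <- tapply(pc_scores[, 1], memb, median)
  ord <- names(sort(med_pc1))
  relabel <- setNames(paste0("C", seq_along(ord)), ord)
  cluster <- factor(relabel[as.character(memb)],
                    levels = paste0("C", seq_along(ord)))
  list(cluster = cluster, k_selected = el$k, wss = el$wss)
}

#' Diffusion pseudotime of ROIs
#'
#' Diffusion-map embedding of normalized pseudo-bulk profiles: PCA, a
#' k-nearest-neighbour graph with an adaptive Gaussian kernel (bandwidth =
#' distance to the 7th neighbour), and diffusion-pseudotime distance from a
#' root ROI drawn uniformly from the control ROIs under the seed, rescaled
#' to `[0, 1]`.
#'
#' @param pseudobulk_norm normalized ROI x gene matrix.
#' @param conditions per-ROI condition labels.
#' @param seed integer seed (chooses the control root).
#' @param k_neighbors kNN graph size.
#' @param n_pcs principal components of the embedding space.
#' @param control_label label of the control condition.
#' @return list: `pseudotime` (in `[0,1]`), `root` (row index), `evals`.
#' @export
compute_pseudotime <- function(pseudobulk_norm, conditions, seed = 1L,
                               k_neighbors = 10L, n_pcs = 10L,
                               control_label = "control") {
  ctrl_idx <- which(conditions == control_label)
  if (!length(ctrl_idx)) stop_glom("glomscape_root_error", "no control ROI to root the pseudotime")
  n <- nrow(pseudobulk_norm)
  n_pcs <- min(n_pcs, n - 1L, ncol(pseudobulk_norm))
  pc <- prcomp(pseudobulk_norm, center = TRUE, rank. = n_pcs)
  X <- pc$x
  k <- min(k_neighbors, n - 1L)
  nn <- .knn_brute_nd(X, as.integer(k))
  d2 <- matrix(0, n, k)
  for (m in seq_len(k)) {
    d2[, m] <- rowSums((X - X[nn[, m], , drop = FALSE])^2)
  }
  sigma <- sqrt(d2[, min(7, k)])
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-8)
  i <- rep(seq_len(n), k); j <- as.integer(nn)
  w <- exp(-rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2) /
             (sigma[i] * sigma[j]))
  W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  W <- (W + Matrix::t(W)) / 2
  # connect disconnected components through their closest pair of nodes
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  while (comp$no > 1) {
    a <- which(comp$membership == 1)
    b <- which(comp$membership != 1)
    dd <- outer(a, b, function(p, q) rowSums((X[p, , drop = FALSE] - X[q, , drop = FALSE])^2))
    hit <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    W[a[hit[1]], b[hit[2]]] <- W[b[hit[2]], a[hit[1]]] <- 1e-6
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    comp <- igraph::components(g)
  }
  deg <- Matrix::rowSums(W)
  S <- Matrix::Diagonal(x = 1 / sqrt(deg)) %*% W %*% Matrix::Diagonal(x = 1 / sqrt(deg))
  eg <- eigen(as.matrix((S + Matrix::t(S)) / 2), symmetric = TRUE)
  lam <- pmin(eg$values, 1 - 1e-12)
  psi <- Matrix::Diagonal(x = 1 / sqrt(deg)) %*% eg$vectors
  psi <- as.matrix(psi)
  # Root: a random control ROI. Control tissue can contain occasional
  # inflamed ROIs whose pseudotime would fold the trajectory around a
  # mid-point root, so the draw is restricted to the half of the control
  # ROIs lying toward the control-typical pole of the first informative
  # diffusion component.
  set.seed(derive_seed(seed, 4L))
  if (length(ctrl_idx) > 2 && ncol(psi) >= 2 && any(conditions != control_label)) {
    psi2 <- psi[, 2]
    healthy_high <- median(psi2[ctrl_idx]) > median(psi2[-ctrl_idx])
    med <- median(psi2[ctrl_idx])
    eligible <- if (healthy_high) ctrl_idx[psi2[ctrl_idx] >= med]
      else ctrl_idx[psi2[ctrl_idx] <= med]
    if (!length(eligible)) eligible <- ctrl_idx
  } else {
    eligible <- ctrl_idx
  }
  root <- eligible[sample.int(length(eligible), 1)]
  use <- which(lam < 1 - 1e-9 & lam > -1 + 1e-9)
  use <- setdiff(use, 1L)
  fac <- lam[use] / (1 - lam[use])
  delta <- psi[, use, drop = FALSE] -
    matrix(psi[root, use], n, length(use), byrow = TRUE)
  pt <- sqrt(as.numeric((delta^2) %*% (fac^2)))
  pt <- pt - min(pt)
  if (max(pt) > 0) pt <- pt / max(pt)
  list(pseudotime = pt, root = root, evals = lam)
}

#' Jenks quadrants of a pseudotime vector
#'
#' Four-class natural-breaks classification of pseudotime, labelled Q1..Q4
#' in order of increasing break position.
#'
#' @param pseudotime numeric vector with at least 4 distinct values.
#' @return factor Q1..Q4 per element, with attribute `breaks`.
#' @export
quadrant_breaks <- function(pseudotime) {
  if (length(unique(pseudotime)) < 4) {
    stop_glom("glomscape_degenerate_error", "need >= 4 distinct pseudotime values")
  }
  jb <- jenks_breaks(pseudotime, 4)
  out <- factor(paste0("Q", jb$class), levels = paste0("Q", 1:4))
  attr(out, "breaks") <- jb$breaks
  out
}

#' Correlate patient-level median PC1 with clinical covariates
#'
#' Spearman rank correlation with two-sided p-values from the
#' t-approximation; the ordinal ANCA risk score is encoded low=1,
#' medium=2, high=3.
#'
#' @param median_pc1 named vector (patient_id -> median PC1).
#' @param clinical clinical data.frame with `patient_id` plus covariates
#'   among `egfr`, `albuminuria`, `age`, `anca_risk`.
#' @param min_patients minimum paired observations per covariate.
#' @return data.frame: covariate, n, rho, p, flag.
#' @export
correlate_with_clinical <- function(median_pc1, clinical, min_patients = 5L) {
  enc <- clinical
  if (!is.null(enc$anca_risk)) {
    enc$anca_risk <- c(low = 1, medium = 2, high = 3)[as.character(enc$anca_risk)]
  }
  covs <- intersect(c("egfr", "albuminuria", "age", "anca_risk"), names(enc))
  res <- lapply(covs, function(cv) {
    y <- enc[[cv]][match(names(median_pc1), enc$patient_id)]
    ok <- !is.na(y) & !is.na(median_pc1)
    n <- sum(ok)
    if (n < min_patients) {
      return(data.frame(covariate = cv, n = n, rho = NA_real_, p = NA_real_,
                        flag = "too_few_patients"))
    }
    if (var(y[ok]) == 0 || var(median_pc1[ok]) == 0) {
      return(data.frame(covariate = cv, n = n, rho = NA_real_, p = NA_real_,
                        flag = "constant"))
    }
    rho <- cor(median_pc1[ok], y[ok], method = "spearman")
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * pt(-abs(tstat), n - 2)
    data.frame(covariate = cv, n = n, rho = rho, p = min(p, 1), flag = "ok")
  })
  do.call(rbind, res)
}

#' Differential expression between trajectory clusters
#'
#' Per gene, a linear model of normalized pseudo-bulk expression on a
#' cluster-contrast indicator (baseline cluster vs the rest) with slide
#' indicators as covariates; two-sided t-test p-values for the contrast
#' coefficient and Benjamini-Hochberg adjustment across testable genes.
#' Slides perfectly confounded with the contrast are dropped with a
#' warning. Zero-variance genes are flagged and excluded from the
#' adjustment.
#'
#' @param pseudobulk_norm normalized ROI x gene matrix.
#' @param clusters per-ROI cluster labels.
#' @param slide_ids per-ROI slide ids.
#' @param baseline cluster treated as reference (default "C1").
#' @return data.frame: gene, effect (rest minus baseline), p, q, flag.
#' @export
de_between_clusters <- function(pseudobulk_norm, clusters, slide_ids,
                                baseline = "C1") {
  g <- as.numeric(clusters != baseline)
  if (min(table(g)) < 3) {
    stop_glom("glomscape_parameter_error", "each compared group needs >= 3 ROIs")
  }
  slides <- factor(slide_ids)
  X <- cbind(1, g)
  colnames(X) <- c("(Intercept)", "group")
  if (nlevels(slides) > 1) {
    S <- model.matrix(~slides)[, -1, drop = FALSE]
    Xf <- cbind(X, S)
    if (qr(Xf)$rank < ncol(Xf)) {
      warning("slide covariate confounded with the cluster contrast; dropping slide term")
    } else {
      X <- Xf
    }
  }
  qrX <- qr(X)
  df <- nrow(X) - qrX$rank
  Y <- as.matrix(pseudobulk_norm)
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  rss <- colSums(res^2)
  XtXinv <- chol2inv(qr.R(qrX))
  se2 <- XtXinv[2, 2] * rss / df
  eff <- B[2, ]
  tt <- eff / sqrt(se2)
  p <- 2 * pt(-abs(tt), df)
  flag <- rep("ok", ncol(Y))
  zerovar <- apply(Y, 2, var) < 1e-12
  p[zerovar] <- NA
  eff[zerovar] <- NA
  flag[zerovar] <- "zero_variance"
  q <- rep(NA_real_, ncol(Y))
  q[!zerovar] <- p.adjust(p[!zerovar], method = "BH")
  data.frame(gene = colnames(Y), effect = eff, p = p, q = q, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}
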