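#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, genes; tab separated).
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Gene-set activity score per cell
#'
#' Mean, over the set genes present in the panel, of the gene-wise
#' z-scored (across all cells) normalized expression. Genes with zero
#' variance contribute 0. With a targeted panel of a few hundred genes,
#' expression-matched background pools are too small for bin-matched
#' scoring, so the z-mean is the default; `method = "binned"` subtracts
#' the mean z-score of an expression-matched background bin instead.
#'
#' @param normalized cells x genes normalized expression (sparse or dense).
#' @param gene_set character vector of set genes.
#' @param method `"zmean"` (default) or `"binned"`.
#' @param n_bins background bins for `method = "binned"`.
#' @return list: `score` (per cell), `genes_used`, `fraction_present`.
#' @export
score_gene_set <- function(normalized, gene_set, method = c("zmean", "binned"),
                           n_bins = 10L) {
  method <- match.arg(method)
  present <- intersect(gene_set, colnames(normalized))
  if (!length(present)) {
    stop_glom("glomscape_empty_set_error",
              "no set gene present in the panel (missing: %s)",
              paste(gene_set, collapse = ", "))
  }
  zmat_cols <- function(cols) {
    x <- as.matrix(normalized[, cols, drop = FALSE])
    mu <- colMeans(x)
    sdv <- apply(x, 2, sd)
    z <- sweep(x, 2, mu)
    ok <- sdv > 0
    z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sdv[ok], "/")
    z[, !ok] <- 0
    z
  }
  score <- rowMeans(zmat_cols(present))
  if (method == "binned") {
    means <- Matrix::colMeans(normalized)
    bins <- cut(rank(means, ties.method = "first"), breaks = n_bins, labels = FALSE)
    names(bins) <- colnames(normalized)
    bg <- unlist(lapply(unique(bins[present]), function(b) {
      setdiff(names(bins)[bins == b], present)
    }))
    if (length(bg)) score <- score - rowMeans(zmat_cols(bg))
  }
  list(score = as.numeric(score), genes_used = present,
       fraction_present = length(present) / length(unique(gene_set)))
}

#' Fibrosis score per cell
#'
#' [score_gene_set()] with a default extracellular-matrix gene set
#' (collagens, fibronectin, lumican, TIMP1) intersected with the panel.
#'
#' @param normalized cells x genes normalized expression.
#' @param gene_set override of the default fibrosis set.
#' @return as [score_gene_set()].
#' @export
fibrosis_score <- function(normalized,
                           gene_set = c("COL1A1", "COL4A1", "FN1", "LUM", "TIMP1")) {
  score_gene_set(normalized, gene_set)
}

#' Quadratic trend of a per-cell score along the trajectory
#'
#' Restricts to cells of a target type, attaches each cell its ROI's PC1
#' value, and fits ordinary least squares of score on (1, pc1, pc1^2) with
#' an analytic pointwise 95% confidence band. When the curvature is
#' negative the fitted peak location -b/(2c) is reported.
#'
#' @param scores per-cell scores.
#' @param cell_types per-cell type labels.
#' @param target_type type to restrict to (e.g. `"PEC"`).
#' @param roi_ids per-cell ROI membership (NA outside ROIs).
#' @param pc1_per_roi named vector: ROI id -> PC1.
#' @param grid_n evaluation grid size for the confidence band.
#' @return list: `coefficients` (intercept, linear, quadratic), `peak`
#'   (NA unless curvature < 0), `band` (grid data.frame: pc1, fit, lo, hi),
#'   `n` (cells used).
#' @export
trend_along_trajectory <- function(scores, cell_types, target_type, roi_ids,
                                   pc1_per_roi, grid_n = 50L) {
  sel <- which(cell_types == target_type & !is.na(roi_ids) &
                 as.character(roi_ids) %in% names(pc1_per_roi))
  x <- pc1_per_roi[as.character(roi_ids[sel])]
  y <- scores[sel]
  if (length(y) < 4) stop_glom("glomscape_fit_error", "fewer points than parameters")
  X <- cbind(1, x, x^2)
  fit <- lm.fit(X, y)
  cf <- setNames(fit$coefficients, c("intercept", "linear", "quadratic"))
  df <- length(y) - 3L
  s2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  grid <- seq(min(x), max(x), length.out = grid_n)
  G <- cbind(1, grid, grid^2)
  pred <- as.numeric(G %*% cf)
  se <- sqrt(rowSums((G %*% XtXinv) * G) * s2)
  tq <- qt(0.975, df)
  vcv <- XtXinv * s2
  peak <- if (!is.na(cf[3]) && cf[3] < 0) -cf[2] / (2 * cf[3]) else NA_real_
  list(coefficients = cf,
       se = sqrt(diag(vcv)),
       peak = peak,
       band = data.frame(pc1 = grid, fit = pred, lo = pred - tq * se,
                         hi = pred + tq * se),
       n = length(y))
}
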