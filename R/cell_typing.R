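#' Library-size normalization and log1p transform
#'
#' Scales each cell (row) so its total equals `target_sum`, then applies
#' `log(1 + x)` elementwise. All-zero cells pass through unchanged. The
#' cell-typing workflow uses a target of 1,000 counts; ROI pseudo-bulk
#' profiles use 10,000.
#'
#' @param counts non-negative cells x genes matrix (sparse or dense).
#' @param target_sum per-cell total after scaling.
#' @return sparse normalized matrix of the same shape.
#' @export
normalize_log1p <- function(counts, target_sum = 1000) {
  if (target_sum <= 0) stop_glom("glomscape_parameter_error", "target_sum must be > 0")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                        "CsparseMatrix")
  if (length(counts@x) && any(counts@x < 0)) {
    stop_glom("glomscape_validation_error", "counts must be non-negative")
  }
  tot <- Matrix::rowSums(counts)
  scale <- ifelse(tot > 0, target_sum / tot, 0)
  out <- Matrix::Diagonal(x = scale) %*% counts
  out <- methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Fit a regularized multinomial cell-type classifier
#'
#' Ridge-penalized multinomial logistic regression on log-normalized
#' reference profiles, with the penalty strength chosen by 5-fold
#' cross-validation over a log-spaced grid (1e-2 to 1e2). Deterministic
#' given `seed` (fold assignment is seeded).
#'
#' @param reference_counts cells x genes counts of the labeled reference.
#' @param reference_labels character/factor vector of cell-type labels.
#' @param target_sum normalization target (default 1,000).
#' @param lambda_grid penalty grid, descending.
#' @param seed integer seed.
#' @return a `cell_type_model`: labels, genes, coefficient matrix
#'   (labels x genes + intercept), normalization spec, chosen lambda.
#' @export
fit_classifier <- function(reference_counts, reference_labels, target_sum = 1000,
                           lambda_grid = 10^seq(2, -2, length.out = 9), seed = 1L) {
  y <- as.character(reference_labels)
  tab <- table(y)
  if (length(tab) < 2) stop_glom("glomscape_training_error", "need at least 2 labels")
  if (any(tab < 2)) {
    stop_glom("glomscape_training_error", "label(s) with fewer than 2 cells: %s",
              paste(names(tab)[tab < 2], collapse = ", "))
  }
  x <- normalize_log1p(reference_counts, target_sum)
  set.seed(derive_seed(seed, 2L))
  foldid <- sample(rep(seq_len(5), length.out = nrow(x)))
  fit <- glmnet::cv.glmnet(x, factor(y), family = "multinomial", alpha = 0,
                           lambda = lambda_grid, foldid = foldid,
                           standardize = FALSE)
  cf <- glmnet::coef.glmnet(fit$glmnet.fit, s = fit$lambda.min)
  labels <- sort(unique(y))
  genes <- colnames(reference_counts)
  W <- matrix(0, nrow = length(labels), ncol = length(genes) + 1L,
              dimnames = list(labels, c("(Intercept)", genes)))
  for (lb in labels) W[lb, ] <- as.numeric(cf[[lb]])
  structure(list(labels = labels, genes = genes, coefficients = W,
                 normalization = list(target_sum = target_sum, log1p = TRUE),
                 lambda = fit$lambda.min, seed = seed),
            class = "cell_type_model")
}

#' @export
print.cell_type_model <- function(x, ...) {
  cat(sprintf("cell_type_model: %d labels x %d genes (ridge lambda %.4g, target_sum %g)\n",
              length(x$labels), length(x$genes), x$lambda,
              x$normalization$target_sum))
  invisible(x)
}

#' Serialize / restore a cell-type model as JSON
#' @param model a `cell_type_model`.
#' @param path output (input) file path.
#' @return `write_cell_type_model` the path, invisibly;
#'   `read_cell_type_model` the model.
#' @export
write_cell_type_model <- function(model, path) {
  jsonlite::write_json(list(labels = model$labels, genes = model$genes,
                            coefficients = model$coefficients,
                            normalization = model$normalization,
                            lambda = model$lambda, seed = model$seed),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cell_type_model
#' @export
read_cell_type_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- if (is.matrix(o$coefficients)) o$coefficients
    else matrix(unlist(o$coefficients), nrow = length(o$labels), byrow = TRUE)
  dimnames(W) <- list(o$labels, c("(Intercept)", o$genes))
  structure(list(labels = o$labels, genes = o$genes, coefficients = W,
                 normalization = as.list(o$normalization), lambda = o$lambda,
                 seed = o$seed),
            class = "cell_type_model")
}

#' Predict cell types with a fitted classifier
#'
#' Counts are restricted to the model's genes (missing model genes padded
#' with zeros; at least half the model genes must be present), normalized
#' with the model's spec, and scored; the per-cell argmax label and its
#' softmax probability are returned. Ties break by lexicographic label
#' order.
#'
#' @param model a `cell_type_model`.
#' @param table a `spatial_cell_table` (or a counts matrix with gene
#'   column names).
#' @return data.frame with `cell_id` (if available), `label`, `confidence`,
#'   plus the probability matrix as attribute `probabilities`.
#' @export
predict_cell_types <- function(model, table) {
  counts <- if (inherits(table, "spatial_cell_table")) table$counts else table
  common <- intersect(model$genes, colnames(counts))
  overlap <- length(common) / length(model$genes)
  if (overlap < 0.5) {
    stop_glom("glomscape_compatibility_error",
              "only %.1f%% of model genes present in the data (need >= 50%%)",
              100 * overlap)
  }
  idx <- match(model$genes, colnames(counts))
  if (!anyNA(idx)) {
    x <- counts[, idx, drop = FALSE]
  } else {
    x <- Matrix::Matrix(0, nrow = nrow(counts), ncol = length(model$genes),
                        dimnames = list(rownames(counts), model$genes), sparse = TRUE)
    x[, common] <- counts[, common]
  }
  xn <- normalize_log1p(x, model$normalization$target_sum)
  W <- model$coefficients
  scores <- as.matrix(xn %*% t(W[, -1, drop = FALSE]))
  scores <- sweep(scores, 2, W[, 1], "+")
  scores <- scores - apply(scores, 1, max)
  probs <- exp(scores)
  probs <- probs / rowSums(probs)
  colnames(probs) <- model$labels           # labels are sorted: argmax ties
  lab_idx <- apply(probs, 1, which.max)     # resolve to lexicographic order
  out <- data.frame(label = model$labels[lab_idx],
                    confidence = probs[cbind(seq_len(nrow(probs)), lab_idx)],
                    stringsAsFactors = FALSE)
  if (inherits(table, "spatial_cell_table")) out <- cbind(cell_id = table$cells$cell_id, out)
  attr(out, "probabilities") <- probs
  out
}

#' Remove clusters with low median annotation confidence
#'
#' Drops all cells belonging to clusters whose median prediction confidence
#' is strictly below the threshold (default 0.6).
#'
#' @param confidences per-cell prediction confidences.
#' @param cluster_ids per-cell cluster assignment, aligned to `confidences`.
#' @param min_median_confidence threshold; clusters with median `<` this
#'   value are removed.
#' @return list: `mask` (logical keep vector) and `cluster_medians`.
#' @export
filter_low_confidence_clusters <- function(confidences, cluster_ids,
                                           min_median_confidence = 0.6) {
  if (!length(confidences)) {
    return(list(mask = logical(0), cluster_medians = numeric(0)))
  }
  med <- tapply(confidences, cluster_ids, median)
  keep_cluster <- !(med < min_median_confidence)
  mask <- keep_cluster[as.character(cluster_ids)]
  names(mask) <- NULL
  list(mask = as.logical(mask), cluster_medians = med)
}

#' Relabel fibrotic mesangial cells inside glomeruli
#'
#' Mesangial-labeled cells inside glomerular domains whose fibrosis score
#' exceeds a reference percentile (default: the 90th percentile of control
#' glomerular mesangial cells) are relabeled as fibrotic mesangial. For
#' disease-only data, pass a precomputed `threshold`.
#'
#' @param labels per-cell type labels.
#' @param fibrosis_scores per-cell fibrosis scores ([fibrosis_score()]).
#' @param glomerular per-cell logical: inside a glomerular domain.
#' @param conditions per-cell condition labels (needed unless `threshold`
#'   is given).
#' @param mesangial_label,fibrotic_label labels to match / assign.
#' @param ref_condition condition defining the reference distribution.
#' @param percentile reference percentile (default 0.9).
#' @param threshold optional precomputed score threshold.
#' @return list: `labels` (relabeled), `threshold`, `n_relabeled`.
#' @export
relabel_fibrotic_mesangial <- function(labels, fibrosis_scores, glomerular,
                                       conditions = NULL,
                                       mesangial_label = "MC",
                                       fibrotic_label = "FMC",
                                       ref_condition = "control",
                                       percentile = 0.9, threshold = NULL) {
  if (is.null(threshold)) {
    if (is.null(conditions)) {
      stop_glom("glomscape_parameter_error",
                "need per-cell conditions (or an explicit threshold)")
    }
    ref <- fibrosis_scores[labels == mesangial_label & glomerular &
                             conditions == ref_condition]
    if (!length(ref)) {
      stop_glom("glomscape_parameter_error",
                "no %s-condition mesangial cells to set the fibrosis threshold",
                ref_condition)
    }
    threshold <- quantile(ref, percentile, names = FALSE)
  }
  hit <- labels == mesangial_label & glomerular & fibrosis_scores > threshold
  labels[hit] <- fibrotic_label
  list(labels = labels, threshold = threshold, n_relabeled = sum(hit))
}
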