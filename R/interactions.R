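#' Configuration of the spatial communication model
#'
#' Defaults follow the secreted-signalling analysis settings: a 250-um
#' interaction range, a 10-um contact range, a 0.1 trimmed-mean trim, and
#' a permutation null for significance. The model itself is a documented
#' simplification of diffusion-based interaction tools: a hard range
#' truncation stands in for diffusion weighting, and a Hill response with
#' half-saturation 0.5 (on the log-normalized scale) maps expression
#' summaries into `[0, 1)`.
#'
#' @param interaction_range_um range for secreted signalling.
#' @param contact_range_um range for contact interactions.
#' @param trim trimmed-mean tail fraction (`0 <= trim < 0.5`).
#' @param n_permutations label permutations for significance.
#' @param alpha significance level for aggregated/differential networks.
#' @param min_cells minimum cells per type to score a pair.
#' @param half_saturation Hill half-saturation constant.
#' @param target_sum normalization target for expression summaries.
#' @param seed integer seed.
#' @return list of class `interaction_config`.
#' @export
interaction_config <- function(interaction_range_um = 250, contact_range_um = 10,
                               trim = 0.1, n_permutations = 100L, alpha = 0.05,
                               min_cells = 10L, half_saturation = 0.5,
                               target_sum = 1000, seed = 1L) {
  if (trim < 0 || trim >= 0.5) stop_glom("glomscape_parameter_error", "need 0 <= trim < 0.5")
  if (interaction_range_um <= 0 || contact_range_um <= 0) {
    stop_glom("glomscape_parameter_error", "ranges must be > 0")
  }
  structure(list(interaction_range_um = interaction_range_um,
                 contact_range_um = contact_range_um, trim = trim,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 min_cells = as.integer(min_cells),
                 half_saturation = half_saturation, target_sum = target_sum,
                 seed = seed),
            class = "interaction_config")
}

#' Read a ligand-receptor database table
#'
#' CSV with columns `interaction_id`, `ligand_genes`, `receptor_genes`
#' (multi-gene entries ';'-joined), `pathway`, `category`
#' (secreted/contact).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_lr_database <- function(path) {
  db <- read.csv(path, stringsAsFactors = FALSE)
  assert_cols(db, c("interaction_id", "ligand_genes", "receptor_genes",
                    "pathway", "category"), basename(path))
  if (any(!nzchar(db$ligand_genes)) || any(!nzchar(db$receptor_genes)) ||
      any(!nzchar(db$pathway))) {
    stop_glom("glomscape_validation_error",
              "ligand, receptor and pathway entries must be nonempty")
  }
  if (!all(db$category %in% c("secreted", "contact"))) {
    stop_glom("glomscape_validation_error", "category must be 'secreted' or 'contact'")
  }
  db
}

#' Lay slides out left-to-right with x offsets
#'
#' Adds offsets to the x coordinates of every slide except the first so
#' that cross-slide distances always exceed the interaction range
#' (minimum gap = `gap_factor` times the range); y coordinates and all
#' within-slide distances are unchanged.
#'
#' @param table a `spatial_cell_table`.
#' @param interaction_range_um the interaction range the gap protects.
#' @param gap_factor multiple of the range separating consecutive slides.
#' @return the table with shifted x coordinates.
#' @export
apply_slide_offsets <- function(table, interaction_range_um = 250, gap_factor = 10) {
  if (gap_factor * interaction_range_um <= 0) {
    stop_glom("glomscape_parameter_error", "gap_factor x range must be > 0")
  }
  slides <- unique(table$cells$slide_id)
  offset <- 0
  for (s in slides) {
    idx <- table$cells$slide_id == s
    xs <- table$cells$x_um[idx]
    table$cells$x_um[idx] <- xs - min(xs) + offset
    offset <- offset + (max(xs) - min(xs)) + gap_factor * interaction_range_um
  }
  table
}

#' Trimmed (truncated) mean
#'
#' Sorts the values, drops `floor(trim * n)` from each tail, and averages
#' the remainder.
#'
#' @param values numeric vector (nonempty).
#' @param trim tail fraction in `[0, 0.5)`.
#' @return scalar mean.
#' @export
truncated_mean <- function(values, trim = 0.1) {
  if (!length(values)) stop_glom("glomscape_parameter_error", "empty value vector")
  if (trim < 0 || trim >= 0.5) stop_glom("glomscape_parameter_error", "need 0 <= trim < 0.5")
  v <- sort(values)
  k <- floor(trim * length(v))
  mean(v[(k + 1):(length(v) - k)])
}

hill <- function(u, k) u / (k + u)

# trimmed-mean expression per (gene, type), genes in columns of expr
type_gene_summary <- function(expr, labels, types, trim) {
  out <- matrix(0, length(types), ncol(expr),
                dimnames = list(types, colnames(expr)))
  for (ty in types) {
    rows <- which(labels == ty)
    for (g in seq_len(ncol(expr))) {
      out[ty, g] <- truncated_mean(expr[rows, g], trim)
    }
  }
  out
}

# proximity fraction matrices per range, pooled over slides by pair count
proximity_matrices <- function(x, y, slide, labels, types, ranges) {
  ti <- match(labels, types)
  K <- length(types)
  out <- lapply(ranges, function(r) matrix(0, K, K, dimnames = list(types, types)))
  names(out) <- names(ranges)
  denom <- matrix(0, K, K)
  nums <- lapply(ranges, function(r) matrix(0, K, K))
  for (s in unique(slide)) {
    idx <- which(slide == s)
    cnt <- table(factor(ti[idx], levels = seq_len(K)))
    nvec <- as.numeric(cnt)
    dn <- outer(nvec, nvec)
    diag(dn) <- nvec * (nvec - 1)
    denom <- denom + dn
    for (rn in names(ranges)) {
      nums[[rn]] <- nums[[rn]] +
        .pair_count_matrix(x[idx], y[idx], ti[idx], K, ranges[[rn]])
    }
  }
  for (rn in names(ranges)) {
    pi_m <- nums[[rn]] / denom
    pi_m[denom == 0] <- 0
    dimnames(pi_m) <- list(types, types)
    out[[rn]] <- pi_m
  }
  out
}

geometric_mean <- function(v) exp(mean(log(pmax(v, 0) + 1e-12)))

network_rows <- function(db, summ, pim, types, n_per_type, config) {
  rows <- list()
  for (r in seq_len(nrow(db))) {
    lg <- strsplit(db$ligand_genes[r], ";", fixed = TRUE)[[1]]
    rg <- strsplit(db$receptor_genes[r], ";", fixed = TRUE)[[1]]
    if (!all(c(lg, rg) %in% colnames(summ))) next
    pim_r <- if (db$category[r] == "contact") pim$contact else pim$secreted
    L <- apply(summ[, lg, drop = FALSE], 1, geometric_mean)
    R <- apply(summ[, rg, drop = FALSE], 1, geometric_mean)
    hL <- hill(L, config$half_saturation)
    hR <- hill(R, config$half_saturation)
    prob <- outer(hL, hR) * pim_r
    prob[n_per_type < config$min_cells, ] <- 0
    prob[, n_per_type < config$min_cells] <- 0
    rows[[length(rows) + 1L]] <- data.frame(
      interaction_id = db$interaction_id[r], pathway = db$pathway[r],
      source = rep(types, times = length(types)),
      target = rep(types, each = length(types)),
      prob = as.numeric(prob), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Spatially constrained communication probabilities
#'
#' For every interaction and ordered (source, target) type pair within one
#' condition: the ligand summary is the 0.1-trimmed mean of log-normalized
#' ligand expression over source cells (geometric mean across multi-gene
#' ligands), the receptor summary likewise over target cells, and the
#' spatial proximity is the fraction of (source, target) cell pairs within
#' the category's range (secreted: interaction range; contact: contact
#' range), computed per slide and pooled by cell-pair count. The
#' communication probability is `h(L) * h(R) * pi` with a Hill response
#' `h`; type pairs with fewer than `min_cells` cells score zero.
#' Interactions whose genes are absent from the panel are skipped with a
#' warning.
#'
#' @param table a `spatial_cell_table` (one condition; see
#'   [compute_communication()] for per-condition networks).
#' @param cell_types per-cell type labels.
#' @param lr_db ligand-receptor database ([read_lr_database()]).
#' @param config an [interaction_config()].
#' @return object of class `communication_network`: `edges` data.frame
#'   (interaction, pathway, source, target, prob), `types`, and the
#'   context needed for permutation testing.
#' @export
communication_probability <- function(table, cell_types, lr_db, config = interaction_config()) {
  genes_needed <- unique(unlist(strsplit(
    c(lr_db$ligand_genes, lr_db$receptor_genes), ";", fixed = TRUE)))
  missing <- setdiff(genes_needed, colnames(table$counts))
  if (length(missing)) {
    skip <- vapply(seq_len(nrow(lr_db)), function(r) {
      any(strsplit(paste(lr_db$ligand_genes[r], lr_db$receptor_genes[r], sep = ";"),
                   ";", fixed = TRUE)[[1]] %in% missing)
    }, logical(1))
    warning(sprintf("skipping %d interaction(s) with genes absent from the panel: %s",
                    sum(skip), paste(head(missing, 5), collapse = ", ")))
  }
  types <- sort(unique(as.character(cell_types)))
  norm <- normalize_log1p(table$counts, config$target_sum)
  genes_used <- intersect(genes_needed, colnames(norm))
  expr <- as.matrix(norm[, genes_used, drop = FALSE])
  labels <- as.character(cell_types)
  summ <- type_gene_summary(expr, labels, types, config$trim)
  ranges <- list(secreted = config$interaction_range_um,
                 contact = config$contact_range_um)
  pim <- proximity_matrices(table$cells$x_um, table$cells$y_um,
                            table$cells$slide_id, labels, types, ranges)
  n_per_type <- as.numeric(table(factor(labels, levels = types)))
  names(n_per_type) <- types
  edges <- network_rows(lr_db, summ, pim, types, n_per_type, config)
  structure(list(edges = edges, types = types,
                 context = list(x = table$cells$x_um, y = table$cells$y_um,
                                slide = table$cells$slide_id, labels = labels,
                                expr = expr, lr_db = lr_db,
                                n_per_type = n_per_type)),
            class = "communication_network")
}

#' Per-condition communication networks
#'
#' Applies slide offsets, splits the table by condition and runs
#' [communication_probability()] on each.
#'
#' @inheritParams communication_probability
#' @return named list of `communication_network` objects.
#' @export
compute_communication <- function(table, cell_types, lr_db, config = interaction_config()) {
  table <- apply_slide_offsets(table, config$interaction_range_um)
  out <- list()
  for (cond in unique(table$cells$condition)) {
    idx <- which(table$cells$condition == cond)
    out[[cond]] <- communication_probability(subset_cells(table, idx),
                                             cell_types[idx], lr_db, config)
  }
  out
}

#' Permutation significance of communication probabilities
#'
#' Permutes cell-type labels within each slide, recomputes every
#' interaction probability, and reports add-one permutation p-values
#' `p = (1 + #(perm >= obs)) / (1 + n_permutations)`.
#'
#' @param network a `communication_network`.
#' @param config an [interaction_config()] (`n_permutations >= 20`).
#' @return the network with a `pval` column added to `edges`.
#' @export
permutation_significance <- function(network, config = interaction_config()) {
  if (config$n_permutations < 20) {
    stop_glom("glomscape_parameter_error", "need n_permutations >= 20")
  }
  ctx <- network$context
  types <- network$types
  edges <- network$edges
  if (is.null(edges)) return(network)
  ranges <- list(secreted = config$interaction_range_um,
                 contact = config$contact_range_um)
  exceed <- numeric(nrow(edges))
  set.seed(derive_seed(config$seed, 6L))
  for (b in seq_len(config$n_permutations)) {
    lab <- ctx$labels
    for (s in unique(ctx$slide)) {
      idx <- which(ctx$slide == s)
      lab[idx] <- lab[idx][sample.int(length(idx))]
    }
    summ <- type_gene_summary(ctx$expr, lab, types, config$trim)
    pim <- proximity_matrices(ctx$x, ctx$y, ctx$slide, lab, types, ranges)
    n_per_type <- as.numeric(table(factor(lab, levels = types)))
    names(n_per_type) <- types
    perm_edges <- network_rows(ctx$lr_db, summ, pim, types, n_per_type, config)
    exceed <- exceed + as.numeric(perm_edges$prob >= edges$prob)
  }
  edges$pval <- (1 + exceed) / (1 + config$n_permutations)
  network$edges <- edges
  network
}

#' Aggregate significant communication into type-pair weights
#'
#' @param network a `communication_network` with p-values.
#' @param alpha significance threshold.
#' @return source x target matrix of summed significant probabilities.
#' @export
aggregate_network <- function(network, alpha = 0.05) {
  types <- network$types
  W <- matrix(0, length(types), length(types), dimnames = list(types, types))
  e <- network$edges
  if (is.null(e)) return(W)
  if (is.null(e$pval)) stop_glom("glomscape_parameter_error", "run permutation_significance first")
  sig <- e[e$pval <= alpha, , drop = FALSE]
  if (nrow(sig)) {
    agg <- tapply(sig$prob, list(sig$source, sig$target), sum)
    W[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  }
  W
}

#' Differential interaction network (disease minus control)
#'
#' Elementwise difference of aggregated significant weights; type sets are
#' padded with zero rows/columns so both networks cover the union.
#'
#' @param network_disease,network_control networks with p-values.
#' @param alpha significance threshold.
#' @return signed source x target weight-difference matrix.
#' @export
differential_network <- function(network_disease, network_control, alpha = 0.05) {
  types <- sort(union(network_disease$types, network_control$types))
  pad <- function(W) {
    M <- matrix(0, length(types), length(types), dimnames = list(types, types))
    M[rownames(W), colnames(W)] <- W
    M
  }
  pad(aggregate_network(network_disease, alpha)) -
    pad(aggregate_network(network_control, alpha))
}

#' Incoming signalling toward a target cell type
#'
#' Lists every significant (source, interaction) edge directed at the
#' target type across one or more networks, sorted by probability.
#'
#' @param networks a `communication_network` or named list of them.
#' @param target_type receiving cell type.
#' @param alpha significance threshold.
#' @return data.frame: condition, source, interaction_id, pathway, prob,
#'   pval.
#' @export
incoming_signals <- function(networks, target_type, alpha = 0.05) {
  if (inherits(networks, "communication_network")) networks <- list(all = networks)
  rows <- lapply(names(networks), function(nm) {
    e <- networks[[nm]]$edges
    if (is.null(e) || is.null(e$pval)) return(NULL)
    e <- e[e$target == target_type & e$pval <= alpha & e$prob > 0, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    cbind(condition = nm, e[, c("source", "interaction_id", "pathway", "prob", "pval")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(condition = character(0), source = character(0),
                      interaction_id = character(0), pathway = character(0),
                      prob = numeric(0), pval = numeric(0)))
  }
  out[order(-out$prob), , drop = FALSE]
}
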