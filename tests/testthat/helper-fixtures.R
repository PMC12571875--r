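# Shared fixtures and independent oracles for the test suite.

# small two-condition cohort used by many tests; built once per session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_samples_per_condition = c("control" = 2, "anti-GBM" = 2),
                           glomeruli_per_sample = 3L, field_size_um = 700)
      cache <<- c(generate_cohort(cfg, seed = 42), list(config = cfg))
    }
    cache
  }
})

# full default cohort (the study conditions), built once per session
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config()
      cache <<- c(generate_cohort(cfg, seed = 11), list(config = cfg))
    }
    cache
  }
})

# truth-derived compartment labeling (bypasses the niche pipeline)
truth_labeling <- function(sim) {
  tc <- sim$truth$cells
  data.frame(cell_id = sim$table$cells$cell_id,
             sample_id = sim$table$cells$sample_id,
             condition = sim$table$cells$condition,
             compartment = tc$true_compartment,
             glomerulus_id = tc$true_glomerulus,
             roi_id = tc$true_glomerulus,
             stringsAsFactors = FALSE)
}

# a tiny hand-made table: n cells on a grid, counts over a few genes
toy_table <- function(n = 20, genes = c("PODXL", "CLDN1", "GPX3"),
                      condition = "control", sample_id = "s1", seed = 1) {
  set.seed(seed)
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      x_um = runif(n, 0, 200), y_um = runif(n, 0, 200),
                      slide_id = "sl1", sample_id = sample_id,
                      condition = condition, stringsAsFactors = FALSE)
  counts <- matrix(rpois(n * length(genes), 2), n,
                   dimnames = list(cells$cell_id, genes))
  spatial_cell_table(cells, counts)
}

# adjusted Rand index (independent of any clustering code under test)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# exhaustive optimal 1-D partition into k classes (oracle for Jenks)
jenks_oracle <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ssd <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_class <- NULL
  for (ci in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, ci], n)
    tot <- 0
    cls_sorted <- integer(n)
    for (m in seq_len(k)) {
      seg <- (bounds[m] + 1):bounds[m + 1]
      tot <- tot + ssd(xs[seg])
      cls_sorted[seg] <- m
    }
    if (tot < best - 1e-12) { best <- tot; best_class <- cls_sorted }
  }
  cls <- integer(n)
  cls[order(x)] <- best_class
  list(class = cls, wss = best)
}

# brute-force compartment assignment oracle (all-pairs distances)
compartment_oracle <- function(table, glomerulus_ids, perimeter_um = 100) {
  n <- nrow(table$cells)
  comp <- rep("tubulointerstitial", n)
  gl <- glomerulus_ids
  comp[!is.na(gl)] <- "glomerular"
  for (i in which(is.na(glomerulus_ids))) {
    same <- which(table$cells$sample_id == table$cells$sample_id[i] &
                    !is.na(glomerulus_ids))
    if (!length(same)) next
    d <- sqrt((table$cells$x_um[same] - table$cells$x_um[i])^2 +
                (table$cells$y_um[same] - table$cells$y_um[i])^2)
    dmin <- min(d)
    if (dmin <= perimeter_um) {
      comp[i] <- "periglomerular"
      cand <- same[d == dmin]
      gl[i] <- min(glomerulus_ids[cand])
    }
  }
  list(compartment = comp, glomerulus_id = gl)
}

# brute-force proximity fraction oracle for one (S, T) pair, within slides
proximity_oracle <- function(x, y, slide, labels, s_type, t_type, range) {
  num <- 0; den <- 0
  for (sl in unique(slide)) {
    si <- which(slide == sl & labels == s_type)
    ti <- which(slide == sl & labels == t_type)
    for (i in si) for (j in ti) {
      if (i == j) next
      den <- den + 1
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= range^2) num <- num + 1
    }
  }
  if (den == 0) 0 else num / den
}

# brute-force drug scoring oracle
drug_score_oracle <- function(drug_table, pathway_genes, weights, min_score = 0.1) {
  pathway_genes <- unique(toupper(pathway_genes))
  res <- list()
  for (d in sort(unique(drug_table$drug_id))) {
    rows <- drug_table[drug_table$drug_id == d, ]
    inter <- rows[toupper(rows$target_gene) %in% pathway_genes, ]
    n_ov <- nrow(inter)
    s_b <- n_ov / length(pathway_genes)
    s_a <- 0
    for (a in inter$action) {
      w <- 0
      for (nm in names(weights)) if (grepl(nm, tolower(a), fixed = TRUE)) w <- max(w, weights[[nm]])
      s_a <- s_a + w
    }
    s_f <- s_b * (1 + s_a / max(1, n_ov))
    res[[d]] <- data.frame(drug_id = d, n_overlap = n_ov, s_b = s_b,
                           s_a = s_a, s_f = s_f)
  }
  out <- do.call(rbind, res)
  out <- out[out$s_f >= min_score, , drop = FALSE]
  out[order(-out$s_f, out$drug_id), ]
}

# per-pixel protein aggregation oracle
protein_oracle <- function(image, polygons) {
  px <- image$pixel_size_um
  sums <- numeric(length(polygons))
  for (k in seq_along(polygons)) {
    poly <- polygons[[k]]
    s <- 0
    for (i in seq_len(nrow(image$intensity))) {
      for (j in seq_len(ncol(image$intensity))) {
        cx <- image$origin[1] + (i - 0.5) * px
        cy <- image$origin[2] + (j - 0.5) * px
        if (points_in_polygon(cx, cy, poly)) s <- s + image$intensity[i, j]
      }
    }
    sums[k] <- s
  }
  sums
}
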