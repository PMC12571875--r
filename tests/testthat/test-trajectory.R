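test_that("pseudo-bulk sums raw counts and hits the normalization identity", {
  cells <- data.frame(cell_id = c("a", "b", "c"), x_um = 1:3, y_um = 1:3,
                      slide_id = "sl", sample_id = "s1", condition = "control")
  counts <- rbind(c(1L, 2L), c(3L, 4L), c(5L, 5L))
  colnames(counts) <- c("g1", "g2")
  tab <- spatial_cell_table(cells, counts)
  lab <- data.frame(cell_id = cells$cell_id, sample_id = "s1",
                    condition = "control", compartment = "glomerular",
                    glomerulus_id = c(1, 1, 2), roi_id = c(1, 1, 2))
  pb <- pseudobulk_rois(tab, lab)
  expect_equal(unname(pb$raw["roi_1", ]), c(4, 6))
  expect_equal(sum(pb$raw), sum(counts))          # conservation
  expect_equal(unname(rowSums(expm1(pb$normalized))), c(10000, 10000),
               tolerance = 1e-4)
})

test_that("PC1 is oriented healthy-to-disease and recovers severity", {
  sim <- small_cohort()
  pb <- pseudobulk_rois(sim$table, truth_labeling(sim))
  traj <- fit_crescent_trajectory(pb$normalized, pb$roi_info$condition)
  ctrl <- pb$roi_info$condition == "control"
  expect_lte(median(traj$pc1[ctrl]), median(traj$pc1[!ctrl]))
  sev <- sim$truth$rois$severity[match(pb$roi_info$roi_id,
                                       sim$truth$rois$glomerulus_id)]
  expect_gte(cor(traj$pc1, sev, method = "spearman"), 0.8)
})

test_that("duplicating every ROI leaves PC1 unchanged per original", {
  sim <- small_cohort()
  pb <- pseudobulk_rois(sim$table, truth_labeling(sim))
  n <- nrow(pb$normalized)
  dup <- rbind(pb$normalized, pb$normalized)
  conds <- rep(pb$roi_info$condition, 2)
  t1 <- fit_crescent_trajectory(pb$normalized, pb$roi_info$condition)
  t2 <- fit_crescent_trajectory(dup, conds)
  expect_equal(t2$pc1[1:n], t2$pc1[(n + 1):(2 * n)])
  expect_gt(abs(cor(t1$pc1, t2$pc1[1:n])), 0.999)
  expect_error(fit_crescent_trajectory(matrix(1, 5, 4), rep(c("a", "b"), c(2, 3))),
               class = "glomscape_degenerate_error")
})

test_that("ROI clustering finds blob structure and applies the merge rule", {
  set.seed(12)
  blobs <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 8), 30),
                 matrix(rnorm(60, 16), 30))
  truth <- rep(1:3, each = 30)
  conds <- rep(c("control", "SLE", "anti-GBM"), each = 30)
  cl <- cluster_rois(blobs, conds, k_max = 8, seed = 1)
  expect_equal(cl$k_selected, 3L)
  expect_equal(ari(cl$cluster, truth), 1)
  # cluster names ordered by median PC1 (column 1)
  med <- tapply(blobs[, 1], cl$cluster, median)
  expect_true(all(diff(med[paste0("C", seq_along(med))]) > 0))

  # two control-dominated blobs merge into one cluster
  conds2 <- rep(c("control", "control", "anti-GBM"), each = 30)
  cl2 <- cluster_rois(blobs, conds2, k_max = 8, merge_control_fraction = 0.6,
                      seed = 1)
  expect_equal(length(unique(cl2$cluster)), 2L)
  merged <- cl2$cluster[truth %in% c(1, 2)]
  expect_equal(length(unique(merged)), 1L)
})

test_that("diffusion pseudotime starts at the root and orders a line manifold", {
  set.seed(13)
  n <- 60
  pos <- seq(0, 1, length.out = n)
  emb <- cbind(pos, 0) + matrix(rnorm(2 * n, 0, 0.01), n)
  pbn <- emb %*% matrix(rnorm(2 * 40), 2)
  conds <- rep(c("control", "disease"), c(12, n - 12))
  r <- compute_pseudotime(pbn, conds, seed = 1)
  expect_equal(r$pseudotime[r$root], 0)
  expect_true(all(r$pseudotime >= 0 & r$pseudotime <= 1))
  expect_gte(abs(cor(r$pseudotime, pos, method = "spearman")), 0.95)
  # different control roots give consistent orderings
  r2 <- compute_pseudotime(pbn, conds, seed = 2)
  expect_gte(cor(r$pseudotime, r2$pseudotime, method = "spearman"), 0.9)
  expect_error(compute_pseudotime(pbn, rep("disease", n), seed = 1),
               class = "glomscape_root_error")
})

test_that("Jenks natural breaks equal exhaustive enumeration for n <= 25", {
  # the printed triplet example has its exact optimal split
  x <- c(1, 2, 3, 11, 12, 13, 21, 22, 23, 31, 32, 33)
  jb <- jenks_breaks(x, 4)
  expect_equal(jb$class, rep(1:4, each = 3))
  # random instances vs the oracle
  set.seed(14)
  for (rep_i in 1:8) {
    n <- sample(8:20, 1)
    k <- sample(2:4, 1)
    x <- round(rnorm(n, sd = 10), 2)
    if (length(unique(x)) < k) next
    jb <- jenks_breaks(x, k)
    or <- jenks_oracle(x, k)
    expect_equal(jb$wss, or$wss, tolerance = 1e-9)
    expect_equal(jb$class, or$class)
  }
})

test_that("quadrants are affine-invariant and need 4 distinct values", {
  x <- c(1, 2, 3, 11, 12, 13, 21, 22, 23, 31, 32, 33)
  q1 <- quadrant_breaks(x)
  expect_equal(as.character(q1), rep(paste0("Q", 1:4), each = 3))
  q2 <- quadrant_breaks(3 * x - 7)
  expect_equal(as.character(q1), as.character(q2))
  expect_error(quadrant_breaks(rep(1, 10)), class = "glomscape_degenerate_error")
})

test_that("clinical correlation reproduces known Spearman structure", {
  pc1 <- setNames(c(1, 2, 3, 4, 5, 6), paste0("P", 1:6))
  clin <- data.frame(patient_id = paste0("P", 1:6),
                     egfr = c(60, 50, 40, 30, 20, 10),
                     age = c(1, 2, 3, 4, 5, 6),
                     anca_risk = c("low", "low", "medium", "medium", "high", "high"))
  res <- correlate_with_clinical(pc1, clin)
  expect_equal(res$rho[res$covariate == "age"], 1)
  expect_equal(res$rho[res$covariate == "egfr"], -1)
  expect_gt(res$rho[res$covariate == "anca_risk"], 0.9)
  # symmetry of Spearman rho
  expect_equal(res$rho[res$covariate == "age"],
               correlate_with_clinical(setNames(clin$age, clin$patient_id),
                                       data.frame(patient_id = clin$patient_id,
                                                  age = unname(pc1)))$rho)
  # constant covariate flagged
  clin$egfr <- 50
  expect_equal(correlate_with_clinical(pc1, clin)$flag[1], "constant")
})

test_that("synthetic eGFR decreasing in severity yields a negative correlation", {
  sim <- small_cohort()
  pb <- pseudobulk_rois(sim$table, truth_labeling(sim))
  traj <- fit_crescent_trajectory(pb$normalized, pb$roi_info$condition)
  med <- tapply(traj$pc1, pb$roi_info$patient_id, median)
  res <- correlate_with_clinical(med, sim$truth$clinical, min_patients = 4)
  expect_lt(res$rho[res$covariate == "egfr"], 0)
})

test_that("cluster DE detects a planted effect and flags degenerate genes", {
  set.seed(15)
  n <- 40
  g <- rep(c("C1", "C2"), each = n / 2)
  slides <- rep(c("sl1", "sl2"), n / 2)
  Y <- matrix(rnorm(n * 30), n, dimnames = list(NULL, sprintf("g%02d", 1:30)))
  Y[g != "C1", 1] <- Y[g != "C1", 1] + 2       # planted +2 log-units
  Y[, 2] <- 1                                   # zero variance
  de <- de_between_clusters(Y, g, slides)
  expect_lt(de$q[1], 0.05)
  expect_gt(de$effect[1], 0)
  expect_equal(de$flag[2], "zero_variance")
  expect_true(is.na(de$q[2]))
  # a slide perfectly confounded with the contrast drops the slide term
  expect_warning(de_between_clusters(Y, g, slide_ids = g), "confounded")
  expect_error(de_between_clusters(Y, rep(c("C1", "C2"), c(2, n - 2)), slides),
               class = "glomscape_parameter_error")
})
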