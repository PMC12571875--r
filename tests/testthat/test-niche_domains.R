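# two spatially segregated expression blocks inside one sample
block_sample <- function(n_per_block = 250, seed = 2) {
  set.seed(seed)
  cfg <- cohort_config()
  counts <- rbind(sample_expression("POD", 0.1, cfg, n = n_per_block),
                  sample_expression("PT", 0.1, cfg, n = n_per_block))
  cells <- data.frame(
    cell_id = sprintf("c%04d", seq_len(2 * n_per_block)),
    x_um = c(runif(n_per_block, 0, 200), runif(n_per_block, 400, 600)),
    y_um = runif(2 * n_per_block, 0, 200),
    slide_id = "sl1", sample_id = "s1", condition = "control",
    stringsAsFactors = FALSE)
  list(table = spatial_cell_table(cells, counts),
       block = rep(c(1, 2), each = n_per_block))
}

test_that("spatial domain annotation recovers segregated expression blocks", {
  bs <- block_sample()
  dom <- annotate_spatial_domains(bs$table, resolution = 0.05, seed = 1)
  expect_gte(ari(dom$domain_cluster, bs$block), 0.9)
})

test_that("domain annotation is invariant to cell order up to relabeling", {
  bs <- block_sample(n_per_block = 150)
  dom1 <- annotate_spatial_domains(bs$table, resolution = 0.1, seed = 1)
  set.seed(3)
  perm <- sample(n_cells(bs$table))
  dom2 <- annotate_spatial_domains(subset_cells(bs$table, perm), resolution = 0.1, seed = 1)
  expect_equal(ari(dom1$domain_cluster[perm], dom2$domain_cluster), 1)
})

test_that("k_neighbors = 0 clusters on each cell's own expression", {
  # interleaved types in space: self-only aggregation must split by type,
  # which spatial smoothing would destroy
  set.seed(4)
  cfg <- cohort_config()
  n <- 150
  counts <- rbind(sample_expression("POD", 0.1, cfg, n = n),
                  sample_expression("TC", 0.1, cfg, n = n))
  ord <- sample(2 * n)
  cells <- data.frame(cell_id = sprintf("c%04d", seq_len(2 * n)),
                      x_um = runif(2 * n, 0, 100), y_um = runif(2 * n, 0, 100),
                      slide_id = "sl1", sample_id = "s1", condition = "control")
  tab <- spatial_cell_table(cells[ord, ], counts[ord, ])
  truth <- rep(c(1, 2), each = n)[ord]
  dom <- annotate_spatial_domains(tab, k_neighbors = 0, resolution = 0.05, seed = 1)
  expect_gte(ari(dom$domain_cluster, truth), 0.9)
})

test_that("undersized samples are skipped with a warning", {
  tab <- toy_table(n = 10)
  expect_warning(dom <- annotate_spatial_domains(tab, k_neighbors = 15, seed = 1),
                 "skipped")
  expect_true(all(is.na(dom$domain_cluster)))
})

test_that("glomerulus instancing matches connected-component geometry", {
  # two discs of cells 500 um apart -> two components matching the discs
  set.seed(5)
  n <- 40
  ang <- runif(2 * n, 0, 2 * pi); rad <- 50 * sqrt(runif(2 * n))
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(2 * n)),
    x_um = c(rad[1:n] * cos(ang[1:n]), 500 + rad[(n + 1):(2 * n)] * cos(ang[(n + 1):(2 * n)])),
    y_um = rad * sin(ang),
    slide_id = "sl1", sample_id = "s1", condition = "control")
  counts <- matrix(1L, 2 * n, 2, dimnames = list(cells$cell_id, c("g1", "g2")))
  tab <- spatial_cell_table(cells, counts)
  ids <- instance_glomeruli(tab, rep(TRUE, 2 * n), link_distance_um = 30,
                            min_cells = 5)
  expect_equal(length(unique(ids)), 2L)
  expect_equal(length(unique(ids[1:n])), 1L)
  expect_equal(length(unique(ids[(n + 1):(2 * n)])), 1L)
  expect_true(ids[1] != ids[n + 1])

  # min_cells threshold: a 10-cell disc yields no instance
  ids10 <- instance_glomeruli(subset_cells(tab, 1:10), rep(TRUE, 10),
                              min_cells = 15)
  expect_true(all(is.na(ids10)))

  # infinite link distance joins everything
  ids_inf <- instance_glomeruli(tab, rep(TRUE, 2 * n), link_distance_um = Inf,
                                min_cells = 5)
  expect_equal(length(unique(ids_inf)), 1L)
})

test_that("compartment assignment respects the 100-um perimeter exactly", {
  # one glomerular cell at the origin; probes at 50 / 100 / 150 um
  cells <- data.frame(cell_id = c("g", "p50", "p100", "t150"),
                      x_um = c(0, 50, 100, 150), y_um = 0,
                      slide_id = "sl1", sample_id = "s1", condition = "control")
  counts <- matrix(1L, 4, 1, dimnames = list(cells$cell_id, "g1"))
  tab <- spatial_cell_table(cells, counts)
  lab <- assign_compartments(tab, c(1L, NA, NA, NA), perimeter_um = 100)
  expect_equal(lab$compartment, c("glomerular", "periglomerular",
                                  "periglomerular", "tubulointerstitial"))
  expect_equal(lab$roi_id, c(1L, 1L, 1L, NA))
  expect_error(assign_compartments(tab, c(1L, NA, NA, NA), perimeter_um = 0),
               class = "glomscape_parameter_error")
})

test_that("compartment assignment equals the all-pairs brute-force oracle", {
  tab <- toy_table(n = 200, seed = 6)
  set.seed(7)
  ids <- rep(NA_integer_, 200)
  ids[sample(200, 30)] <- sample(1:3, 30, replace = TRUE)
  lab <- assign_compartments(tab, ids, perimeter_um = 60)
  oracle <- compartment_oracle(tab, ids, perimeter_um = 60)
  expect_equal(lab$compartment, oracle$compartment)
  expect_equal(lab$glomerulus_id, oracle$glomerulus_id)
  # partition: every cell has exactly one compartment
  expect_true(all(lab$compartment %in%
                    c("glomerular", "periglomerular", "tubulointerstitial")))
  # monotonicity: wider perimeter never shrinks the periglomerular set
  lab2 <- assign_compartments(tab, ids, perimeter_um = 90)
  pg1 <- lab$cell_id[lab$compartment == "periglomerular"]
  pg2 <- lab2$cell_id[lab2$compartment == "periglomerular"]
  expect_true(all(pg1 %in% pg2))
})

test_that("compartment composition computes exact fractions", {
  lab <- data.frame(cell_id = sprintf("c%d", 1:6),
                    sample_id = "s1", condition = "control",
                    compartment = c(rep("glomerular", 4), "tubulointerstitial",
                                    "tubulointerstitial"),
                    glomerulus_id = c(1, 1, 1, 1, NA, NA),
                    roi_id = c(1, 1, 1, 1, NA, NA))
  types <- c("POD", "POD", "PEC", "MC", "PT", "PT")
  comp <- compartment_composition(lab, types)
  roi <- comp$per_roi[comp$per_roi$compartment == "glomerular", ]
  frac <- setNames(roi$fraction, roi$cell_type)
  expect_equal(frac[["POD"]], 0.5)
  expect_equal(frac[["PEC"]], 0.25)
  expect_equal(frac[["MC"]], 0.25)
  sums <- tapply(comp$per_roi$fraction,
                 paste(comp$per_roi$unit, comp$per_roi$compartment), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
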