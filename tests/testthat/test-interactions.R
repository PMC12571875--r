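# a small two-type spatial fixture with controllable ligand/receptor levels
lr_fixture <- function(n_s = 30, n_t = 30, gap = 50, lig = 5, rec = 5,
                       slide = rep("sl1", n_s + n_t), seed = 20) {
  set.seed(seed)
  n <- n_s + n_t
  cells <- data.frame(cell_id = sprintf("c%03d", 1:n),
                      x_um = c(runif(n_s, 0, 100), runif(n_t, gap, gap + 100)),
                      y_um = runif(n, 0, 100),
                      slide_id = slide, sample_id = paste0("s_", slide), condition = "disease",
                      stringsAsFactors = FALSE)
  counts <- cbind(L1 = c(rpois(n_s, lig), rpois(n_t, 0.1)),
                  R1 = c(rpois(n_s, 0.1), rpois(n_t, rec)),
                  BG = rpois(n, 3))
  rownames(counts) <- cells$cell_id
  list(table = spatial_cell_table(cells, counts),
       types = rep(c("S", "T"), c(n_s, n_t)),
       db = data.frame(interaction_id = "L1_R1", ligand_genes = "L1",
                       receptor_genes = "R1", pathway = "TEST",
                       category = "secreted", stringsAsFactors = FALSE))
}

test_that("slide offsets separate slides and preserve within-slide geometry", {
  fx <- lr_fixture(slide = rep(c("sl1", "sl2"), each = 30))
  tab <- fx$table
  shifted <- apply_slide_offsets(tab, interaction_range_um = 250, gap_factor = 10)
  i1 <- shifted$cells$slide_id == "sl1"
  expect_gte(min(outer(shifted$cells$x_um[!i1], shifted$cells$x_um[i1], "-")),
             2500)
  d0 <- dist(cbind(tab$cells$x_um[i1], tab$cells$y_um[i1]))
  d1 <- dist(cbind(shifted$cells$x_um[i1], shifted$cells$y_um[i1]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  # a single slide is only translated, never stretched
  one <- subset_cells(tab, which(i1))
  s1 <- apply_slide_offsets(one, 250)
  expect_equal(diff(range(s1$cells$x_um)), diff(range(one$cells$x_um)))
})

test_that("truncated mean drops floor(trim*n) per tail then averages", {
  expect_equal(truncated_mean(c(0:8, 100), trim = 0.1), mean(1:8))
  expect_equal(truncated_mean(c(0:8, 100), trim = 0.1), 4.5)
  expect_equal(truncated_mean(c(3, 1, 2), trim = 0), 2)
  expect_equal(truncated_mean(rep(7, 9), trim = 0.3), 7)
  expect_error(truncated_mean(numeric(0)), class = "glomscape_parameter_error")
  expect_error(truncated_mean(1:3, trim = 0.5), class = "glomscape_parameter_error")
})

test_that("communication probability follows ligand, receptor and proximity", {
  cfg <- interaction_config(n_permutations = 25, min_cells = 5, seed = 1)
  fx <- lr_fixture(gap = 50)
  net <- communication_probability(fx$table, fx$types, fx$db, cfg)
  e <- net$edges
  st <- e[e$source == "S" & e$target == "T", ]
  expect_gt(st$prob, 0)
  # zero ligand in the source type kills the probability
  fx0 <- lr_fixture(lig = 0)
  # force exact zeros (rpois(., 0) already is 0)
  net0 <- communication_probability(fx0$table, fx0$types, fx0$db, cfg)
  expect_equal(net0$edges$prob[net0$edges$source == "S" & net0$edges$target == "T"], 0)
  # proximity fraction equals the exhaustive pair-count oracle
  pim <- glomscape:::proximity_matrices(fx$table$cells$x_um, fx$table$cells$y_um,
                                        fx$table$cells$slide_id, fx$types,
                                        c("S", "T"),
                                        list(secreted = 80, contact = 10))
  pi_oracle <- proximity_oracle(fx$table$cells$x_um, fx$table$cells$y_um,
                                fx$table$cells$slide_id, fx$types, "S", "T", 80)
  expect_equal(pim$secreted["S", "T"], pi_oracle, tolerance = 1e-12)
  pi_oracle_ss <- proximity_oracle(fx$table$cells$x_um, fx$table$cells$y_um,
                                   fx$table$cells$slide_id, fx$types, "S", "S", 80)
  expect_equal(pim$secreted["S", "S"], pi_oracle_ss, tolerance = 1e-12)
  # types with fewer than min_cells score zero
  cfg_big <- interaction_config(min_cells = 1000)
  net_big <- communication_probability(fx$table, fx$types, fx$db, cfg_big)
  expect_true(all(net_big$edges$prob == 0))
})

test_that("source and target confined to different slides yield zero probability", {
  fx <- lr_fixture(slide = rep(c("sl1", "sl2"), c(30, 30)), gap = 0)
  cfg <- interaction_config(min_cells = 5)
  tab <- apply_slide_offsets(fx$table, cfg$interaction_range_um)
  net <- communication_probability(tab, fx$types, fx$db, cfg)
  e <- net$edges
  expect_equal(e$prob[e$source == "S" & e$target == "T"], 0)
})

test_that("interactions with absent genes are skipped with a warning", {
  fx <- lr_fixture()
  db <- rbind(fx$db, data.frame(interaction_id = "X_Y", ligand_genes = "NOPE",
                                receptor_genes = "R1", pathway = "TEST",
                                category = "secreted"))
  cfg <- interaction_config(min_cells = 5)
  expect_warning(net <- communication_probability(fx$table, fx$types, db, cfg),
                 "absent")
  expect_false("X_Y" %in% net$edges$interaction_id)
})

test_that("permutation p-values hit the add-one floor for planted signal", {
  fx <- lr_fixture(gap = 20, lig = 8, rec = 8)
  cfg <- interaction_config(n_permutations = 49, min_cells = 5, seed = 3)
  net <- communication_probability(fx$table, fx$types, fx$db, cfg)
  net <- permutation_significance(net, cfg)
  e <- net$edges
  expect_true(all(e$pval > 0 & e$pval <= 1))
  expect_equal(e$pval[e$source == "S" & e$target == "T"], 1 / 50)
  expect_error(permutation_significance(net, interaction_config(n_permutations = 5)),
               class = "glomscape_parameter_error")
})

test_that("differential networks difference significant weights with padding", {
  fx <- lr_fixture(gap = 20)
  cfg <- interaction_config(n_permutations = 25, min_cells = 5, seed = 4)
  net <- permutation_significance(
    communication_probability(fx$table, fx$types, fx$db, cfg), cfg)
  zero <- differential_network(net, net)
  expect_true(all(zero == 0))
  # antisymmetry needs two distinct networks
  fx2 <- lr_fixture(gap = 20, lig = 2, seed = 33)
  net2 <- permutation_significance(
    communication_probability(fx2$table, fx2$types, fx2$db, cfg), cfg)
  expect_equal(differential_network(net, net2), -differential_network(net2, net))
})

test_that("incoming-signal tables surface planted disease signalling to PECs", {
  # EC and MC produce the ligand near PECs only in disease
  set.seed(21)
  build <- function(lig_mean) {
    n <- 90
    cells <- data.frame(cell_id = sprintf("c%03d", 1:n),
                        x_um = runif(n, 0, 120), y_um = runif(n, 0, 120),
                        slide_id = "sl1", sample_id = "s1", condition = "x")
    types <- rep(c("EC", "MC", "PEC"), each = 30)
    counts <- cbind(PDGFB = c(rpois(60, lig_mean), rpois(30, 0.05)),
                    PDGFRB = c(rpois(60, 0.05), rpois(30, 6)),
                    BG = rpois(n, 3))
    rownames(counts) <- cells$cell_id
    list(tab = spatial_cell_table(cells, counts), types = types)
  }
  db <- data.frame(interaction_id = "PDGFB_PDGFRB", ligand_genes = "PDGFB",
                   receptor_genes = "PDGFRB", pathway = "PDGF",
                   category = "secreted")
  cfg <- interaction_config(n_permutations = 49, min_cells = 5, seed = 5)
  dis <- build(6); ctl <- build(0.05)
  net_d <- permutation_significance(
    communication_probability(dis$tab, dis$types, db, cfg), cfg)
  net_c <- permutation_significance(
    communication_probability(ctl$tab, ctl$types, db, cfg), cfg)
  inc <- incoming_signals(list(disease = net_d, control = net_c), "PEC")
  expect_gt(nrow(inc), 0)
  top <- inc[inc$condition == "disease", ]
  expect_setequal(unique(top$source[top$pathway == "PDGF"])[1:2], c("EC", "MC"))
  dn <- differential_network(net_d, net_c)
  expect_gt(dn["EC", "PEC"], 0)
  expect_gt(dn["MC", "PEC"], 0)
})

test_that("lr database loader validates schema and category values", {
  db <- read_lr_database(system.file("extdata", "lr_database_synthetic.csv",
                                     package = "glomscape"))
  expect_true(all(db$category %in% c("secreted", "contact")))
  expect_true("TGFB1_TGFBR" %in% db$interaction_id)
  dir <- withr::local_tempdir()
  bad <- db; bad$category[1] <- "weird"
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_lr_database(file.path(dir, "bad.csv")),
               class = "glomscape_validation_error")
})
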