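#' Build a synthetic reference atlas for classifier training
#'
#' Draws labelled expression profiles for the 12 classifier-visible cell
#' types across a grid of severities (an atlas spanning healthy and
#' diseased states). The fibrotic-mesangial state is deliberately absent:
#' it is recovered downstream by the relabeling rule, not by the
#' classifier.
#'
#' @param config a [cohort_config()].
#' @param n_per_type reference cells per type.
#' @param seed integer seed.
#' @return list: `counts` (sparse cells x genes), `labels`.
#' @export
synthetic_reference <- function(config = cohort_config(), n_per_type = 300L,
                                seed = 1L) {
  set.seed(derive_seed(seed, 8L))
  types <- setdiff(synthetic_cell_types(), "FMC")
  sev_grid <- seq(0.05, 0.95, by = 0.1)
  per_bin <- ceiling(n_per_type / length(sev_grid))
  blocks <- list(); labels <- character(0)
  for (ty in types) {
    for (s in sev_grid) {
      blocks[[length(blocks) + 1L]] <- sample_expression(ty, s, config, n = per_bin)
      labels <- c(labels, rep(ty, per_bin))
    }
  }
  counts <- do.call(rbind, blocks)
  rownames(counts) <- sprintf("ref_%06d", seq_along(labels))
  list(counts = counts, labels = labels)
}

#' Niche annotation pipeline stage
#'
#' Domains, glomerular cluster selection, instancing, compartment
#' assignment and fibrotic-mesangial relabeling in one call.
#'
#' @param table a `spatial_cell_table` (post QC).
#' @param cell_types per-cell predicted labels.
#' @param params list of stage parameters (k_neighbors, n_pcs, resolution,
#'   link_distance_um, min_cells, perimeter_um, fibrosis_percentile).
#' @param fibrosis_threshold optional precomputed relabeling threshold.
#' @param seed integer seed.
#' @return list: `labeling`, `cell_types` (with FMC relabeled),
#'   `glomerulus_ids`, `fibrosis_threshold`, `domains`.
#' @export
niche_pipeline <- function(table, cell_types, params = list(),
                           fibrosis_threshold = NULL, seed = 1L) {
  p <- modifyList(list(k_neighbors = 15L, n_pcs = 20L, resolution = 0.5,
                       link_distance_um = 30, min_cells = 15L,
                       perimeter_um = 100, fibrosis_percentile = 0.9), params)
  normalized <- normalize_log1p(table$counts, 1000)
  domains <- annotate_spatial_domains(table, normalized, p$k_neighbors,
                                      p$n_pcs, p$resolution, seed)
  mask <- select_glomerular_clusters(table, domains, normalized)
  glom_ids <- instance_glomeruli(table, mask, p$link_distance_um, p$min_cells)
  labeling <- assign_compartments(table, glom_ids, p$perimeter_um)
  fib <- fibrosis_score(normalized)$score
  rel <- relabel_fibrotic_mesangial(
    cell_types, fib, labeling$compartment == "glomerular",
    conditions = table$cells$condition,
    percentile = p$fibrosis_percentile, threshold = fibrosis_threshold)
  list(labeling = labeling, cell_types = rel$labels, glomerulus_ids = glom_ids,
       fibrosis_threshold = rel$threshold, n_relabeled = rel$n_relabeled,
       domains = domains)
}

default_gmt_path <- function() {
  system.file("extdata", "gene_sets_synthetic.gmt", package = "glomscape")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read, QC, cell typing, niche annotation,
#' trajectory construction, pathway scoring, communication analysis,
#' protein integration and drug prioritization from one configuration,
#' with a single global seed fanned out to per-stage seeds. Re-running
#' with the same configuration reproduces all outputs.
#'
#' @param config nested list (or YAML/JSON path) with either a
#'   `synthetic` block (overrides for [cohort_config()]) or an `inputs`
#'   block (paths for [read_cells()]), per-stage parameter blocks and a
#'   global `seed`; `output_dir` optionally receives stage CSVs and a
#'   JSON manifest.
#' @return list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.null(config$synthetic) && !is.null(config$inputs)) {
    stop_glom("glomscape_config_error",
              "config must have exactly one of 'synthetic' or 'inputs'")
  }
  if (is.null(config$synthetic) && is.null(config$inputs)) {
    stop_glom("glomscape_config_error", "config needs a 'synthetic' or 'inputs' block")
  }
  seed <- config$seed %||% 1L
  manifest <- list(seed = seed, stages = list())
  t0 <- Sys.time()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(...),
                                   elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  }

  # --- data ------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    cfg <- do.call(cohort_config, config$synthetic)
    sim <- generate_cohort(cfg, seed = derive_seed(seed, 10L))
    table <- sim$table
    truth <- sim$truth
    clinical <- truth$clinical
  } else {
    cfg <- cohort_config()
    table <- read_cells(config$inputs$cells, config$inputs$counts,
                        config$inputs$polygons)
    clinical <- if (!is.null(config$inputs$clinical)) read_clinical(config$inputs$clinical)
    if (!is.null(config$inputs$panel)) {
      table <- subset_to_panel(table, read_gene_panel(config$inputs$panel)$gene)
    }
  }
  note("data", n_cells = n_cells(table), n_genes = ncol(table$counts))

  # --- qc --------------------------------------------------------------
  qc <- config$qc %||% list()
  table <- qc_filter_cells(table, min_unique_genes = qc$min_unique_genes %||% 5L,
                           max_mito_fraction = qc$max_mito_fraction,
                           exclude_cells = qc$exclude_cells)
  if (!is.null(truth)) {
    truth$cells <- truth$cells[match(table$cells$cell_id, truth$cells$cell_id), ]
  }
  note("qc", n_cells = n_cells(table),
       removed = as.list(attr(table, "qc_removed")))

  # --- cell typing -----------------------------------------------------
  ty <- config$typing %||% list()
  if (!is.null(ty$model)) {
    model <- read_cell_type_model(ty$model)
  } else if (!is.null(ty$reference_counts)) {
    ref_counts <- Matrix::readMM(ty$reference_counts)
    colnames(ref_counts) <- readLines(paste0(ty$reference_counts, ".genes.txt"))
    ref_labels <- readLines(ty$reference_labels)
    model <- fit_classifier(ref_counts, ref_labels,
                            target_sum = ty$target_sum %||% 1000,
                            seed = derive_seed(seed, 11L))
  } else {
    ref <- synthetic_reference(cfg, n_per_type = ty$n_reference_per_type %||% 300L,
                               seed = derive_seed(seed, 11L))
    model <- fit_classifier(ref$counts, ref$labels,
                            target_sum = ty$target_sum %||% 1000,
                            seed = derive_seed(seed, 11L))
  }
  pred <- predict_cell_types(model, table)
  note("typing", n_labels = length(model$labels),
       median_confidence = round(median(pred$confidence), 4))

  # --- niches ----------------------------------------------------------
  niche <- niche_pipeline(table, pred$label, config$niches %||% list(),
                          seed = derive_seed(seed, 12L))
  comp <- compartment_composition(niche$labeling, niche$cell_types)
  note("niches", n_glomeruli = length(unique(stats::na.omit(niche$glomerulus_ids))),
       n_relabeled_fmc = niche$n_relabeled)

  # --- trajectory ------------------------------------------------------
  tr <- config$trajectory %||% list()
  pb <- pseudobulk_rois(table, niche$labeling)
  traj <- fit_crescent_trajectory(pb$normalized, pb$roi_info$condition,
                                  n_pcs = tr$n_pcs %||% 10L)
  clus <- cluster_rois(traj$scores, pb$roi_info$condition,
                       k_max = tr$k_max %||% 10L, seed = derive_seed(seed, 13L))
  ptime <- compute_pseudotime(pb$normalized, pb$roi_info$condition,
                              seed = derive_seed(seed, 14L))
  quad <- quadrant_breaks(ptime$pseudotime)
  roi_slides <- table$cells$slide_id[match(pb$roi_info$sample_id,
                                           table$cells$sample_id)]
  de <- tryCatch(de_between_clusters(pb$normalized, clus$cluster, roi_slides),
                 error = function(e) NULL)
  med_pc1 <- tapply(traj$pc1, pb$roi_info$patient_id, median)
  clin_cor <- if (!is.null(clinical)) correlate_with_clinical(med_pc1, clinical)
  note("trajectory", n_rois = nrow(pb$raw), k_selected = clus$k_selected)

  # --- pathway scores --------------------------------------------------
  gmt <- read_gmt(config$scoring$gmt %||% default_gmt_path())
  normalized <- normalize_log1p(table$counts, 1000)
  pc1_per_roi <- setNames(traj$pc1, as.character(pb$roi_info$roi_id))
  scores <- lapply(gmt, function(gs) score_gene_set(normalized, gs)$score)
  trends <- lapply(scores, function(sc) {
    tryCatch(trend_along_trajectory(sc, niche$cell_types, "PEC",
                                    niche$labeling$roi_id, pc1_per_roi),
             error = function(e) NULL)
  })
  note("scores", sets = names(gmt))

  # --- interactions (ROI cells only) -----------------------------------
  inter <- NULL
  ic <- config$interactions %||% list()
  if (isTRUE(ic$enabled %||% TRUE)) {
    icfg <- interaction_config(
      n_permutations = ic$n_permutations %||% 100L,
      min_cells = ic$min_cells %||% 10L,
      seed = derive_seed(seed, 15L))
    roi_cells <- which(!is.na(niche$labeling$roi_id))
    lr_db <- read_lr_database(ic$lr_database %||%
                                system.file("extdata", "lr_database_synthetic.csv",
                                            package = "glomscape"))
    lr_db <- lr_db[lr_db$category == "secreted", , drop = FALSE]
    nets <- compute_communication(subset_cells(table, roi_cells),
                                  niche$cell_types[roi_cells], lr_db, icfg)
    nets <- lapply(nets, permutation_significance, config = icfg)
    diffs <- NULL
    if ("control" %in% names(nets)) {
      dis <- setdiff(names(nets), "control")
      diffs <- lapply(setNames(dis, dis), function(d) {
        differential_network(nets[[d]], nets[["control"]], icfg$alpha)
      })
    }
    inter <- list(networks = nets, differential = diffs,
                  incoming_pec = incoming_signals(nets, "PEC", icfg$alpha))
    note("interactions", n_conditions = length(nets))
  }

  # --- protein (synthetic channel, optional) ---------------------------
  prot <- NULL
  pcfg <- config$protein %||% list()
  if (isTRUE(pcfg$enabled %||% FALSE) && !is.null(truth)) {
    sample_ids <- pcfg$samples %||% unique(table$cells$sample_id)
    tabs <- lapply(sample_ids, function(sid) {
      ren <- render_protein_channel(table, truth, cfg,
                                    pixel_size_um = pcfg$pixel_size_um %||% 2,
                                    sample_id = sid,
                                    noise_sd = pcfg$noise_sd %||% 0.05,
                                    seed = derive_seed(seed, 16L))
      aggregate_protein(ren$image, ren$polygons)
    })
    ptab <- do.call(rbind, tabs)
    ptab <- ptab[match(table$cells$cell_id, ptab$cell_id), ]
    keep <- !is.na(ptab$cell_id)
    prot <- positivity_along_trajectory(ptab[keep, ], niche$cell_types[keep],
                                        "PEC", niche$labeling$roi_id[keep],
                                        pc1_per_roi)
    note("protein", n_cells = sum(keep))
  }

  # --- drugs -----------------------------------------------------------
  dg <- config$drugs %||% list()
  drug_table <- read_drug_table(dg$drug_table %||%
                                  system.file("extdata", "drug_targets_synthetic.csv",
                                              package = "glomscape"))
  pathway_name <- dg$pathway %||% "PDGF_SIGNALING"
  drugs <- score_drugs(drug_table, gmt[[pathway_name]],
                       min_score = dg$min_score %||% 0.1)
  note("drugs", n_ranked = nrow(drugs))

  out <- list(table = table, truth = truth, model = model, prediction = pred,
              niche = niche, composition = comp, pseudobulk = pb,
              trajectory = traj, clusters = clus, pseudotime = ptime,
              quadrants = quad, de = de, median_pc1 = med_pc1,
              clinical_correlation = clin_cor, scores = scores,
              trends = trends, interactions = inter, protein = prot,
              drugs = drugs, manifest = manifest)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cbind(niche$labeling, cell_type = niche$cell_types),
              file.path(config$output_dir, "compartments.csv"), row.names = FALSE)
    write.csv(comp$condition_medians,
              file.path(config$output_dir, "composition_medians.csv"), row.names = FALSE)
    roi_out <- cbind(pb$roi_info, pc1 = traj$pc1, cluster = clus$cluster,
                     pseudotime = ptime$pseudotime, quadrant = quad)
    write.csv(roi_out, file.path(config$output_dir, "trajectory_rois.csv"),
              row.names = FALSE)
    write.csv(de, file.path(config$output_dir, "de_results.csv"), row.names = FALSE)
    write.csv(drugs, file.path(config$output_dir, "drug_ranking.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
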