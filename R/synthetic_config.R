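#' Cell types used by the synthetic kidney-tissue generator
#'
#' Twelve classifier-visible types plus the fibrotic-mesangial state `FMC`,
#' which shares mesangial markers and is recovered downstream by the
#' fibrotic-signature relabeling rule (it is absent from classifier
#' references, mirroring how the state is defined in practice).
#'
#' @return character vector of type labels.
#' @export
synthetic_cell_types <- function() {
  c("POD", "PEC", "MC", "FMC", "EC", "VSMC", "FIB", "PT", "CD",
    "MAC", "TC", "NK", "B")
}

#' Marker genes per synthetic cell type
#' @return named list of marker gene vectors (FMC shares MC markers).
#' @export
synthetic_markers <- function() {
  list(
    POD  = c("PODXL", "NPHS1", "NPHS2", "PTPRQ"),
    PEC  = c("CLDN1", "PAX8", "CD44", "VCAM1"),
    MC   = c("PDGFRB", "ITGA8", "GATA3", "TNS1"),
    EC   = c("PECAM1", "EMCN", "FLT1", "EGFL7"),
    VSMC = c("ACTA2", "MYH11", "TAGLN", "CNN1"),
    FIB  = c("PDGFRA", "DCN", "C7", "FBLN1"),
    PT   = c("GPX3", "LRP2", "CUBN", "SLC34A1"),
    CD   = c("AQP2", "AQP3", "SCNN1G", "CALB1"),
    MAC  = c("CD163", "LYZ", "C1QA", "MRC1"),
    TC   = c("CD3D", "CD3E", "CD3G", "IL7R"),
    NK   = c("NKG7", "GNLY", "KLRD1", "PRF1"),
    B    = c("CD79A", "MS4A1", "CD19", "IGHM")
  )
}

#' Functional gene groups of the synthetic panel
#' @return named list: fibrosis set, PDGF/TGFB ligands, receptors and
#'   downstream response genes, miscellaneous signalling genes.
#' @export
synthetic_gene_groups <- function() {
  list(
    fibrosis      = c("COL1A1", "COL4A1", "FN1", "LUM", "TIMP1"),
    pdgf_ligands  = c("PDGFA", "PDGFB", "PDGFC", "PDGFD"),
    pdgf_receptors = c("PDGFRA", "PDGFRB"),
    pdgf_response = c("PIK3R1", "STAT3", "MAPK3", "SPRY1", "JUN", "FOS"),
    tgfb_ligands  = "TGFB1",
    tgfb_receptors = c("TGFBR1", "TGFBR2"),
    tgfb_response = c("SMAD3", "SMAD7", "SERPINE1", "JUNB", "SKIL", "ID1", "TGIF1"),
    misc          = c("VEGFA", "DLL4", "NOTCH1"),
    mito          = c("MT-CO1", "MT-ND1", "MT-CYB")
  )
}

#' The synthetic 480-gene panel
#'
#' Real kidney/immune marker, fibrosis and signalling gene names padded with
#' background filler genes to a panel of exactly 480 genes. The panel is
#' synthetic: it mimics the scale and structure of a targeted in-situ panel,
#' not any published panel's content.
#'
#' @return data.frame with columns `gene`, `category`.
#' @export
synthetic_gene_panel <- function() {
  mk <- synthetic_markers()
  gg <- synthetic_gene_groups()
  named <- data.frame(
    gene = c(unlist(mk, use.names = FALSE), unlist(gg, use.names = FALSE)),
    category = c(rep(paste0("marker_", names(mk)), lengths(mk)),
                 rep(names(gg), lengths(gg))),
    stringsAsFactors = FALSE
  )
  named <- named[!duplicated(named$gene), , drop = FALSE]  # receptors double as markers
  n_fill <- 480L - nrow(named)
  fill <- data.frame(gene = sprintf("BG%03d", seq_len(n_fill)),
                     category = "background", stringsAsFactors = FALSE)
  rbind(named, fill)
}

#' Default per-condition, per-compartment cell-type compositions
#'
#' Expected cell-type fractions (per cent / 100) for each condition and
#' compartment. Entries reported for the real cohort (glomerular podocyte,
#' PEC, mesangial, fibrotic-mesangial and macrophage medians; periglomerular
#' and tubulointerstitial T-cell medians) are used verbatim as the
#' generator's expectations; the remaining entries are plausible kidney
#' tissue compositions chosen so each column sums to 1.
#'
#' @return named list `compositions[[compartment]]`: matrix types x conditions.
#' @export
default_compositions <- function() {
  types <- synthetic_cell_types()
  conds <- c("control", "SLE", "ANCA-GN", "anti-GBM")
  glom <- cbind(
    control    = c(POD = 30,   PEC = 6,  MC = 17.9, FMC = 1.6, EC = 25, VSMC = 3,
                   FIB = 2,    PT = 9.5, CD = 2,    MAC = 0.4, TC = 1,  NK = 0.8, B = 0.8),
    SLE        = c(POD = 25.9, PEC = 8,  MC = 10.2, FMC = 2,   EC = 23, VSMC = 3,
                   FIB = 3.5,  PT = 14.4, CD = 3,   MAC = 2,   TC = 2.5, NK = 1,  B = 1.5),
    `ANCA-GN`  = c(POD = 25,   PEC = 15, MC = 7.1,  FMC = 6.4, EC = 19, VSMC = 3,
                   FIB = 4.5,  PT = 10,  CD = 2,    MAC = 2,   TC = 3.5, NK = 1.2, B = 1.3),
    `anti-GBM` = c(POD = 23.8, PEC = 15, MC = 4.3,  FMC = 8.8, EC = 16, VSMC = 3,
                   FIB = 5.5,  PT = 7.3, CD = 2,    MAC = 7.8, TC = 4,  NK = 1.2, B = 1.3)
  )
  peri <- cbind(
    control    = c(POD = 0.5, PEC = 2,   MC = 2, FMC = 1,   EC = 14, VSMC = 4,
                   FIB = 8,   PT = 50,   CD = 12, MAC = 2.5, TC = 1.1, NK = 1.4, B = 1.5),
    SLE        = c(POD = 0.5, PEC = 2.5, MC = 2, FMC = 1.5, EC = 13, VSMC = 4,
                   FIB = 9,   PT = 45.5, CD = 11, MAC = 4,   TC = 2.5, NK = 2,   B = 2.5),
    `ANCA-GN`  = c(POD = 0.5, PEC = 3,   MC = 2, FMC = 3,   EC = 12, VSMC = 4,
                   FIB = 11,  PT = 40.2, CD = 10, MAC = 5,   TC = 4.8, NK = 2,   B = 2.5),
    `anti-GBM` = c(POD = 0.5, PEC = 3,   MC = 2, FMC = 4,   EC = 11, VSMC = 4,
                   FIB = 12,  PT = 36.1, CD = 9,  MAC = 6,   TC = 7.4, NK = 2.5, B = 2.5)
  )
  tubulo <- cbind(
    control    = c(POD = 0.2, PEC = 0.5, MC = 1, FMC = 0.5, EC = 12,   VSMC = 3,
                   FIB = 8,   PT = 55,   CD = 15,   MAC = 2,   TC = 1.13, NK = 0.87, B = 0.8),
    SLE        = c(POD = 0.2, PEC = 0.5, MC = 1, FMC = 1,   EC = 11.5, VSMC = 3,
                   FIB = 9.5, PT = 51.5, CD = 13.5, MAC = 3.5, TC = 2.28, NK = 1.22, B = 1.3),
    `ANCA-GN`  = c(POD = 0.2, PEC = 0.5, MC = 1, FMC = 2,   EC = 11,   VSMC = 3,
                   FIB = 11,  PT = 47.5, CD = 12.5, MAC = 4.5, TC = 3.82, NK = 1.48, B = 1.5),
    `anti-GBM` = c(POD = 0.2, PEC = 0.5, MC = 1, FMC = 2.5, EC = 10.5, VSMC = 3,
                   FIB = 12,  PT = 45,   CD = 12,   MAC = 5,   TC = 4.4,  NK = 1.9,  B = 2)
  )
  out <- list(glomerular = glom, periglomerular = peri, tubulointerstitial = tubulo)
  for (nm in names(out)) {
    m <- out[[nm]][types, conds, drop = FALSE] / 100
    stopifnot(all(abs(colSums(m) - 1) < 1e-6))
    out[[nm]] <- m
  }
  out
}

#' Baseline expression means per cell type
#'
#' Rows are generator cell types, columns the 480 panel genes. Marker genes
#' of a type sit far above the background mean; fibrosis and signalling
#' genes carry the baselines that the severity modifiers act on.
#'
#' @param config a [cohort_config()] (for background and marker levels).
#' @return numeric matrix types x genes.
#' @export
baseline_expression <- function(config = cohort_config()) {
  panel <- synthetic_gene_panel()$gene
  types <- synthetic_cell_types()
  mk <- synthetic_markers()
  gg <- synthetic_gene_groups()
  ex <- config$expression
  mu <- matrix(ex$background_mean, nrow = length(types), ncol = length(panel),
               dimnames = list(types, panel))
  for (ty in names(mk)) mu[ty, mk[[ty]]] <- ex$marker_mean
  mu["FMC", mk$MC] <- ex$marker_mean            # shares mesangial identity
  mu["FMC", gg$fibrosis] <- ex$fmc_fibrosis_mean
  mu["FIB", gg$fibrosis] <- ex$fib_fibrosis_mean
  mu["PEC", gg$fibrosis] <- ex$pec_fibrosis_mean
  mu["PEC", c(gg$pdgf_response, gg$pdgf_receptors,
              gg$tgfb_response, gg$tgfb_receptors)] <- ex$response_mean
  for (ty in c("EC", "MC", "VSMC", "MAC")) mu[ty, gg$pdgf_ligands] <- ex$ligand_mean
  for (ty in c("FMC", "MAC", "TC", "POD", "EC")) mu[ty, gg$tgfb_ligands] <- ex$ligand_mean
  mu["POD", "VEGFA"] <- 1
  mu["EC", "DLL4"] <- 0.5
  mu[c("MC", "VSMC"), "NOTCH1"] <- 0.5
  mu[, gg$mito] <- ex$mito_mean
  mu
}

#' Severity response multipliers for one cell type
#'
#' Encodes the latent-severity dynamics the generator emulates: a
#' rise-then-fall (quadratic hump, peak at s = 0.5) PDGF response and a
#' monotone saturating TGF-beta response in PECs, a monotone fibrosis
#' programme in PECs and fibrotic-mesangial cells, and severity-scaled
#' ligand production in the sender types.
#'
#' @param type cell type label.
#' @param s severity in `[0, 1]`.
#' @param config a [cohort_config()].
#' @return named multiplier vector over panel genes (mostly 1).
#' @export
severity_multipliers <- function(type, s, config = cohort_config()) {
  panel <- synthetic_gene_panel()$gene
  gg <- synthetic_gene_groups()
  se <- config$severity_effects
  m <- rep(1, length(panel))
  names(m) <- panel
  hump <- 4 * s * (1 - s)
  sat <- s / (se$tgfb_halfpoint + s)
  if (type == "PEC") {
    m[gg$pdgf_response] <- 1 + se$pdgf_amplitude * hump
    m[gg$tgfb_response] <- 1 + se$tgfb_amplitude * sat
    m[gg$fibrosis] <- 1 + se$pec_fibrosis_slope * s
  }
  if (type == "FMC") {
    m[gg$fibrosis] <- 1 + se$fmc_fibrosis_slope * s
  }
  if (type %in% c("EC", "MC", "VSMC", "MAC")) {
    m[gg$pdgf_ligands] <- 1 + se$ligand_slope * s
  }
  if (type %in% c("FMC", "MAC", "TC", "POD", "EC")) {
    m[gg$tgfb_ligands] <- 1 + se$ligand_slope * s
  }
  m
}

#' Configuration of a synthetic cohort
#'
#' Defaults encode the emulated study conditions: circular glomerular
#' niches (radius 90 +/- 15 um) inside square tissue fields, an exact
#' 100-um periglomerular annulus, per-condition/per-compartment cell-type
#' compositions anchored at the reported medians, per-ROI latent severity
#' drawn from condition-specific Beta distributions, negative-binomial
#' counts over a 480-gene panel at a per-cell depth of a few tens of
#' transcripts, and a Ki-67-like protein channel whose PEC positivity
#' follows a rise-then-fall severity curve.
#'
#' @param n_samples_per_condition named integer vector (condition -> samples).
#' @param glomeruli_per_sample glomerulus discs per tissue field.
#' @param glomerulus_radius_um mean and sd of disc radii.
#' @param field_size_um side of the square field.
#' @param cell_density cells per 1000 um^2 per compartment.
#' @param severity_beta named list of `c(shape1, shape2)` per condition.
#' @param composition_shift linear composition response to severity
#'   (deviations from the condition median severity).
#' @param dirichlet_concentration between-ROI composition jitter
#'   (larger = tighter around the expectation).
#' @param expression expression-scale parameters (background/marker means,
#'   NB size, ...).
#' @param severity_effects amplitudes of the severity-driven expression
#'   programmes.
#' @param protein Ki-67-like channel model parameters.
#' @param geometry disc placement parameters.
#' @param samples_per_slide samples sharing one slide id.
#' @param ... overrides merged into the structure above.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples_per_condition = c("control" = 5, "SLE" = 5,
                                                      "ANCA-GN" = 5, "anti-GBM" = 5),
                          glomeruli_per_sample = 4L,
                          glomerulus_radius_um = c(mean = 90, sd = 15),
                          field_size_um = 800,
                          cell_density = c(glomerular = 8, periglomerular = 7,
                                           tubulointerstitial = 7),
                          severity_beta = list("control" = c(1.2, 10), "SLE" = c(2, 5),
                                               "ANCA-GN" = c(4, 3), "anti-GBM" = c(6, 2)),
                          composition_shift = NULL,
                          dirichlet_concentration = 600,
                          expression = NULL,
                          severity_effects = NULL,
                          protein = NULL,
                          geometry = NULL,
                          samples_per_slide = 5L,
                          ...) {
  expression <- modifyList(list(
    background_mean = 0.025, marker_mean = 5.5, response_mean = 0.4,
    ligand_mean = 0.15, pec_fibrosis_mean = 0.7, fmc_fibrosis_mean = 1.5,
    fib_fibrosis_mean = 0.5, mito_mean = 0.05, nb_size = 2
  ), expression %||% list())
  severity_effects <- modifyList(list(
    pdgf_amplitude = 3, tgfb_amplitude = 3.5, tgfb_halfpoint = 0.3,
    pec_fibrosis_slope = 5, fmc_fibrosis_slope = 1, ligand_slope = 3
  ), severity_effects %||% list())
  composition_shift <- modifyList(list(
    glomerular = c(PEC = 0.10, MAC = 0.03, FMC = 0.05,
                   POD = -0.06, EC = -0.06, MC = -0.05, PT = -0.01),
    periglomerular = c(TC = 0.05, MAC = 0.03, FIB = 0.02, PT = -0.07, CD = -0.03),
    tubulointerstitial = c(TC = 0.04, MAC = 0.02, PT = -0.05, CD = -0.01)
  ), composition_shift %||% list())
  protein <- modifyList(list(
    background_mean = 0.5, background_sd = 0.15,
    positive_mean = 3, positive_sd = 0.3,
    base_positive_rate = 0.05, positive_rate_amplitude = 0.7,
    polygon_radius_um = 4
  ), protein %||% list())
  geometry <- modifyList(list(core_gap_um = 60, max_placement_tries = 4000L,
                              perimeter_um = 100), geometry %||% list())
  cfg <- list(
    n_samples_per_condition = n_samples_per_condition,
    glomeruli_per_sample = as.integer(glomeruli_per_sample),
    glomerulus_radius_um = glomerulus_radius_um,
    field_size_um = field_size_um,
    cell_density = cell_density,
    severity_beta = severity_beta,
    composition_shift = composition_shift,
    dirichlet_concentration = dirichlet_concentration,
    compositions = default_compositions(),
    expression = expression,
    severity_effects = severity_effects,
    protein = protein,
    geometry = geometry,
    samples_per_slide = as.integer(samples_per_slide)
  )
  cfg <- modifyList(cfg, list(...))
  stopifnot(cfg$glomerulus_radius_um[["mean"]] > 0, all(cfg$cell_density > 0),
            cfg$field_size_um > 0)
  for (comp in names(cfg$compositions)) {
    m <- cfg$compositions[[comp]]
    if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-6)) {
      stop_glom("glomscape_parameter_error",
                "composition fractions for %s must be >= 0 and sum to 1", comp)
    }
  }
  structure(cfg, class = "cohort_config")
}
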