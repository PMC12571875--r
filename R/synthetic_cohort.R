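place_glomeruli <- function(config) {
  g <- config$glomeruli_per_sample
  L <- config$field_size_um
  rmu <- config$glomerulus_radius_um[["mean"]]
  rsd <- config$glomerulus_radius_um[["sd"]]
  radii <- pmin(pmax(rnorm(g, rmu, rsd), 0.5 * rmu), 1.6 * rmu)
  gap <- config$geometry$core_gap_um
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  for (i in seq_len(g)) {
    repeat {
      tries <- tries + 1L
      if (tries > config$geometry$max_placement_tries) {
        stop_glom("glomscape_geometry_error",
                  "could not place %d non-overlapping glomeruli in a %g-um field; increase field_size_um",
                  g, L)
      }
      x <- runif(1, radii[i] + 5, L - radii[i] - 5)
      y <- runif(1, radii[i] + 5, L - radii[i] - 5)
      if (!length(cx) ||
          all(sqrt((cx - x)^2 + (cy - y)^2) >= radii[seq_along(cx)] + radii[i] + gap)) {
        cx <- c(cx, x); cy <- c(cy, y)
        break
      }
    }
  }
  data.frame(cx = cx, cy = cy, radius = radii)
}

# boundary-distance classification of points against placed discs;
# ownership by nearest disc boundary, periglomerular within perimeter_um
classify_points <- function(px, py, glo, perimeter_um) {
  n <- length(px)
  bdist <- matrix(Inf, n, nrow(glo))
  for (j in seq_len(nrow(glo))) {
    bdist[, j] <- sqrt((px - glo$cx[j])^2 + (py - glo$cy[j])^2) - glo$radius[j]
  }
  nearest <- max.col(-bdist, ties.method = "first")
  nd <- bdist[cbind(seq_len(n), nearest)]
  comp <- ifelse(nd <= 0, "glomerular",
                 ifelse(nd <= perimeter_um, "periglomerular", "tubulointerstitial"))
  glom_row <- ifelse(comp == "tubulointerstitial", NA_integer_, nearest)
  list(compartment = comp, glomerulus_row = glom_row)
}

shift_composition <- function(base, shift, delta) {
  p <- base
  common <- intersect(names(shift), names(p))
  p[common] <- p[common] + shift[common] * delta
  p <- pmax(p, 0)
  p / sum(p)
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  if (sum(x) <= 0) x <- alpha
  x / sum(x)
}

#' Draw negative-binomial expression counts for cells of one type
#'
#' Per-gene means are the type's baseline expression scaled by its severity
#' multipliers ([severity_multipliers()]); counts are negative binomial with
#' the configured size (Poisson in the large-size limit). Uses the current
#' RNG state: all randomness in a cohort flows from [generate_cohort()]'s
#' single seed.
#'
#' @param cell_type generator cell type.
#' @param severity latent severity in `[0, 1]`.
#' @param config a [cohort_config()].
#' @param n number of cells to draw.
#' @return sparse `n` x genes count matrix.
#' @export
sample_expression <- function(cell_type, severity, config = cohort_config(), n = 1L) {
  mu <- expression_means(cell_type, severity, config)
  counts <- matrix(rnbinom(n * length(mu), size = config$expression$nb_size,
                           mu = rep(mu, each = n)), nrow = n)
  colnames(counts) <- names(mu)
  methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Analytic expression means for a (type, severity) pair
#'
#' @inheritParams sample_expression
#' @return named numeric vector of per-gene negative-binomial means.
#' @export
expression_means <- function(cell_type, severity, config = cohort_config()) {
  base <- baseline_expression(config)
  if (!cell_type %in% rownames(base)) {
    stop_glom("glomscape_key_error", "unknown cell type '%s'", cell_type)
  }
  base[cell_type, ] * severity_multipliers(cell_type, severity, config)
}

#' Generate a synthetic spatial transcriptomics cohort
#'
#' For each sample, places non-overlapping glomerulus discs in a square
#' field, fills the discs, their exact 100-um periglomerular annuli and the
#' remaining tubulointerstitial tissue with cells at the configured
#' densities, draws a latent severity per glomerulus (ROI) from the
#' condition's Beta distribution, perturbs compartment compositions around
#' the condition medians as a function of severity (PEC and innate immune
#' expansion, podocyte and mesangial loss, T-cell infiltration), and samples
#' negative-binomial counts per cell. Returns the cell table together with
#' complete ground truth (per-cell type / compartment / glomerulus, per-ROI
#' severity, and a synthetic clinical table whose eGFR declines with mean
#' severity).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; output is deterministic given (config, seed).
#' @return list with elements `table` (a [spatial_cell_table()]) and
#'   `truth` (data.frames `cells`, `rois`, `samples`, `clinical`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(derive_seed(seed, 1L))
  types <- synthetic_cell_types()
  comps <- config$compositions
  shift <- config$composition_shift
  dens <- config$cell_density / 1000   # cells per um^2
  L <- config$field_size_um
  conds <- names(config$n_samples_per_condition)
  conc <- config$dirichlet_concentration

  cells_list <- list(); truth_list <- list(); roi_list <- list(); sample_list <- list()
  glom_counter <- 0L; patient_counter <- 0L

  for (cond in conds) {
    ab <- config$severity_beta[[cond]]
    s_med <- qbeta(0.5, ab[1], ab[2])
    for (si in seq_len(config$n_samples_per_condition[[cond]])) {
      sample_id <- sprintf("%s_s%02d", cond, si)
      slide_id <- sprintf("%s_sl%d", cond, (si - 1L) %/% config$samples_per_slide + 1L)
      patient_counter <- patient_counter + 1L
      patient_id <- sprintf("P%03d", patient_counter)

      glo <- place_glomeruli(config)
      glo$glomerulus_id <- glom_counter + seq_len(nrow(glo))
      glom_counter <- glom_counter + nrow(glo)
      glo$severity <- rbeta(nrow(glo), ab[1], ab[2])
      delta <- glo$severity - s_med
      sample_delta <- mean(delta)
      sample_sev <- mean(glo$severity)

      # candidate points, tagged by the region they were drawn for
      blocks <- list()
      for (j in seq_len(nrow(glo))) {
        n_g <- rpois(1, dens[["glomerular"]] * pi * glo$radius[j]^2)
        rr <- glo$radius[j] * sqrt(runif(n_g)); th <- runif(n_g, 0, 2 * pi)
        blocks[[length(blocks) + 1L]] <-
          data.frame(x = glo$cx[j] + rr * cos(th), y = glo$cy[j] + rr * sin(th),
                     src = "glomerular", src_row = j)
        r_out <- glo$radius[j] + config$geometry$perimeter_um
        n_p <- rpois(1, dens[["periglomerular"]] * pi * (r_out^2 - glo$radius[j]^2))
        rr <- sqrt(runif(n_p, glo$radius[j]^2, r_out^2)); th <- runif(n_p, 0, 2 * pi)
        blocks[[length(blocks) + 1L]] <-
          data.frame(x = glo$cx[j] + rr * cos(th), y = glo$cy[j] + rr * sin(th),
                     src = "periglomerular", src_row = j)
      }
      n_t <- rpois(1, dens[["tubulointerstitial"]] * L^2)
      blocks[[length(blocks) + 1L]] <-
        data.frame(x = runif(n_t, 0, L), y = runif(n_t, 0, L),
                   src = "tubulointerstitial", src_row = NA_integer_)
      pts <- do.call(rbind, blocks)
      pts <- pts[pts$x >= 0 & pts$x <= L & pts$y >= 0 & pts$y <= L, , drop = FALSE]
      cl <- classify_points(pts$x, pts$y, glo, config$geometry$perimeter_um)
      keep <- (pts$src == "glomerular") |
        (pts$src == "periglomerular" & cl$compartment == "periglomerular" &
           cl$glomerulus_row == pts$src_row & !is.na(cl$glomerulus_row)) |
        (pts$src == "tubulointerstitial" & cl$compartment == "tubulointerstitial")
      keep[is.na(keep)] <- FALSE
      pts <- pts[keep, , drop = FALSE]
      comp <- cl$compartment[keep]
      grow <- cl$glomerulus_row[keep]

      n_cell <- nrow(pts)
      if (n_cell == 0) next
      true_type <- character(n_cell)
      severity_cell <- numeric(n_cell)

      # per-ROI compositions for glomerular and periglomerular compartments
      for (j in seq_len(nrow(glo))) {
        for (cm in c("glomerular", "periglomerular")) {
          idx <- which(comp == cm & grow == j)
          if (!length(idx)) next
          p <- shift_composition(comps[[cm]][, cond], shift[[cm]], delta[j])
          p <- rdirichlet1(conc * p)
          true_type[idx] <- sample(types, length(idx), replace = TRUE, prob = p)
          severity_cell[idx] <- glo$severity[j]
        }
      }
      idx <- which(comp == "tubulointerstitial")
      if (length(idx)) {
        p <- shift_composition(comps[["tubulointerstitial"]][, cond],
                               shift[["tubulointerstitial"]], sample_delta)
        p <- rdirichlet1(conc * p)
        true_type[idx] <- sample(types, length(idx), replace = TRUE, prob = p)
        severity_cell[idx] <- sample_sev
      }

      cell_id <- sprintf("%s_c%05d", sample_id, seq_len(n_cell))
      cells_list[[length(cells_list) + 1L]] <- data.frame(
        cell_id = cell_id, x_um = pts$x, y_um = pts$y,
        slide_id = slide_id, sample_id = sample_id, patient_id = patient_id,
        condition = cond, stringsAsFactors = FALSE)
      truth_list[[length(truth_list) + 1L]] <- data.frame(
        cell_id = cell_id, true_type = true_type, true_compartment = comp,
        true_glomerulus = ifelse(is.na(grow), NA_integer_, glo$glomerulus_id[grow]),
        true_severity = severity_cell, stringsAsFactors = FALSE)
      roi_list[[length(roi_list) + 1L]] <- data.frame(
        glomerulus_id = glo$glomerulus_id, sample_id = sample_id,
        patient_id = patient_id, condition = cond,
        cx = glo$cx, cy = glo$cy, radius = glo$radius,
        severity = glo$severity, stringsAsFactors = FALSE)
      sample_list[[length(sample_list) + 1L]] <- data.frame(
        sample_id = sample_id, patient_id = patient_id, slide_id = slide_id,
        condition = cond, mean_severity = sample_sev, stringsAsFactors = FALSE)
    }
  }

  cells <- do.call(rbind, cells_list)
  truth_cells <- do.call(rbind, truth_list)
  rois <- do.call(rbind, roi_list)
  samples <- do.call(rbind, sample_list)

  # expression: one NB block per (type, severity) group
  key <- paste(truth_cells$true_type, signif(truth_cells$true_severity, 10))
  counts <- NULL
  blocks <- vector("list", length(unique(key)))
  order_idx <- integer(0)
  ki <- 0L
  for (k in unique(key)) {
    ki <- ki + 1L
    idx <- which(key == k)
    blocks[[ki]] <- sample_expression(truth_cells$true_type[idx[1]],
                                      truth_cells$true_severity[idx[1]],
                                      config, n = length(idx))
    order_idx <- c(order_idx, idx)
  }
  counts <- do.call(rbind, blocks)
  counts <- counts[order(order_idx), , drop = FALSE]

  # synthetic clinical covariates tied to mean severity
  egfr <- pmax(5, 100 * (1 - samples$mean_severity) + rnorm(nrow(samples), 0, 6))
  alb <- 100 + 2500 * samples$mean_severity * exp(rnorm(nrow(samples), 0, 0.3))
  age <- round(runif(nrow(samples), 35, 75))
  risk <- ifelse(samples$condition == "ANCA-GN",
                 as.character(cut(samples$mean_severity, c(-0.01, 1 / 3, 2 / 3, 1.01),
                                  labels = c("low", "medium", "high"))),
                 NA_character_)
  clinical <- data.frame(patient_id = samples$patient_id, egfr = egfr,
                         albuminuria = alb, age = age, anca_risk = risk,
                         stringsAsFactors = FALSE)

  table <- spatial_cell_table(cells, counts)
  truth <- list(cells = truth_cells, rois = rois, samples = samples,
                clinical = clinical)
  list(table = table, truth = truth)
}

#' Model value of the Ki-67-like protein channel
#'
#' Deterministic per-cell mean: background for all types, plus a
#' rise-then-fall severity response for PECs expressed through the
#' positivity rate (peak at severity 0.5).
#'
#' @param type cell type.
#' @param severity latent severity.
#' @param protein the `protein` block of a [cohort_config()].
#' @return expected per-cell intensity.
#' @export
protein_model_value <- function(type, severity, protein) {
  p_pos <- ifelse(type == "PEC",
                  protein$base_positive_rate +
                    protein$positive_rate_amplitude * 4 * severity * (1 - severity),
                  0)
  protein$background_mean + p_pos * (protein$positive_mean - protein$background_mean)
}

#' Render a synthetic protein channel for one sample
#'
#' Rasterizes a Ki-67-like intensity image: each cell's regular-hexagon
#' polygon is filled with the cell's intensity (pixel-center membership,
#' additive where polygons overlap), plus optional Gaussian pixel noise.
#' PEC intensities follow a bimodal positive/negative model whose positive
#' rate rises then falls in severity; other types stay at background.
#'
#' @param table a `spatial_cell_table` (one sample, or pass `sample_id`).
#' @param truth truth object from [generate_cohort()].
#' @param config a [cohort_config()].
#' @param pixel_size_um pixel size of the rendered grid.
#' @param sample_id sample to render (defaults to the only sample present).
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param stochastic if `FALSE`, every cell is filled with its deterministic
#'   model value ([protein_model_value()]) instead of a bimodal draw.
#' @param seed seed for the intensity draws and pixel noise.
#' @return list: `image` (a [protein_image()]), `polygons` (named list of
#'   hexagons), `cell_values` (per-cell fill intensities).
#' @export
render_protein_channel <- function(table, truth, config = cohort_config(),
                                   pixel_size_um = 2, sample_id = NULL,
                                   noise_sd = 0, stochastic = TRUE, seed = 1L) {
  if (pixel_size_um <= 0) stop_glom("glomscape_parameter_error", "pixel_size_um must be > 0")
  samples <- unique(table$cells$sample_id)
  if (is.null(sample_id)) {
    if (length(samples) != 1) {
      stop_glom("glomscape_parameter_error",
                "table holds %d samples; pass sample_id", length(samples))
    }
    sample_id <- samples
  }
  sub <- subset_cells(table, which(table$cells$sample_id == sample_id))
  tc <- truth$cells[match(sub$cells$cell_id, truth$cells$cell_id), ]
  pr <- config$protein
  set.seed(derive_seed(seed, 7L))
  n <- n_cells(sub)
  if (stochastic) {
    p_pos <- ifelse(tc$true_type == "PEC",
                    pr$base_positive_rate +
                      pr$positive_rate_amplitude * 4 * tc$true_severity * (1 - tc$true_severity),
                    0)
    pos <- runif(n) < p_pos
    vals <- ifelse(pos, rnorm(n, pr$positive_mean, pr$positive_sd),
                   rnorm(n, pr$background_mean, pr$background_sd))
    vals <- pmax(vals, 0)
  } else {
    vals <- protein_model_value(tc$true_type, tc$true_severity, pr)
  }
  L <- config$field_size_um
  npix <- ceiling(L / pixel_size_um)
  if (npix > 4096) stop_glom("glomscape_size_error", "field too large for pixel budget")
  img <- matrix(0, nrow = npix, ncol = npix)
  polys <- cell_hexagons(sub, radius_um = pr$polygon_radius_um)
  centers <- (seq_len(npix) - 0.5) * pixel_size_um
  for (i in seq_len(n)) {
    poly <- polys[[i]]
    xi <- which(centers >= min(poly[, 1]) - pixel_size_um &
                  centers <= max(poly[, 1]) + pixel_size_um)
    yi <- which(centers >= min(poly[, 2]) - pixel_size_um &
                  centers <= max(poly[, 2]) + pixel_size_um)
    if (!length(xi) || !length(yi)) next
    gx <- rep(centers[xi], times = length(yi))
    gy <- rep(centers[yi], each = length(xi))
    inside <- points_in_polygon(gx, gy, poly)
    if (any(inside)) {
      ix <- rep(xi, times = length(yi))[inside]
      iy <- rep(yi, each = length(xi))[inside]
      img[cbind(ix, iy)] <- img[cbind(ix, iy)] + vals[i]
    }
  }
  if (noise_sd > 0) {
    img <- pmax(img + matrix(rnorm(npix * npix, 0, noise_sd), npix, npix), 0)
  }
  list(image = protein_image(img, pixel_size_um, channel = "KI67"),
       polygons = polys,
       cell_values = setNames(vals, sub$cells$cell_id))
}
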