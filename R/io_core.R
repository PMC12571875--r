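#' Construct a spatial cell table
#'
#' The central container of the package: a per-cell metadata table plus a
#' sparse cells-by-genes count matrix and optional cell-boundary polygons.
#' Coordinates are micrometres with an arbitrary per-slide origin; all
#' downstream geometry uses distances only.
#'
#' @param cells data.frame with at least `cell_id`, `x_um`, `y_um`,
#'   `slide_id`, `sample_id`, `condition`. Extra columns (e.g. `patient_id`,
#'   `cell_type`) are preserved.
#' @param counts sparse (or coercible) non-negative integer matrix, one row
#'   per cell in the order of `cells`; column names are gene names.
#' @param polygons optional named list mapping `cell_id` to a two-column
#'   matrix of polygon vertices (x_um, y_um).
#' @return an object of class `spatial_cell_table`.
#' @export
spatial_cell_table <- function(cells, counts, polygons = NULL) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  assert_cols(cells, c("cell_id", "x_um", "y_um", "slide_id", "sample_id", "condition"),
              "cells table")
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) {
    stop_glom("glomscape_validation_error", "cell_id values must be unique")
  }
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
    stop_glom("glomscape_validation_error", "cell coordinates must be finite")
  }
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != nrow(cells)) {
    stop_glom("glomscape_alignment_error",
              "counts has %d rows but cells table has %d rows", nrow(counts), nrow(cells))
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop_glom("glomscape_validation_error", "counts must be non-negative integers")
  }
  if (is.null(colnames(counts))) {
    stop_glom("glomscape_validation_error", "counts must carry gene names as column names")
  }
  rownames(counts) <- cells$cell_id
  # each sample must map to one condition and one slide
  map <- unique(cells[, c("sample_id", "condition", "slide_id")])
  if (anyDuplicated(map$sample_id)) {
    stop_glom("glomscape_validation_error",
              "each sample_id must map to exactly one condition and slide")
  }
  if (!is.null(polygons)) {
    polygons <- polygons[intersect(names(polygons), cells$cell_id)]
  }
  structure(list(cells = cells, counts = counts, polygons = polygons),
            class = "spatial_cell_table")
}

#' @export
print.spatial_cell_table <- function(x, ...) {
  cat(sprintf("spatial_cell_table: %d cells x %d genes, %d sample(s), %d slide(s)\n",
              nrow(x$cells), ncol(x$counts),
              length(unique(x$cells$sample_id)), length(unique(x$cells$slide_id))))
  cat("conditions:", paste(sort(unique(as.character(x$cells$condition))), collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a spatial cell table
#' @param x a `spatial_cell_table`.
#' @return integer cell count.
#' @export
n_cells <- function(x) nrow(x$cells)

#' Subset a spatial cell table by cell index or id
#' @param table a `spatial_cell_table`.
#' @param idx logical/integer index or character cell ids.
#' @return the subsetted `spatial_cell_table`.
#' @export
subset_cells <- function(table, idx) {
  if (is.character(idx)) idx <- match(idx, table$cells$cell_id)
  cells <- table$cells[idx, , drop = FALSE]
  rownames(cells) <- NULL
  spatial_cell_table(cells, table$counts[idx, , drop = FALSE],
                     polygons = table$polygons)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  as.data.frame(data.table::fread(path, sep = sep, header = TRUE,
                                  stringsAsFactors = FALSE))
}

#' Read a spatial cell table from disk
#'
#' Expects a delimited cell-metadata table (CSV/TSV by extension), a
#' MatrixMarket counts file with companion plain-text gene and cell index
#' files (`<counts>.genes.txt`, `<counts>.cells.txt` next to it, one entry
#' per line), and optionally a JSON polygon file mapping cell ids to vertex
#' lists.
#'
#' @param cells_path path to the delimited cell table.
#' @param counts_path path to the MTX counts file.
#' @param polygons_path optional path to the polygons JSON.
#' @return a validated [spatial_cell_table()].
#' @export
read_cells <- function(cells_path, counts_path, polygons_path = NULL) {
  cells <- read_delim_auto(cells_path)
  assert_cols(cells, c("cell_id", "x_um", "y_um", "slide_id", "sample_id", "condition"),
              basename(cells_path))
  counts <- Matrix::readMM(counts_path)
  genes <- readLines(paste0(counts_path, ".genes.txt"))
  cell_ids <- readLines(paste0(counts_path, ".cells.txt"))
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(genes)) {
    stop_glom("glomscape_alignment_error",
              "counts matrix is %d x %d but index files list %d cells and %d genes",
              nrow(counts), ncol(counts), length(cell_ids), length(genes))
  }
  if (nrow(counts) != nrow(cells)) {
    stop_glom("glomscape_alignment_error",
              "counts file has %d rows, cells file has %d rows", nrow(counts), nrow(cells))
  }
  if (!identical(as.character(cells$cell_id), cell_ids)) {
    ord <- match(as.character(cells$cell_id), cell_ids)
    if (anyNA(ord)) {
      stop_glom("glomscape_alignment_error", "cell ids in counts index do not match cells table")
    }
    counts <- counts[ord, , drop = FALSE]
  }
  colnames(counts) <- genes
  polygons <- NULL
  if (!is.null(polygons_path)) {
    raw <- jsonlite::read_json(polygons_path, simplifyVector = TRUE)
    polygons <- lapply(raw, function(p) {
      m <- matrix(unlist(p), ncol = 2, byrow = FALSE)
      colnames(m) <- c("x_um", "y_um")
      m
    })
  }
  spatial_cell_table(cells, counts, polygons)
}

#' Write a spatial cell table to disk
#'
#' Writes the formats [read_cells()] consumes: a cell CSV, an MTX counts
#' file with `.genes.txt` / `.cells.txt` index files, and optionally a
#' polygons JSON.
#'
#' @param table a `spatial_cell_table`.
#' @param cells_path output path for the cell table (CSV).
#' @param counts_path output path for the MTX counts.
#' @param polygons_path optional output path for the polygons JSON.
#' @return invisibly, the paths written.
#' @export
write_cells <- function(table, cells_path, counts_path, polygons_path = NULL) {
  data.table::fwrite(table$cells, cells_path)
  Matrix::writeMM(table$counts, counts_path)
  writeLines(colnames(table$counts), paste0(counts_path, ".genes.txt"))
  writeLines(table$cells$cell_id, paste0(counts_path, ".cells.txt"))
  if (!is.null(polygons_path) && !is.null(table$polygons)) {
    jsonlite::write_json(lapply(table$polygons, function(m) unclass(as.data.frame(m))),
                         polygons_path, digits = NA, auto_unbox = FALSE)
  }
  invisible(c(cells_path, counts_path, polygons_path))
}

#' Cell-level quality filtering
#'
#' Removes cells expressing fewer than `min_unique_genes` unique genes and,
#' when `max_mito_fraction` is given, cells whose mitochondrial count
#' fraction exceeds it (mitochondrial genes identified by prefix). Cell
#' order is preserved and per-criterion removal counts are attached as the
#' `qc_removed` attribute.
#'
#' @param table a `spatial_cell_table`.
#' @param min_unique_genes minimum number of genes with count > 0 (default 5).
#' @param max_mito_fraction optional maximum mitochondrial count fraction.
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @param exclude_cells optional character vector of cell ids to drop
#'   (e.g. manually flagged artifact regions).
#' @return the filtered `spatial_cell_table`.
#' @export
qc_filter_cells <- function(table, min_unique_genes = 5L, max_mito_fraction = NULL,
                            mito_prefix = "MT-", exclude_cells = NULL) {
  if (min_unique_genes < 1) {
    stop_glom("glomscape_parameter_error", "min_unique_genes must be >= 1")
  }
  if (n_cells(table) == 0) {
    attr(table, "qc_removed") <- c(low_genes = 0L, high_mito = 0L, excluded = 0L)
    return(table)
  }
  genes_per_cell <- Matrix::rowSums(table$counts > 0)
  keep <- genes_per_cell >= min_unique_genes
  removed <- c(low_genes = sum(!keep), high_mito = 0L, excluded = 0L)
  if (!is.null(max_mito_fraction)) {
    mito <- startsWith(colnames(table$counts), mito_prefix)
    tot <- Matrix::rowSums(table$counts)
    mfrac <- ifelse(tot > 0, Matrix::rowSums(table$counts[, mito, drop = FALSE]) / tot, 0)
    drop_mito <- keep & (mfrac > max_mito_fraction)
    removed["high_mito"] <- sum(drop_mito)
    keep <- keep & !drop_mito
  }
  if (!is.null(exclude_cells)) {
    drop_ex <- keep & (table$cells$cell_id %in% exclude_cells)
    removed["excluded"] <- sum(drop_ex)
    keep <- keep & !drop_ex
  }
  out <- subset_cells(table, which(keep))
  attr(out, "qc_removed") <- removed
  out
}

#' Read a gene panel
#'
#' Accepts a one-gene-per-line text file or a CSV with a `gene` column and
#' optional `category` column. Gene names must be unique.
#'
#' @param path panel file path.
#' @return data.frame with columns `gene`, `category`.
#' @export
read_gene_panel <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    assert_cols(df, "gene", basename(path))
    if (is.null(df$category)) df$category <- NA_character_
  } else {
    df <- data.frame(gene = readLines(path), category = NA_character_,
                     stringsAsFactors = FALSE)
    if (nrow(df) && identical(df$gene[1], "gene")) df <- df[-1, , drop = FALSE]
  }
  df <- df[nzchar(df$gene), , drop = FALSE]
  if (anyDuplicated(df$gene)) {
    stop_glom("glomscape_validation_error", "gene panel contains duplicated gene names")
  }
  rownames(df) <- NULL
  df[, c("gene", "category")]
}

#' Read a clinical covariate table
#'
#' @param path CSV with `patient_id` plus numeric covariates (`egfr`,
#'   `albuminuria`, `age`) and optionally ordinal `anca_risk`
#'   (low/medium/high).
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, "patient_id", basename(path))
  if (anyDuplicated(df$patient_id)) {
    stop_glom("glomscape_validation_error", "patient_id values must be unique")
  }
  for (col in intersect(c("egfr", "albuminuria", "age"), names(df))) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop_glom("glomscape_validation_error", "clinical covariate %s must be >= 0", col)
    }
  }
  df
}

#' Restrict a table to a gene panel
#'
#' Genes absent from the panel are dropped with a warning (panel subsetting
#' ahead of classifier training/prediction); panel genes absent from the
#' table are ignored.
#'
#' @param table a `spatial_cell_table`.
#' @param panel_genes character vector of panel gene names.
#' @return the table restricted to `intersect(colnames(counts), panel_genes)`.
#' @export
subset_to_panel <- function(table, panel_genes) {
  keep <- colnames(table$counts) %in% panel_genes
  if (!all(keep)) {
    warning(sprintf("dropping %d gene(s) absent from the panel", sum(!keep)))
  }
  table$counts <- table$counts[, keep, drop = FALSE]
  table
}
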