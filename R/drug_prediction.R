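#' Default action weights for drug scoring
#'
#' Inhibitory actions (inhibitor/antagonist) weigh 1, weaker or ambiguous
#' actions (binder/activator/agonist) weigh 0.5; any other action label
#' weighs 0 but still counts toward pathway coverage.
#'
#' @return named numeric vector.
#' @export
default_action_weights <- function() {
  c(inhibitor = 1, antagonist = 1, binder = 0.5, activator = 0.5, agonist = 0.5)
}

#' Read a drug-target-action table
#'
#' CSV with columns `drug_id`, `target_gene`, `action`. Gene names are
#' uppercased; duplicate (drug, gene) rows are deduplicated keeping the
#' highest-weight action, with a warning.
#'
#' @param path CSV path.
#' @param weight_map action weights used for deduplication.
#' @return data.frame: drug_id, target_gene, action.
#' @export
read_drug_table <- function(path, weight_map = default_action_weights()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("drug_id", "target_gene", "action"), basename(path))
  df$target_gene <- toupper(df$target_gene)
  dedup_drug_table(df, weight_map)
}

action_weight <- function(action, weight_map) {
  a <- tolower(action)
  w <- numeric(length(a))
  for (nm in names(weight_map)) {
    hit <- grepl(nm, a, fixed = TRUE)
    w[hit] <- pmax(w[hit], weight_map[[nm]])
  }
  w
}

dedup_drug_table <- function(df, weight_map = default_action_weights()) {
  key <- paste(df$drug_id, df$target_gene, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (drug, gene) rows deduplicated keeping the highest-weight action")
    w <- action_weight(df$action, weight_map)
    df <- df[order(key, -w), , drop = FALSE]
    df <- df[!duplicated(paste(df$drug_id, df$target_gene, sep = "\r")), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Pathway-coverage drug scoring and ranking
#'
#' For each drug `d` with target set `T_d` and a pathway gene set `G_p`:
#' the base score `S_b = |T_d intersect G_p| / |G_p|` measures pathway
#' coverage; the action score `S_a = sum of w(a_{d,g})` over the
#' intersection genes weighs how the drug acts on them (inhibitors and
#' antagonists 1, binders/activators/agonists 0.5, matched
#' case-insensitively as substrings); the final score is
#' `S_f = S_b * (1 + S_a / max(1, |T_d intersect G_p|))`. Drugs below
#' `min_score` are dropped; the rest are ranked by `S_f` descending with
#' ties broken by drug id.
#'
#' @param drug_table data.frame drug_id / target_gene / action.
#' @param pathway_genes the pathway gene set `G_p` (nonempty).
#' @param weight_map named action-weight vector (names matched as
#'   lowercase substrings of the action label).
#' @param min_score final-score filter threshold (default 0.1).
#' @return data.frame: drug_id, n_targets, n_overlap, s_b, s_a, s_f,
#'   ranked; only drugs with `s_f >= min_score`.
#' @export
score_drugs <- function(drug_table, pathway_genes,
                        weight_map = default_action_weights(),
                        min_score = 0.1) {
  if (!length(pathway_genes)) {
    stop_glom("glomscape_parameter_error", "pathway gene set is empty")
  }
  pathway_genes <- unique(toupper(pathway_genes))
  drug_table$target_gene <- toupper(drug_table$target_gene)
  drug_table <- dedup_drug_table(drug_table, weight_map)
  drug_table$weight <- action_weight(drug_table$action, weight_map)
  drug_table$in_path <- drug_table$target_gene %in% pathway_genes
  dt <- data.table::as.data.table(drug_table)
  res <- dt[, .(n_targets = .N,
                n_overlap = sum(in_path),
                s_a = sum(weight[in_path])), by = drug_id]
  res[, s_b := n_overlap / length(pathway_genes)]
  res[, s_f := s_b * (1 + s_a / pmax(1, n_overlap))]
  res <- res[s_f >= min_score]
  res <- res[order(-s_f, drug_id)]
  out <- as.data.frame(res[, .(drug_id, n_targets, n_overlap, s_b, s_a, s_f)])
  out$rank <- seq_len(nrow(out))
  out
}
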