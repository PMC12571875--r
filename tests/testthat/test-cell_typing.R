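test_that("normalize_log1p applies the stated transform exactly", {
  m <- matrix(c(2, 2, 0, 0, 3, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "z", "b"), c("g1", "g2")))
  out <- as.matrix(normalize_log1p(m, 1000))
  expect_equal(out["a", ], c(g1 = log(501), g2 = log(501)))
  expect_equal(out["z", ], c(g1 = 0, g2 = 0))        # all-zero cell untouched
  expect_equal(sum(expm1(out["b", ])), 1000, tolerance = 1e-6)
  expect_error(normalize_log1p(matrix(-1, 1, 1)), class = "glomscape_validation_error")
  expect_error(normalize_log1p(m, 0), class = "glomscape_parameter_error")
})

sep_reference <- function(n = 40) {
  # two types with disjoint markers, perfectly separable
  counts <- rbind(
    matrix(rep(c(10L, 10L, 0L, 0L), each = n), n),
    matrix(rep(c(0L, 0L, 10L, 10L), each = n), n))
  colnames(counts) <- c("m1", "m2", "m3", "m4")
  list(counts = counts, labels = rep(c("POD", "PT"), each = n))
}

test_that("classifier separates disjoint-marker types perfectly", {
  ref <- sep_reference()
  model <- fit_classifier(ref$counts, ref$labels, seed = 1)
  pred <- predict_cell_types(model, ref$counts)
  expect_equal(mean(pred$label == ref$labels), 1)
  probs <- attr(pred, "probabilities")
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  expect_true(all(pred$confidence[pred$label == "POD"] > 0.9))
})

test_that("classifier reaches held-out accuracy >= 0.90 on the synthetic reference", {
  cfg <- cohort_config()
  ref <- synthetic_reference(cfg, n_per_type = 200, seed = 4)
  set.seed(10)
  hold <- sample(length(ref$labels), round(0.25 * length(ref$labels)))
  model <- fit_classifier(ref$counts[-hold, ], ref$labels[-hold], seed = 4)
  pred <- predict_cell_types(model, ref$counts[hold, ])
  expect_gte(mean(pred$label == ref$labels[hold]), 0.90)
})

test_that("label-shuffled training collapses to chance accuracy", {
  cfg <- cohort_config()
  ref <- synthetic_reference(cfg, n_per_type = 60, seed = 5)
  set.seed(11)
  shuffled <- sample(ref$labels)
  hold <- sample(length(shuffled), 600)
  # shuffling can leave sparse CV folds; glmnet warns but still fits
  model <- suppressWarnings(fit_classifier(ref$counts[-hold, ], shuffled[-hold],
                                           seed = 5))
  pred <- predict_cell_types(model, ref$counts[hold, ])
  k <- length(unique(ref$labels))
  expect_lt(abs(mean(pred$label == shuffled[hold]) - 1 / k), 0.05)
})

test_that("prediction is invariant to gene order and library-size scaling", {
  ref <- sep_reference()
  model <- fit_classifier(ref$counts, ref$labels, seed = 1)
  x <- ref$counts[c(1, 50), ]
  perm <- c(3, 1, 4, 2)
  expect_equal(predict_cell_types(model, x[, perm])$label,
               predict_cell_types(model, x)$label)
  expect_equal(predict_cell_types(model, x * 7L)$label,
               predict_cell_types(model, x)$label)
})

test_that("insufficient gene overlap raises a compatibility error", {
  ref <- sep_reference()
  model <- fit_classifier(ref$counts, ref$labels, seed = 1)
  x <- matrix(1L, 2, 2, dimnames = list(NULL, c("other1", "other2")))
  err <- expect_error(predict_cell_types(model, x),
                      class = "glomscape_compatibility_error")
  expect_match(conditionMessage(err), "0.0%")
  expect_error(fit_classifier(ref$counts[1:41, ], ref$labels[1:41], seed = 1),
               class = "glomscape_training_error")
})

test_that("model JSON serialization round-trips predictions", {
  ref <- sep_reference()
  model <- fit_classifier(ref$counts, ref$labels, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_cell_type_model(model, path)
  back <- read_cell_type_model(path)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  expect_equal(predict_cell_types(back, ref$counts)$label,
               predict_cell_types(model, ref$counts)$label)
})

test_that("low-confidence cluster filtering uses a strict threshold on medians", {
  conf <- c(0.5, 0.55, 0.58, 0.9, 0.95)
  cl <- c(1, 1, 1, 2, 2)
  out <- filter_low_confidence_clusters(conf, cl, 0.6)
  expect_equal(out$mask, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.numeric(out$cluster_medians), c(0.55, 0.925))

  # medians {0.4, 0.6, 0.9}: only the 0.4 cluster is removed (strict <)
  conf <- c(0.4, 0.4, 0.6, 0.6, 0.9, 0.9)
  cl <- c("a", "a", "b", "b", "c", "c")
  out <- filter_low_confidence_clusters(conf, cl, 0.6)
  expect_equal(out$mask, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))

  # all clusters above threshold: identity mask; empty input: empty mask
  expect_true(all(filter_low_confidence_clusters(c(0.7, 0.8), c(1, 2))$mask))
  expect_length(filter_low_confidence_clusters(numeric(0), integer(0))$mask, 0)
})

test_that("fibrotic-mesangial relabeling follows the reference percentile rule", {
  labels <- rep("MC", 100)
  scores <- seq(0, 1, length.out = 100)
  glom <- rep(TRUE, 100)
  conds <- rep(c("control", "anti-GBM"), each = 50)
  out <- relabel_fibrotic_mesangial(labels, scores, glom, conds)
  thr <- quantile(scores[1:50], 0.9, names = FALSE)
  expect_equal(out$threshold, thr)
  expect_equal(out$labels == "FMC", scores > thr)
  # explicit threshold path (disease-only data)
  out2 <- relabel_fibrotic_mesangial(labels, scores, glom, threshold = 0.95)
  expect_equal(sum(out2$labels == "FMC"), sum(scores > 0.95))
  # non-mesangial and extraglomerular cells are never touched
  labels2 <- c("POD", "MC")
  out3 <- relabel_fibrotic_mesangial(labels2, c(10, 10), c(TRUE, FALSE), threshold = 1)
  expect_equal(out3$labels, labels2)
})
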