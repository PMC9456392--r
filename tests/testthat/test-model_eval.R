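test_that("metric bundle matches hand confusion-matrix arithmetic", {
  m <- evaluate_scores(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  # TP=1 FN=1 FP=1 TN=1
  expect_equal(unname(m[c("acc", "recall", "precision", "f1")]),
               c(0.5, 0.5, 0.5, 0.5))

  perfect <- evaluate_scores(c(1, 1, 0), c(0.99, 0.98, 0.01))
  expect_equal(unname(perfect), rep(1, 6))

  expect_error(evaluate_scores(c(1, 1), c(0.2, 0.3)), "both classes")
  expect_error(evaluate_scores(c(1, 0), c(0.2, 0.3, 0.1)))
})

test_that("AUCs agree with brute-force oracles on small inputs with ties", {
  set.seed(31)
  for (i in 1:120) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # heavy ties
    m <- evaluate_scores(y, s)
    expect_equal(unname(m["auc_roc"]), auc_concordance(y, s),
                 tolerance = 1e-12)
    # reversing scores reflects the ROC
    expect_equal(unname(evaluate_scores(y, -s)["auc_roc"]),
                 1 - auc_concordance(y, s), tolerance = 1e-12)
    # F1 identity where defined
    if (!is.nan(m["precision"]) && m["precision"] + m["recall"] > 0) {
      expect_equal(unname(m["f1"]),
                   unname(2 * m["precision"] * m["recall"] /
                            (m["precision"] + m["recall"])))
    }
    # average precision: direct O(n^2) recomputation at each threshold
    th <- sort(unique(s), decreasing = TRUE)
    prec <- rec <- numeric(length(th))
    for (j in seq_along(th)) {
      prec[j] <- sum(y == 1 & s >= th[j]) / sum(s >= th[j])
      rec[j] <- sum(y == 1 & s >= th[j]) / sum(y == 1)
    }
    expect_equal(unname(m["auc_pr"]), sum(diff(c(0, rec)) * prec),
                 tolerance = 1e-12)
  }
})

test_that("AUC matches an established implementation on larger data", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- sample(0:1, 300, replace = TRUE)
  s <- rnorm(300) + y
  expect_equal(unname(evaluate_scores(y, s)["auc_roc"]),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("classifier separates a planted-margin table and needs 2 classes", {
  set.seed(41)
  n <- 300
  y <- sample(0:1, n, replace = TRUE)
  x <- cbind(2 * y - 1 + rnorm(n, 0, 0.1), matrix(rnorm(n * 5), n))
  model <- train_classifier(x, y, boost_config(n_rounds = 30, seed = 1))
  sc <- strucsynergy:::predict_scores(model, x)
  expect_gte(mean((sc > 0.5) == y), 0.99)
  expect_error(train_classifier(x, rep(1, n)), "each class")
})

test_that("shuffled labels give chance-level held-out ranking", {
  tp <- tiny_pipeline()
  ftn <- tp$ft
  set.seed(55)
  ftn$y <- sample(ftn$y)
  cv <- cross_validate(ftn, folds = 5, repeats = 1,
                       cfg = boost_config(n_rounds = 40), seed = 56)
  pooled <- evaluate_scores(ftn$y, rowMeans(cv$oof))
  expect_lt(abs(pooled[["auc_roc"]] - 0.5), 0.05)
})

test_that("stratified folds partition records and preserve class balance", {
  y <- c(rep(1, 52), rep(0, 51))
  fid <- strucsynergy:::stratified_folds(y, 5, seed = 3)
  sizes <- as.vector(table(fid))
  expect_equal(sort(sizes, decreasing = TRUE), c(21, 21, 21, 20, 20))
  expect_equal(sum(sizes), 103)
  for (f in 1:5) {
    expect_true(abs(sum(y[fid == f]) - 52 / 5) <= 1)  # class ratio +/- 1
  }

  tp <- tiny_pipeline()
  cv <- cross_validate(tp$ft, folds = 5, repeats = 2,
                       cfg = boost_config(n_rounds = 30), seed = 6)
  # each record is tested exactly once per repeat
  expect_true(all(!is.na(cv$oof)))
  for (r in 1:2) {
    expect_equal(sort(unique(cv$fold_id[, r])), 1:5)
  }
  expect_equal(nrow(cv$metrics), 10)
  expect_true(all(cv$metrics$auc_roc >= 0 & cv$metrics$auc_roc <= 1))
})

test_that("planted signal beats its own permuted null on every fold", {
  tp <- tiny_pipeline()
  cfg <- boost_config(n_rounds = 40)
  cv_sig <- cross_validate(tp$ft, folds = 5, repeats = 1, cfg = cfg,
                           seed = 61)
  ftn <- tp$ft
  set.seed(62)
  ftn$y <- sample(ftn$y)
  cv_null <- cross_validate(ftn, folds = 5, repeats = 1, cfg = cfg,
                            seed = 61)
  expect_true(all(cv_sig$metrics$auc_roc > cv_null$metrics$auc_roc))
})

test_that("per-group performance reflects planted per-cell signal", {
  study <- make_synergy_study(n_drugs = 10, n_cells = 4, n_records = 600,
                              n_motifs = 4, motif_size = 6, seed = 71,
                              targets_per_drug = 4, targets_per_cell = 6,
                              cell_effect = c(2, 0, 1, 1))
  emb <- embed_network(study$network, dim = 16,
                       walk = walk_config(walks_per_node = 8,
                                          walk_length = 40, k_max = 3,
                                          seed = 72),
                       epochs = 3, seed = 73)
  ft <- suppressWarnings(
    assemble_pairs(study$records, emb, study$drug_map, study$cell_map))
  cv <- cross_validate(ft, folds = 5, repeats = 1,
                       cfg = boost_config(n_rounds = 50), seed = 74)
  per_cell <- stratified_performance(cv, by = "cell")
  expect_gt(per_cell$auc_roc[per_cell$group == "C01"],
            per_cell$auc_roc[per_cell$group == "C02"])
  per_tissue <- stratified_performance(cv, by = "tissue")
  expect_true(all(per_tissue$n_pos + per_tissue$n_neg == per_tissue$n))
  expect_error(stratified_performance(cv, by = "bogus"))
})

test_that("single-class groups are reported as undefined, not dropped", {
  tp <- tiny_pipeline()
  cv <- cross_validate(tp$ft, folds = 5, repeats = 1,
                       cfg = boost_config(n_rounds = 20), seed = 81)
  # force one cell line to a single class in the metadata view
  idx <- cv$meta$cell == cv$meta$cell[1]
  cv$y[idx] <- 1L
  out <- stratified_performance(cv, by = "cell")
  expect_true(cv$meta$cell[1] %in% out$group)
  expect_true(is.na(out$auc_roc[out$group == cv$meta$cell[1]]))
})

test_that("grid search is an exhaustive argmax with simplicity tie-breaks", {
  tp <- tiny_pipeline()
  g1 <- grid_search(tp$ft, list(max_depth = 4L, n_rounds = 20L), folds = 3,
                    seed = 91)
  expect_equal(g1$best$max_depth, 4L)
  expect_equal(nrow(g1$scores), 1)

  g2 <- grid_search(tp$ft, list(max_depth = c(2L, 7L), n_rounds = 20L),
                    folds = 3, seed = 91)
  expect_equal(nrow(g2$scores), 2)
  best_auc <- max(g2$scores$auc_roc)
  expect_equal(g2$scores$auc_roc[g2$scores$max_depth == g2$best$max_depth],
               best_auc)
  expect_error(grid_search(tp$ft, list()), "empty")
  expect_error(grid_search(tp$ft, list(nonsense = 1)), "unknown")
})

test_that("cross-validation artefacts export to CSV and JSON", {
  tp <- tiny_pipeline()
  cv <- cross_validate(tp$ft, folds = 3, repeats = 1,
                       cfg = boost_config(n_rounds = 10), seed = 95)
  dir <- withr::local_tempdir()
  write_cv_result(cv, dir)
  expect_true(file.exists(file.path(dir, "cv_metrics.csv")))
  js <- jsonlite::read_json(file.path(dir, "cv_summary.json"))
  expect_equal(js$folds, 3)
  roc <- read.csv(file.path(dir, "roc_points.csv"))
  expect_equal(max(roc$tpr), 1)
})
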