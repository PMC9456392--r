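#' Gradient-boosted tree configuration
#'
#' Defaults are the tuned booster settings for drug-combination
#' classification: `gbtree` booster, `max_depth = 7`,
#' `min_child_weight = 1`, `gamma = 0.1`, `subsample = 0.9`,
#' `colsample_bytree = 0.9`, `learning_rate = 0.1`. The number of boosting
#' rounds is not part of the tuned set; the conventional default of 100 is
#' used and is grid-searchable.
#'
#' @param max_depth,min_child_weight,gamma,subsample,colsample_bytree,learning_rate
#'   Standard XGBoost parameters.
#' @param n_rounds Number of boosting rounds (trees).
#' @param seed Seed passed to the booster (deterministic with
#'   `nthread = 1`).
#' @param nthread Training threads; 1 keeps results reproducible.
#' @return A list of class `"boost_config"`.
#' @export
boost_config <- function(max_depth = 7L, min_child_weight = 1,
                         gamma = 0.1, subsample = 0.9,
                         colsample_bytree = 0.9, learning_rate = 0.1,
                         n_rounds = 100L, seed = 1L, nthread = 1L) {
  stopifnot(max_depth >= 1, subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1,
            learning_rate > 0, n_rounds >= 1)
  structure(list(max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight, gamma = gamma,
                 subsample = subsample, colsample_bytree = colsample_bytree,
                 learning_rate = learning_rate,
                 n_rounds = as.integer(n_rounds),
                 seed = as.integer(seed), nthread = as.integer(nthread)),
            class = "boost_config")
}

#' Train the synergy classifier
#'
#' Fits a binary gradient-boosted tree model (XGBoost, logistic objective)
#' on a feature matrix of concatenated entity vectors.
#'
#' @param x Numeric feature matrix.
#' @param y Integer 0/1 labels, both classes present (at least 2 rows each).
#' @param cfg A [boost_config()].
#' @return An `xgb.Booster` predicting class-1 probability.
#' @export
train_classifier <- function(x, y, cfg = boost_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y %in% c(0, 1)))
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("training needs >= 2 rows of each class")
  }
  params <- xgboost::xgb.params(
    booster = "gbtree", objective = "binary:logistic",
    max_depth = cfg$max_depth, min_child_weight = cfg$min_child_weight,
    gamma = cfg$gamma, subsample = cfg$subsample,
    colsample_bytree = cfg$colsample_bytree, learning_rate = cfg$learning_rate,
    nthread = cfg$nthread, seed = cfg$seed)
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
                     nrounds = cfg$n_rounds, verbose = 0)
}

predict_scores <- function(model, x) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' Classification metric bundle
#'
#' Computes the six evaluation metrics at a score threshold: accuracy,
#' recall, precision, F1 (confusion-matrix arithmetic at `threshold`),
#' AUC-ROC (trapezoidal rule over the ROC curve, equivalent to the
#' concordance probability with ties counted 1/2) and AUC-PR (average
#' precision: precision integrated over recall steps).
#'
#' @param y_true Integer 0/1 labels; both classes must be present.
#' @param y_score Numeric scores, higher = more likely class 1.
#' @param threshold Classification threshold for the thresholded metrics
#'   (default 0.5).
#' @return Named numeric vector: `acc`, `recall`, `precision`, `f1`,
#'   `auc_roc`, `auc_pr`. Precision and F1 are `NaN` when no positive
#'   predictions are made.
#' @export
evaluate_scores <- function(y_true, y_score, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_score))
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y_true)) < 2L) {
    stop("both classes must be present to compute AUCs")
  }
  pred <- as.integer(y_score > threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  acc <- (tp + tn) / length(y_true)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0) NaN else tp / (tp + fp)
  f1 <- if (is.nan(precision) || precision + recall == 0) NaN else
    2 * precision * recall / (precision + recall)
  c(acc = acc, recall = recall, precision = precision, f1 = f1,
    auc_roc = auc_roc(y_true, y_score), auc_pr = auc_pr(y_true, y_score))
}

# ROC/PR points at every distinct score threshold, descending.
roc_points <- function(y_true, y_score) {
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_score[ord]
  grp <- cumsum(!duplicated(s))       # tie group per row
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  list(tp = tp[last], fp = fp[last], P = sum(y == 1), N = sum(y == 0))
}

auc_roc <- function(y_true, y_score) {
  r <- roc_points(y_true, y_score)
  tpr <- c(0, r$tp / r$P)
  fpr <- c(0, r$fp / r$N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

auc_pr <- function(y_true, y_score) {
  r <- roc_points(y_true, y_score)
  rec <- c(0, r$tp / r$P)
  prec <- r$tp / (r$tp + r$fp)
  sum(diff(rec) * prec)
}

#' Stratified cross-validation of the synergy classifier
#'
#' Repeated stratified k-fold cross-validation at the record level. Records
#' are split into folds that preserve the class ratio to within one record;
#' symmetrised duplicate orderings are created only after the split, inside
#' each training fold, so the two orderings of one record can never straddle
#' train and test. Test predictions average the forward and drug-swapped
#' orderings. Fold seeds derive from a single root seed.
#'
#' @param ft A `"feature_table"` from [assemble_pairs()].
#' @param folds Number of folds (default 5).
#' @param repeats Number of independent repetitions with fresh splits
#'   (default 5).
#' @param cfg A [boost_config()].
#' @param seed Root seed for fold assignment and training.
#' @return Object of class `"synergy_cv"`: `metrics` (one row per
#'   repeat x fold), `summary` (mean and sd per metric), `oof` (records x
#'   repeats matrix of out-of-fold scores), `fold_id` (records x repeats),
#'   `roc` (list of per-fold ROC point sets), `meta`, `y`.
#' @export
cross_validate <- function(ft, folds = 5L, repeats = 5L,
                           cfg = boost_config(), seed = 1L) {
  stopifnot(inherits(ft, "feature_table"), folds >= 2, repeats >= 1)
  n <- length(ft$y)
  oof <- matrix(NA_real_, n, repeats)
  fold_id <- matrix(NA_integer_, n, repeats)
  rows <- list()
  rocs <- list()
  for (r in seq_len(repeats)) {
    fid <- stratified_folds(ft$y, folds, derive_seed(seed, 21L, r))
    fold_id[, r] <- fid
    for (f in seq_len(folds)) {
      te <- which(fid == f)
      tr <- which(fid != f)
      train <- training_matrix(ft, tr)
      cfg_f <- cfg
      cfg_f$seed <- derive_seed(seed, 22L, r, f)
      model <- train_classifier(train$x, train$y, cfg_f)
      sc <- (predict_scores(model, ft$x[te, , drop = FALSE]) +
               predict_scores(model, ft$x_rev[te, , drop = FALSE])) / 2
      oof[te, r] <- sc
      m <- evaluate_scores(ft$y[te], sc)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = r, fold = f, t(m))
      rocs[[length(rocs) + 1L]] <- roc_points(ft$y[te], sc)
    }
  }
  metrics <- do.call(rbind, rows)
  mcols <- c("acc", "recall", "precision", "f1", "auc_roc", "auc_pr")
  summ <- data.frame(metric = mcols,
                     mean = vapply(metrics[mcols], mean, numeric(1)),
                     sd = vapply(metrics[mcols], sd, numeric(1)),
                     row.names = NULL)
  structure(list(metrics = metrics, summary = summ, oof = oof,
                 fold_id = fold_id, roc = rocs, meta = ft$meta, y = ft$y,
                 folds = folds, repeats = repeats, seed = seed),
            class = "synergy_cv")
}

# Stratified fold ids: within each class, shuffle then deal round-robin,
# rotating the starting fold so fold sizes differ by at most one overall.
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fid <- integer(length(y))
  offset <- 0L
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fid[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
    offset <- offset + length(idx)
  }
  fid
}

#' @export
print.synergy_cv <- function(x, ...) {
  cat("Cross-validation:", x$folds, "folds x", x$repeats, "repeat(s),",
      length(x$y), "records\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @export
summary.synergy_cv <- function(object, ...) object$summary

#' Per-cell-line or per-tissue ranking performance
#'
#' Groups records by cell line or tissue and reports the ROC-AUC of the
#' pooled out-of-fold scores (averaged over repeats) within each group.
#' Groups containing a single class have no defined AUC and are reported as
#' `NA` rather than dropped.
#'
#' @param cv A `"synergy_cv"` result.
#' @param by Grouping key: `"cell"` or `"tissue"`.
#' @return Data frame: group, number of records, positives, negatives,
#'   `auc_roc` (`NA` when undefined).
#' @export
stratified_performance <- function(cv, by = c("cell", "tissue")) {
  by <- match.arg(by)
  key <- cv$meta[[by]]
  if (all(is.na(key))) stop("no ", by, " metadata available")
  score <- rowMeans(cv$oof)
  out <- lapply(split(seq_along(score), key), function(idx) {
    pos <- sum(cv$y[idx] == 1)
    neg <- sum(cv$y[idx] == 0)
    data.frame(n = length(idx), n_pos = pos, n_neg = neg,
               auc_roc = if (pos == 0 || neg == 0) NA_real_ else
                 auc_roc(cv$y[idx], score[idx]))
  })
  res <- do.call(rbind, out)
  res <- cbind(group = rownames(res), res)
  rownames(res) <- NULL
  res
}

#' Exhaustive grid search over booster parameters
#'
#' Evaluates every parameter combination by cross-validated mean AUC-ROC.
#' Ties are broken toward the simpler model: smaller `max_depth`, then lower
#' `learning_rate`.
#'
#' @param ft A `"feature_table"`.
#' @param grid Named list of parameter vectors (fields of [boost_config()]);
#'   expanded by [expand.grid()].
#' @param folds CV folds per combination (default 5).
#' @param repeats CV repeats per combination (default 1).
#' @param seed Root seed shared by all combinations.
#' @return List: `best` (a [boost_config()]), `scores` (one row per
#'   combination with its mean AUC-ROC).
#' @export
grid_search <- function(ft, grid, folds = 5L, repeats = 1L, seed = 1L) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("empty parameter grid")
  }
  bad <- setdiff(names(grid), names(formals(boost_config)))
  if (length(bad)) stop("unknown grid parameter(s): ",
                        paste(bad, collapse = ", "))
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$auc_roc <- NA_real_
  cfgs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cfg <- do.call(boost_config,
                   c(as.list(tab[i, setdiff(names(tab), "auc_roc"),
                                 drop = FALSE]), list(seed = seed)))
    cfgs[[i]] <- cfg
    cv <- cross_validate(ft, folds = folds, repeats = repeats, cfg = cfg,
                         seed = seed)
    tab$auc_roc[i] <- cv$summary$mean[cv$summary$metric == "auc_roc"]
  }
  zero <- rep(0, nrow(tab))
  ord <- order(-tab$auc_roc,
               if (!is.null(tab$max_depth)) tab$max_depth else zero,
               if (!is.null(tab$learning_rate)) tab$learning_rate else zero)
  list(best = cfgs[[ord[1]]], scores = tab)
}

#' Export a cross-validation result
#'
#' Writes the per-fold metric table as CSV, the summary as JSON, and the
#' per-fold ROC points as CSV (for curve plotting).
#'
#' @param cv A `"synergy_cv"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cv_result <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cv$metrics, file.path(dir, "cv_metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(folds = cv$folds, repeats = cv$repeats,
         summary = cv$summary),
    file.path(dir, "cv_summary.json"), auto_unbox = TRUE, digits = NA)
  roc_df <- do.call(rbind, lapply(seq_along(cv$roc), function(i) {
    r <- cv$roc[[i]]
    data.frame(curve = i, fpr = c(0, r$fp / r$N), tpr = c(0, r$tp / r$P))
  }))
  write.csv(roc_df, file.path(dir, "roc_points.csv"), row.names = FALSE)
  invisible(dir)
}
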