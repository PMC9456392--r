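#' Fit the full structural-embedding synergy model
#'
#' End-to-end fit: embed the PPI network by structural identity
#' ([embed_network()]), mean-pool protein vectors into drug and cell-line
#' features ([entity_feature()]), concatenate them per record
#' ([assemble_pairs()]) and train a gradient-boosted tree classifier
#' ([train_classifier()]). The fitted object predicts the probability that a
#' drug pair is synergistic in a cell line.
#'
#' @param records Synergy records ([read_synergy()] /
#'   [make_synergy_records()]).
#' @param network PPI network (`igraph`, e.g. from [read_edge_list()]).
#' @param drug_map,cell_map Association maps ([read_associations()]).
#' @param dim Embedding dimension (default 64; features are `3 * dim` wide).
#' @param walk [walk_config()] for the random-walk corpus.
#' @param window,epochs,negative Skip-Gram settings ([train_skipgram()]).
#' @param boost [boost_config()] for the classifier.
#' @param symmetrize Train on both drug orderings (default `TRUE`).
#' @param seed Root seed for all stages.
#' @return Object of class `"synergy_fit"` with components `embedding`,
#'   `model`, `features` (the training `"feature_table"`), configs and the
#'   call. Methods: [print()], [summary()], [predict()].
#' @examples
#' study <- make_synergy_study(n_drugs = 6, n_cells = 2, n_records = 120,
#'                             n_motifs = 3, motif_size = 5, seed = 1)
#' fit <- synergy_fit(study$records, study$network, study$drug_map,
#'                    study$cell_map, dim = 16,
#'                    walk = walk_config(walks_per_node = 5, walk_length = 20),
#'                    boost = boost_config(n_rounds = 10), seed = 1)
#' predict(fit, study$records[1:3, ])
#' @export
synergy_fit <- function(records, network, drug_map, cell_map, dim = 64L,
                        walk = walk_config(), window = 5L, epochs = 5L,
                        negative = 5L, boost = boost_config(),
                        symmetrize = TRUE, seed = 1L) {
  walk$seed <- derive_seed(seed, 1L)
  emb <- embed_network(network, dim = dim, walk = walk, window = window,
                       epochs = epochs, negative = negative,
                       seed = derive_seed(seed, 2L))
  ft <- assemble_pairs(records, emb, drug_map, cell_map,
                       symmetrize = symmetrize)
  boost$seed <- derive_seed(seed, 3L)
  train <- training_matrix(ft)
  model <- train_classifier(train$x, train$y, boost)
  structure(list(embedding = emb, model = model, features = ft,
                 drug_map = drug_map, cell_map = cell_map,
                 dim = as.integer(dim), walk = walk, boost = boost,
                 seed = as.integer(seed), call = match.call()),
            class = "synergy_fit")
}

#' Predict synergy probabilities for drug-drug-cell-line triples
#'
#' @param object A `"synergy_fit"`.
#' @param newdata Data frame with columns `drug_a`, `drug_b`, `cell`; all
#'   entities must have been featurisable at fit time.
#' @param type `"prob"` (class-1 probability, default) or `"label"`
#'   (0/1 at threshold 0.5).
#' @param ... Unused.
#' @return Numeric vector of probabilities (average of the two drug
#'   orderings) or integer labels.
#' @export
predict.synergy_fit <- function(object, newdata, type = c("prob", "label"),
                                ...) {
  type <- match.arg(type)
  need <- c("drug_a", "drug_b", "cell")
  stopifnot(all(need %in% names(newdata)))
  feat <- function(map, id) {
    if (!id %in% names(map)) stop("unknown entity: ", id)
    entity_feature(object$embedding, map[[id]])
  }
  d <- object$dim
  score <- vapply(seq_len(nrow(newdata)), function(i) {
    fa <- feat(object$drug_map, newdata$drug_a[i])
    fb <- feat(object$drug_map, newdata$drug_b[i])
    fc <- feat(object$cell_map, newdata$cell[i])
    x <- rbind(c(fa, fb, fc), c(fb, fa, fc))
    colnames(x) <- sprintf("f%03d", seq_len(3L * d) - 1L)
    mean(predict_scores(object$model, x))
  }, numeric(1))
  if (type == "label") as.integer(score > 0.5) else score
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat("Structural-embedding synergy model\n")
  cat("  embedding:", nrow(x$embedding), "proteins x", x$dim,
      "dimensions\n")
  cat("  features :", nrow(x$features$x), "records x",
      ncol(x$features$x), "\n")
  cat("  booster  :", x$boost$n_rounds, "trees, depth",
      x$boost$max_depth, "\n")
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  train <- training_matrix(object$features)
  m <- evaluate_scores(train$y, predict_scores(object$model, train$x))
  out <- list(n_records = length(object$features$y),
              n_proteins = nrow(object$embedding), dim = object$dim,
              n_dropped = object$features$n_dropped,
              training_metrics = m)
  class(out) <- "summary.synergy_fit"
  out
}

#' @export
print.summary.synergy_fit <- function(x, ...) {
  cat("Synergy model summary\n")
  cat("  records:", x$n_records, "( dropped:", x$n_dropped, ")\n")
  cat("  proteins embedded:", x$n_proteins, "at dim", x$dim, "\n")
  cat("  apparent (training) metrics:\n")
  for (nm in names(x$training_metrics)) {
    cat(sprintf("    %-9s %.3f\n", nm, x$training_metrics[[nm]]))
  }
  invisible(x)
}
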