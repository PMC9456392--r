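#' Mean-pooled feature vector of a drug or cell line
#'
#' An entity acting on target proteins `P_1, ..., P_n` is represented by the
#' element-wise arithmetic mean of its targets' embedding vectors,
#' `(P_1 + ... + P_n) / n`. The result is permutation-invariant in the target
#' set and lies coordinate-wise between the targets' minima and maxima.
#'
#' @param emb Embedding matrix (rownames = protein ids).
#' @param targets Non-empty character vector of target proteins, all present
#'   in `emb`.
#' @return Numeric vector of length `ncol(emb)`.
#' @export
entity_feature <- function(emb, targets) {
  targets <- unique(targets)
  if (length(targets) == 0L) stop("empty target set cannot be featurised")
  miss <- setdiff(targets, rownames(emb))
  if (length(miss)) {
    stop("target protein(s) missing from embedding: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  colMeans(emb[targets, , drop = FALSE])
}

#' Assemble the labelled feature table for drug-drug-cell-line records
#'
#' Each record becomes the concatenation
#' `[feat(drug_a), feat(drug_b), feat(cell)]` of three mean-pooled entity
#' vectors (width `3 * d`; 192 for 64-dimensional embeddings). Records
#' involving a drug or cell line without features are dropped and counted.
#' Because concatenation is order-sensitive while synergy is not, the table
#' keeps both orderings of every record: the forward rows in `$x` and the
#' drug-swapped rows in `$x_rev`. With `symmetrize = TRUE` (default) training
#' uses both orderings and prediction averages them.
#'
#' Duplicate (drug_a, drug_b, cell) triples with conflicting labels are kept
#' (with a warning): they are genuine replicate measurements that disagree.
#'
#' @param records Synergy records (see [read_synergy()]).
#' @param emb Embedding matrix.
#' @param drug_map,cell_map Association maps (see [read_associations()]).
#' @param symmetrize Logical; train on both drug orderings (default `TRUE`).
#' @return Object of class `"feature_table"`: `x`, `x_rev` (numeric matrices
#'   with columns `f000...`), `y` (integer labels), `meta` (record metadata
#'   data frame incl. `tissue` when available), `d`, `symmetrize`,
#'   `n_dropped`.
#' @export
assemble_pairs <- function(records, emb, drug_map, cell_map,
                           symmetrize = TRUE) {
  stopifnot(is.matrix(emb))
  d <- ncol(emb)
  featurizable <- function(map) {
    names(map)[vapply(map, function(p) all(p %in% rownames(emb)), logical(1))]
  }
  ok_drug <- featurizable(drug_map)
  ok_cell <- featurizable(cell_map)
  keep <- records$drug_a %in% ok_drug & records$drug_b %in% ok_drug &
    records$cell %in% ok_cell
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(n_dropped, " record(s) dropped: entity without features")
  }
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no featurisable records")

  dup <- duplicated(rec[, c("drug_a", "drug_b", "cell")]) |
    duplicated(rec[, c("drug_a", "drug_b", "cell")], fromLast = TRUE)
  if (any(dup)) {
    conf <- stats::ave(rec$label, rec$drug_a, rec$drug_b, rec$cell,
                       FUN = function(l) length(unique(l)) > 1)
    if (any(conf == 1)) {
      warning(sum(conf == 1), " duplicated triple record(s) carry ",
              "conflicting labels; all kept")
    }
  }

  dmat <- t(vapply(drug_map[ok_drug], function(p) entity_feature(emb, p),
                   numeric(d)))
  cmat <- t(vapply(cell_map[ok_cell], function(p) entity_feature(emb, p),
                   numeric(d)))
  ia <- match(rec$drug_a, rownames(dmat))
  ib <- match(rec$drug_b, rownames(dmat))
  ic <- match(rec$cell, rownames(cmat))
  x <- cbind(dmat[ia, , drop = FALSE], dmat[ib, , drop = FALSE],
             cmat[ic, , drop = FALSE])
  x_rev <- cbind(dmat[ib, , drop = FALSE], dmat[ia, , drop = FALSE],
                 cmat[ic, , drop = FALSE])
  cn <- sprintf("f%03d", seq_len(3L * d) - 1L)
  dimnames(x) <- list(NULL, cn)
  dimnames(x_rev) <- list(NULL, cn)

  tissue <- attr(cell_map, "tissue")
  meta <- data.frame(drug_a = rec$drug_a, drug_b = rec$drug_b,
                     cell = rec$cell, score = rec$score,
                     tissue = if (is.null(tissue)) NA_character_
                              else unname(tissue[rec$cell]),
                     stringsAsFactors = FALSE)
  structure(list(x = x, x_rev = x_rev, y = rec$label, meta = meta, d = d,
                 symmetrize = isTRUE(symmetrize), n_dropped = n_dropped),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$x), "records x", ncol(x$x),
      "features (3 x d =", 3 * x$d, "),",
      sum(x$y == 1), "positive /", sum(x$y == 0), "negative\n")
  if (x$n_dropped) cat("  (", x$n_dropped, "record(s) dropped )\n")
  invisible(x)
}

# Training design matrix for a subset of records: both orderings when the
# table is symmetrised, forward rows otherwise.
training_matrix <- function(ft, idx = seq_along(ft$y)) {
  if (ft$symmetrize) {
    list(x = rbind(ft$x[idx, , drop = FALSE], ft$x_rev[idx, , drop = FALSE]),
         y = c(ft$y[idx], ft$y[idx]))
  } else {
    list(x = ft$x[idx, , drop = FALSE], y = ft$y[idx])
  }
}

#' Export a feature table as CSV
#'
#' Metadata columns, feature columns `f000...`, then the label. Only the
#' forward ordering of each record is written.
#'
#' @param ft A `"feature_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- cbind(ft$meta, as.data.frame(ft$x), label = ft$y)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
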