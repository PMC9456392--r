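#' Train Skip-Gram node embeddings over a walk corpus
#'
#' Treats each walk as a sentence and trains Skip-Gram with negative sampling
#' (5 negatives by default), the standard word2vec objective: predict context
#' tokens within a (dynamically shrunk) window around each centre token.
#' Every node that appears in the corpus receives a vector — there is no
#' minimum-count filtering, since a protein without a vector could not be
#' featurised downstream.
#'
#' Training is single-threaded with a private seeded RNG, so the same corpus,
#' parameters and seed reproduce the embedding matrix bit-identically.
#'
#' @param corpus Walk corpus: list of character vectors
#'   (see [generate_walks()]), or a path readable by [readLines()] with one
#'   space-separated walk per line.
#' @param dim Embedding dimension (commonly 32, 64 or 128; default 64).
#' @param window Context window half-width (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha,min_alpha Initial and floor learning rate.
#' @param seed Integer RNG seed.
#' @return Numeric matrix, one row per vocabulary node (rownames = node ids,
#'   sorted), `dim` columns; all entries finite.
#' @export
train_skipgram <- function(corpus, dim = 64L, window = 5L, epochs = 5L,
                           negative = 5L, alpha = 0.025, min_alpha = 1e-4,
                           seed = 1L) {
  if (is.character(corpus) && length(corpus) == 1L && file.exists(corpus)) {
    corpus <- strsplit(readLines(corpus, warn = FALSE), " ", fixed = TRUE)
  }
  stopifnot(is.list(corpus), dim >= 2, window >= 1, epochs >= 1,
            negative >= 1)
  corpus <- corpus[lengths(corpus) > 0L]
  if (length(corpus) == 0L) stop("empty walk corpus")
  tokens <- unlist(corpus, use.names = FALSE)
  vocab <- sort(unique(tokens))
  counts <- as.numeric(table(factor(tokens, levels = vocab)))
  walks_int <- lapply(corpus, function(w) {
    match(w, vocab) - 1L
  })
  emb <- .sgns_train_cpp(walks_int, length(vocab), as.integer(dim),
                         as.integer(window), as.integer(epochs),
                         as.integer(negative), alpha, min_alpha, counts,
                         as.integer(seed))
  rownames(emb) <- vocab
  stopifnot(all(is.finite(emb)))
  emb
}

#' Embed a PPI network by structural identity
#'
#' Convenience chain: [structural_distances()] ->
#' [build_multilayer_graph()] -> [generate_walks()] -> [train_skipgram()].
#' Nodes with similar local topology (degree-ring profiles), however far
#' apart in the network, end up close in the embedding space.
#'
#' @param g PPI network (`igraph`).
#' @param dim Embedding dimension (default 64).
#' @param walk A [walk_config()].
#' @param window,epochs,negative Skip-Gram settings, see [train_skipgram()].
#' @param seed Root seed; walk and Skip-Gram seeds are derived from it
#'   (a seed inside `walk` takes precedence for the walks).
#' @return Embedding matrix (nodes x `dim`).
#' @export
embed_network <- function(g, dim = 64L, walk = walk_config(),
                          window = 5L, epochs = 5L, negative = 5L,
                          seed = 1L) {
  walk$seed <- if (missing(walk)) derive_seed(seed, 11L) else walk$seed
  sd_tab <- structural_distances(g, walk$k_max)
  mlg <- build_multilayer_graph(sd_tab)
  corpus <- generate_walks(mlg, walk)
  train_skipgram(corpus, dim = dim, window = window, epochs = epochs,
                 negative = negative, seed = derive_seed(seed, 12L))
}
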