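# Independent oracles and shared fixtures for the test suite.

# Brute-force DTW: explore every monotone warping path from (1,1) to (n,m)
# by recursion, taking the minimum summed element cost. Exponential, so only
# for short sequences; deliberately independent of the package's DP kernel.
dtw_brute <- function(a, b) {
  g <- function(x, y) max(x, y) / min(x, y) - 1
  rec <- function(i, j) {
    c0 <- g(a[i], b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(length(a), length(b))
}

# Brute-force concordance AUC: probability that a random positive outranks a
# random negative, ties counted one half.
auc_concordance <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two triangles joined by one edge; (a1,b1), (a2,b2), (a3,b3) are mirror
# (automorphic) pairs.
barbell_graph <- function() {
  igraph::graph_from_edgelist(rbind(
    c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
    c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),
    c("a1", "b1")), directed = FALSE)
}

star_graph <- function(n_leaves = 4) {
  igraph::graph_from_edgelist(
    cbind("c", paste0("l", seq_len(n_leaves))), directed = FALSE)
}

# A random connected graph doubled, with bridges only between corresponding
# node pairs, so that swapping the two copies is a graph automorphism.
doubled_random_graph <- function(n_half, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n_half, p)
    if (igraph::is_connected(g)) break
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  name <- function(copy, i) sprintf("c%d_n%d", copy, i)
  bridges <- sample.int(n_half, 2)
  edges <- rbind(cbind(name(1, el[, 1]), name(1, el[, 2])),
                 cbind(name(2, el[, 1]), name(2, el[, 2])),
                 cbind(name(1, bridges), name(2, bridges)))
  list(graph = igraph::graph_from_edgelist(edges, directed = FALSE),
       sigma = function(nm) ifelse(grepl("^c1_", nm),
                                   sub("^c1_", "c2_", nm),
                                   sub("^c2_", "c1_", nm)))
}

# Small fast study + embedding + feature table, memoised across test files.
.fixture_cache <- new.env(parent = emptyenv())

tiny_pipeline <- function() {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  study <- make_synergy_study(n_drugs = 10, n_cells = 4, n_records = 500,
                              n_motifs = 4, motif_size = 6, seed = 2,
                              targets_per_drug = 4, targets_per_cell = 6)
  emb <- embed_network(study$network, dim = 16,
                       walk = walk_config(walks_per_node = 8,
                                          walk_length = 40, k_max = 3,
                                          seed = 3),
                       epochs = 3, seed = 4)
  ft <- suppressWarnings(
    assemble_pairs(study$records, emb, study$drug_map, study$cell_map))
  .fixture_cache$tiny <- list(study = study, emb = emb, ft = ft)
  .fixture_cache$tiny
}
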