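#' Ordered degree sequence of a node's k-hop ring
#'
#' The structural fingerprint of node `u` at hop distance `k` is the sorted
#' (ascending) list of degrees of the nodes at exactly `k` hops from `u`.
#' At `k = 0` this is the node's own degree; beyond the node's eccentricity
#' the ring is empty.
#'
#' @param g PPI network (`igraph`, named vertices).
#' @param u Node identifier.
#' @param k Hop distance, non-negative integer.
#' @return Integer vector of sorted degrees (possibly length zero).
#' @export
ring_degree_sequence <- function(g, u, k) {
  stopifnot(k >= 0)
  if (!u %in% igraph::V(g)$name) stop("unknown node: ", u)
  d <- as.vector(igraph::distances(g, v = u))
  ring <- which(d == k)
  sort(as.integer(igraph::degree(g)[ring]))
}

#' Dynamic-time-warping distance between two ordered degree sequences
#'
#' Minimal-cost monotone alignment between two ascending degree sequences
#' under the element cost `g(x, y) = max(x, y) / min(x, y) - 1`, which is 0
#' iff the degrees are equal and penalises ratios, not differences (degree 1
#' vs 2 counts as much as 10 vs 20). The full dynamic program is used, with
#' no warping window: after sorting, sequences here are short.
#'
#' @param a,b Numeric vectors of degrees, all entries >= 1, non-empty.
#' @return Non-negative alignment cost; 0 iff `a` and `b` are identical.
#' @export
dtw_degree_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("degree sequences must be non-empty")
  }
  if (any(a < 1) || any(b < 1)) stop("degrees must be >= 1")
  .dtw_cost_cpp(as.numeric(a), as.numeric(b))
}

#' Layered structural distances between all node pairs
#'
#' Computes the cumulative structural distance
#' `f_k(u, v) = f_{k-1}(u, v) + DTW(s_k(u), s_k(v))` for every node pair and
#' every layer `k = 0, ..., k_max`, where `s_k(u)` is the ordered degree
#' sequence of the k-hop ring of `u` (see [ring_degree_sequence()]) and the
#' base case is `f_{-1} = 0`. A pair is present at layer `k` only while both
#' rings are non-empty; once a node's ring empties (k beyond its
#' eccentricity) the pair drops out of all higher layers. `f_k` is symmetric,
#' non-negative and non-decreasing in `k`, and is identically 0 along any
#' graph automorphism orbit.
#'
#' @param g PPI network (`igraph`, named vertices).
#' @param k_max Maximum layer index; capped at the graph diameter.
#' @return Object of class `"struct_dist"`: list with `nodes`, `k_max`
#'   (effective) and `f`, a list of symmetric matrices (layer k at index
#'   `k + 1`; `NA` marks pairs absent from a layer).
#' @export
structural_distances <- function(g, k_max) {
  stopifnot(k_max >= 0)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- nodes
  }
  n <- length(nodes)
  if (n < 2L) stop("need at least 2 nodes to compare structure")
  D <- igraph::distances(g)
  deg <- as.integer(igraph::degree(g))
  k_eff <- min(k_max, max(D[is.finite(D)]))
  f <- vector("list", k_eff + 1L)
  prev <- matrix(0, n, n)
  for (k in 0:k_eff) {
    rings <- lapply(seq_len(n), function(i) {
      as.numeric(sort(deg[which(D[i, ] == k)]))
    })
    gk <- .dtw_pair_matrix_cpp(rings)
    fk <- prev + gk
    dimnames(fk) <- list(nodes, nodes)
    diag(fk) <- NA_real_
    f[[k + 1L]] <- fk
    prev <- fk
    if (all(is.na(fk[upper.tri(fk)]))) {
      f <- f[seq_len(k + 1L)]
      k_eff <- k
      break
    }
  }
  structure(list(nodes = nodes, k_max = k_eff, f = f),
            class = "struct_dist")
}

#' @export
print.struct_dist <- function(x, ...) {
  cat("Structural distance table:", length(x$nodes), "nodes,",
      x$k_max + 1, "layers (k = 0..", x$k_max, ")\n", sep = " ")
  invisible(x)
}

#' Build the multilayer similarity graph from structural distances
#'
#' Each layer `k` is a complete weighted graph over the node pairs retained
#' at that layer, with intra-layer weight `w_k(u, v) = exp(-f_k(u, v))`
#' (so weight 1 iff the structural distance is 0). Consecutive layers are
#' connected per node: the upward edge weight is `log(Gamma_k(u) + e)`,
#' where `Gamma_k(u)` counts intra-layer edges at `u` whose weight exceeds
#' that layer's mean edge weight (so structurally "popular" nodes are pushed
#' up to coarser layers), and the downward weight is 1.
#'
#' @param dist A `"struct_dist"` table from [structural_distances()].
#' @return Object of class `"multilayer_graph"`: per-layer weight matrices
#'   `W`, per-node normalisers `Z` (row sums over partners), upward weights
#'   `up`, per-node top layer, and cached within-layer transition tables.
#' @export
build_multilayer_graph <- function(dist) {
  stopifnot(inherits(dist, "struct_dist"))
  nodes <- dist$nodes
  n <- length(nodes)
  nk <- dist$k_max + 1L
  W <- vector("list", nk)
  Z <- matrix(NA_real_, n, nk, dimnames = list(nodes, NULL))
  up <- matrix(NA_real_, n, nk, dimnames = list(nodes, NULL))
  trans <- vector("list", nk)
  present <- matrix(FALSE, n, nk, dimnames = list(nodes, NULL))
  for (k in seq_len(nk)) {
    wk <- exp(-dist$f[[k]])
    W[[k]] <- wk
    ut <- wk[upper.tri(wk)]
    mean_w <- mean(ut, na.rm = TRUE)
    gamma <- rowSums(wk > mean_w, na.rm = TRUE)
    up[, k] <- log(gamma + exp(1))
    z <- rowSums(wk, na.rm = TRUE)
    npart <- rowSums(!is.na(wk))
    present[, k] <- npart > 0
    Z[, k] <- ifelse(npart > 0, z, NA_real_)
    trans[[k]] <- lapply(seq_len(n), function(i) {
      idx <- which(!is.na(wk[i, ]))
      if (!length(idx)) return(NULL)
      p <- wk[i, idx] / z[i]
      list(targets = unname(idx), cum = unname(cumsum(p)))
    })
  }
  top <- apply(present, 1, function(p) max(which(p)) - 1L)
  structure(list(nodes = nodes, k_max = dist$k_max, W = W, Z = Z, up = up,
                 present = present, top_layer = top, trans = trans),
            class = "multilayer_graph")
}

#' @export
print.multilayer_graph <- function(x, ...) {
  cat("Multilayer similarity graph:", length(x$nodes), "nodes,",
      x$k_max + 1, "layers\n")
  invisible(x)
}

#' Layer-switch probabilities for a node
#'
#' With probability `1 - q` a walker changes layer; it moves up with
#' probability proportional to `log(Gamma_k(u) + e)` and down with
#' probability proportional to 1. Layer 0 forces an upward move and a node's
#' top layer forces a downward move.
#'
#' @param mlg A `"multilayer_graph"`.
#' @param u Node id.
#' @param k Current layer (0-based).
#' @return Named numeric vector `c(up = , down = )` summing to 1.
#' @export
layer_switch_probs <- function(mlg, u, k) {
  i <- match(u, mlg$nodes)
  if (is.na(i)) stop("unknown node: ", u)
  top <- mlg$top_layer[i]
  can_up <- k < top
  can_down <- k > 0
  if (!can_up && !can_down) return(c(up = 0, down = 0))
  if (!can_up) return(c(up = 0, down = 1))
  if (!can_down) return(c(up = 1, down = 0))
  wu <- unname(mlg$up[i, k + 1L])
  c(up = wu / (wu + 1), down = 1 / (wu + 1))
}

#' Walk-sampling configuration
#'
#' Defaults follow the embedding settings used throughout: 20 walks per node
#' of 80 emitted tokens each over a 4-layer (plus layer 0) similarity graph.
#' The stay probability `q` (probability of moving within the current layer
#' rather than switching layers) is a free parameter of the walk; 0.3 is the
#' customary structural-embedding default.
#'
#' @param walks_per_node Walks started from every node (default 20).
#' @param walk_length Number of emitted node tokens per walk (default 80).
#' @param k_max Highest layer index of the multilayer graph (default 4).
#' @param stay_prob Probability `q` in (0, 1) of a within-layer move
#'   (default 0.3).
#' @param seed Integer seed for the walk RNG.
#' @return A list of class `"walk_config"`.
#' @export
walk_config <- function(walks_per_node = 20L, walk_length = 80L, k_max = 4L,
                        stay_prob = 0.3, seed = 1L) {
  stopifnot(walks_per_node >= 1, walk_length >= 1, k_max >= 0,
            stay_prob > 0, stay_prob < 1)
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 k_max = as.integer(k_max),
                 stay_prob = stay_prob, seed = as.integer(seed)),
            class = "walk_config")
}

# One biased walk over the multilayer graph, as vertex indices.
# The start node is emitted once; a within-layer move emits the node it
# lands on; a layer switch consumes an iteration but emits nothing.
walk_once <- function(mlg, start_idx, walk_length, q) {
  out <- integer(walk_length)
  out[1L] <- start_idx
  cur <- start_idx
  k <- 0L
  emitted <- 1L
  while (emitted < walk_length) {
    tr <- mlg$trans[[k + 1L]][[cur]]
    if (!is.null(tr) && runif(1) < q) {
      r <- runif(1)
      cur <- tr$targets[findInterval(r, tr$cum) + 1L]
      emitted <- emitted + 1L
      out[emitted] <- cur
    } else {
      # also reached when the node has no same-layer partner (tr NULL):
      # layer_switch_probs then forces the only legal direction
      p <- layer_switch_probs(mlg, mlg$nodes[cur], k)
      if (p[["up"]] > 0 && runif(1) < p[["up"]]) k <- k + 1L
      else if (p[["down"]] > 0) k <- k - 1L
      # isolated-in-every-layer node: stay at layer 0, next loop retries
    }
  }
  out
}

#' Generate the biased random-walk corpus
#'
#' Starts `walks_per_node` walks from every node. A walk lives on the
#' multilayer graph: it begins at layer 0 at its start node; at each step it
#' moves within the current layer with probability `q` (landing on `v` with
#' probability `exp(-f_k(u, v)) / Z_k(u)` and emitting `v`) and otherwise
#' switches layer (see [layer_switch_probs()]) without emitting. A walk ends
#' after `walk_length` emitted tokens.
#'
#' Node order is reshuffled on every pass over the nodes, and each walk uses
#' a private RNG substream derived from `(seed, pass, node)`, so the corpus
#' is reproducible and stable under any execution order.
#'
#' @param mlg A `"multilayer_graph"` from [build_multilayer_graph()].
#' @param cfg A [walk_config()].
#' @return List of character vectors (node-id sequences) of length
#'   `walks_per_node * n_nodes`, class `"walk_corpus"`.
#' @export
generate_walks <- function(mlg, cfg = walk_config()) {
  stopifnot(inherits(mlg, "multilayer_graph"), inherits(cfg, "walk_config"))
  n <- length(mlg$nodes)
  corpus <- vector("list", cfg$walks_per_node * n)
  pos <- 0L
  for (ep in seq_len(cfg$walks_per_node)) {
    set.seed(derive_seed(cfg$seed, ep, 0L))
    order_ep <- sample.int(n)
    for (v in order_ep) {
      set.seed(derive_seed(cfg$seed, ep, v))
      pos <- pos + 1L
      corpus[[pos]] <- mlg$nodes[walk_once(mlg, v, cfg$walk_length,
                                           cfg$stay_prob)]
    }
  }
  structure(corpus, class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("Walk corpus:", length(x), "walks, max emitted length",
      max(lengths(x)), "\n")
  invisible(x)
}

#' Write a walk corpus as plain text
#'
#' One walk per line, node ids separated by spaces.
#' @param corpus A `"walk_corpus"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_walks <- function(corpus, path) {
  writeLines(vapply(corpus, paste, character(1), collapse = " "), path)
  invisible(path)
}
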