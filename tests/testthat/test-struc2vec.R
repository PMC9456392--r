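test_that("ring degree sequences match hand-computed BFS rings", {
  star <- star_graph(4)
  expect_equal(ring_degree_sequence(star, "c", 0), 4L)
  expect_equal(ring_degree_sequence(star, "l1", 1), 4L)
  expect_equal(ring_degree_sequence(star, "l1", 2), c(1L, 1L, 1L))
  expect_length(ring_degree_sequence(star, "l1", 3), 0)  # beyond eccentricity

  path <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C")),
                                      directed = FALSE)
  expect_equal(ring_degree_sequence(path, "A", 2), 1L)
  expect_error(ring_degree_sequence(path, "Z", 0), "unknown node")
})

test_that("DTW distance has the right base cases and domain checks", {
  expect_equal(dtw_degree_distance(c(3, 3), c(3, 3)), 0)
  expect_equal(dtw_degree_distance(1, 2), 1)          # 2/1 - 1
  expect_equal(dtw_degree_distance(c(1, 2, 3), c(2, 2)), 1.5)
  expect_error(dtw_degree_distance(numeric(0), 1), "non-empty")
  expect_error(dtw_degree_distance(c(1, 0), 1), ">= 1")
})

test_that("DTW equals the brute-force warping-path oracle", {
  set.seed(42)
  for (i in 1:200) {
    a <- sample(1:6, sample(1:5, 1), replace = TRUE)
    b <- sample(1:6, sample(1:5, 1), replace = TRUE)
    expect_equal(dtw_degree_distance(a, b), dtw_brute(a, b),
                 tolerance = 1e-12)
    expect_equal(dtw_degree_distance(a, b), dtw_degree_distance(b, a))
  }
})

test_that("structural distances obey base case, symmetry and monotonicity", {
  g <- barbell_graph()
  sd_tab <- structural_distances(g, 3)
  deg <- igraph::degree(g)
  f0 <- sd_tab$f[[1]]
  nodes <- sd_tab$nodes
  for (u in nodes) for (v in nodes) {
    if (u == v) next
    expect_equal(f0[u, v],
                 max(deg[u], deg[v]) / min(deg[u], deg[v]) - 1)
  }
  for (k in seq_along(sd_tab$f)) {
    fk <- sd_tab$f[[k]]
    expect_equal(fk, t(fk))
    expect_true(all(fk[!is.na(fk)] >= 0))
    if (k > 1) {
      prev <- sd_tab$f[[k - 1]]
      both <- !is.na(fk) & !is.na(prev)
      expect_true(all(fk[both] >= prev[both] - 1e-12))
    }
  }
})

test_that("automorphic nodes are at structural distance zero", {
  g <- barbell_graph()
  sd_tab <- structural_distances(g, 4)
  for (k in seq_along(sd_tab$f)) {
    fk <- sd_tab$f[[k]]
    for (p in list(c("a1", "b1"), c("a2", "b2"), c("a3", "b3"),
                   c("a2", "a3"))) {
      # automorphic pairs: distance 0 wherever both rings still exist
      if (!is.na(fk[p[1], p[2]])) expect_equal(fk[p[1], p[2]], 0)
    }
    # mirror pairs are strictly closer than non-equivalent pairs
    if (!is.na(fk["a1", "a2"])) {
      expect_gt(fk["a1", "a2"], fk["a1", "b1"])
    }
  }
})

test_that("multilayer weights follow the exponential/log construction", {
  sd_tab <- structural_distances(barbell_graph(), 3)
  mlg <- build_multilayer_graph(sd_tab)
  for (k in seq_along(mlg$W)) {
    wk <- mlg$W[[k]]
    ok <- !is.na(wk)
    expect_true(all(wk[ok] > 0 & wk[ok] <= 1))
    expect_equal(wk[ok] == 1, sd_tab$f[[k]][ok] == 0)
    expect_true(all(mlg$up[, k] >= 1))          # log(Gamma + e) >= log(e)
  }
  # Gamma = 0 -> up-weight exactly 1; Gamma = 3 -> log(3 + e)
  expect_equal(log(0 + exp(1)), 1)
  expect_equal(log(3 + exp(1)), 1.7437, tolerance = 1e-4)

  # within-layer transition distributions sum to one
  for (k in seq_along(mlg$trans)) {
    for (tr in mlg$trans[[k]]) {
      if (!is.null(tr)) {
        expect_equal(tr$cum[length(tr$cum)], 1, tolerance = 1e-9)
      }
    }
  }
  # layer-switch distributions sum to one; boundaries are forced
  expect_equal(unname(layer_switch_probs(mlg, "a1", 0)), c(1, 0))
  top <- mlg$top_layer[["a1"]]
  expect_equal(unname(layer_switch_probs(mlg, "a1", top)), c(0, 1))
  if (top > 1) {
    p <- layer_switch_probs(mlg, "a1", 1)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("walk corpus honours its contract", {
  rg <- make_role_graph(3, 6, seed = 5)
  mlg <- build_multilayer_graph(structural_distances(rg$graph, 3))
  cfg <- walk_config(walks_per_node = 4, walk_length = 15, k_max = 3,
                     seed = 9)
  corpus <- generate_walks(mlg, cfg)
  n <- igraph::vcount(rg$graph)
  expect_length(corpus, 4 * n)
  expect_true(all(lengths(corpus) <= 15))
  expect_true(all(unlist(corpus) %in% igraph::V(rg$graph)$name))
  # every node starts walks_per_node walks
  starts <- table(vapply(corpus, `[`, character(1), 1))
  expect_true(all(starts == 4))
  # determinism under the seed
  corpus2 <- generate_walks(mlg, cfg)
  expect_identical(corpus, corpus2)
  # different seed changes the corpus
  corpus3 <- generate_walks(mlg, walk_config(walks_per_node = 4,
                                             walk_length = 15, k_max = 3,
                                             seed = 10))
  expect_false(identical(corpus, corpus3))
})

test_that("a single same-layer partner is reached with probability one", {
  # two-node graph: each node's only partner at layer 0 is the other
  g <- igraph::graph_from_edgelist(rbind(c("A", "B")), directed = FALSE)
  mlg <- build_multilayer_graph(structural_distances(g, 2))
  tr <- mlg$trans[[1]][[1]]
  expect_equal(tr$targets, 2L)
  expect_equal(tr$cum, 1)
  # walks on a 2-node graph alternate and never error
  corpus <- generate_walks(mlg, walk_config(walks_per_node = 2,
                                            walk_length = 10, seed = 1))
  expect_true(all(lengths(corpus) == 10))
})
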