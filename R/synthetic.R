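#' Random graph with planted structural roles
#'
#' Builds `n_motifs` copies of one random connected motif and bridges them
#' sparsely into a single connected graph. Node `r` of every copy plays the
#' same within-motif role, so corresponding nodes across copies are
#' structurally near-equivalent (exactly equivalent up to the perturbation
#' introduced by the bridge edges) — the property a structural embedding
#' must recover.
#'
#' Bridging: each pair of motif copies receives one bridge edge between
#' uniformly chosen endpoints with probability `bridge_prob`. If the result
#' is disconnected the bridges are redrawn (bounded retries), so
#' `bridge_prob = 0` with more than one motif always fails.
#'
#' @param n_motifs Number of motif copies (>= 2).
#' @param motif_size Nodes per motif (>= 3).
#' @param bridge_prob Probability of a bridge per motif pair (default 0.4).
#' @param seed Integer seed.
#' @param max_tries Bridge redraw attempts before giving up (default 50).
#' @return List of class `"role_graph"`: `graph` (igraph, names
#'   `g<motif>_r<role>`), `roles` (named integer vector, roles
#'   `0..motif_size-1`), `motif` (named integer vector).
#' @export
make_role_graph <- function(n_motifs, motif_size, bridge_prob = 0.4,
                            seed = 1L, max_tries = 50L) {
  stopifnot(n_motifs >= 2, motif_size >= 3, bridge_prob >= 0,
            bridge_prob <= 1)
  set.seed(derive_seed(seed, 31L))
  # one connected motif with heterogeneous degrees, shared by all copies
  motif_el <- NULL
  for (try in 1:100) {
    m <- igraph::sample_gnp(motif_size, p = min(1, 2.8 / motif_size))
    if (igraph::is_connected(m) && max(igraph::degree(m)) <
        motif_size - 1L) {
      motif_el <- igraph::as_edgelist(m, names = FALSE)
      break
    }
  }
  if (is.null(motif_el)) stop("could not draw a connected motif")
  node_name <- function(g, r) sprintf("g%d_r%d", g, r - 1L)
  edges <- do.call(rbind, lapply(seq_len(n_motifs), function(gi) {
    cbind(node_name(gi, motif_el[, 1]), node_name(gi, motif_el[, 2]))
  }))
  pairs <- utils::combn(n_motifs, 2)
  for (try in seq_len(max_tries)) {
    take <- runif(ncol(pairs)) < bridge_prob
    bridges <- if (any(take)) {
      t(apply(pairs[, take, drop = FALSE], 2, function(p) {
        c(node_name(p[1], sample.int(motif_size, 1)),
          node_name(p[2], sample.int(motif_size, 1)))
      }))
    } else NULL
    g <- igraph::graph_from_edgelist(rbind(edges, bridges), directed = FALSE)
    g <- igraph::simplify(g)
    if (igraph::is_connected(g) &&
        igraph::vcount(g) == n_motifs * motif_size) {
      nm <- igraph::V(g)$name
      roles <- as.integer(sub("^g\\d+_r", "", nm))
      motif <- as.integer(sub("^g(\\d+)_r\\d+$", "\\1", nm))
      return(structure(list(graph = g,
                            roles = setNames(roles, nm),
                            motif = setNames(motif, nm)),
                       class = "role_graph"))
    }
  }
  stop("could not bridge motifs into a connected graph (bridge_prob too low?)")
}

#' Generate a complete synthetic synergy study
#'
#' Builds a role-structured network ([make_role_graph()]), assigns drugs and
#' cell lines random target-protein sets biased toward a preferred
#' structural role, and samples drug-drug-cell-line records whose synergy
#' score carries a planted, role-borne signal:
#' each role carries a latent activity `v_r` of -1 or +1, and a record's
#' latent score is
#' `effect * strength(cell) * v(cell role) * max(v(role drug A), v(role drug B))`
#' plus Gaussian noise. The signal lives entirely in the structural roles of
#' the targets — never in node identity — so recovering it requires the
#' embedding to capture structural equivalence. The sign statistic is
#' symmetric in the two drugs and balanced (about half of records positive).
#'
#' Records are sampled with replacement over triples, so replicated triples
#' (possibly with conflicting labels, as in real screens) occur.
#'
#' @param n_drugs,n_cells,n_records Study dimensions (defaults 20, 8, 2000).
#' @param effect Planted effect size (default 1); 0 gives a pure-noise null
#'   study.
#' @param noise Gaussian noise standard deviation on the latent score
#'   (default 0.5).
#' @param seed Integer root seed; the whole study is a deterministic
#'   function of it.
#' @param n_motifs,motif_size,bridge_prob Network shape (defaults 6, 8,
#'   0.4); see [make_role_graph()].
#' @param targets_per_drug,targets_per_cell Target-set draw counts
#'   (defaults 6, 10; sets may be smaller after deduplication).
#' @param role_purity Probability that each target draw comes from the
#'   entity's preferred role rather than from anywhere (default 0.8).
#' @param cell_effect Optional numeric vector (length `n_cells`) of
#'   per-cell-line signal multipliers; default all 1.
#' @param n_tissues Tissue labels cycled over cell lines (default 4).
#' @return Object of class `"synergy_study"`: `network` (igraph), `roles`,
#'   `drug_map`, `cell_map` (with tissue attribute), `records`
#'   (see [read_synergy()]), `truth` (per-record latent score and statistic,
#'   per-cell signal strength, role activities), `seed`, `params`.
#' @export
make_synergy_study <- function(n_drugs = 20L, n_cells = 8L,
                               n_records = 2000L, effect = 1, noise = 0.5,
                               seed = 1L, n_motifs = 6L, motif_size = 8L,
                               bridge_prob = 0.4, targets_per_drug = 6L,
                               targets_per_cell = 10L, role_purity = 0.8,
                               cell_effect = NULL, n_tissues = 4L) {
  stopifnot(n_drugs >= 2, n_cells >= 1, n_records >= 1, noise >= 0,
            role_purity >= 0, role_purity <= 1)
  rg <- make_role_graph(n_motifs, motif_size, bridge_prob,
                        seed = derive_seed(seed, 41L))
  nodes <- igraph::V(rg$graph)$name
  roles <- rg$roles

  set.seed(derive_seed(seed, 42L))
  v_role <- setNames(sample(rep_len(c(-1, 1), motif_size)),
                     as.character(0:(motif_size - 1L)))

  draw_targets <- function(pref_role, k) {
    pool_pref <- nodes[roles == pref_role]
    draws <- vapply(seq_len(k), function(i) {
      if (runif(1) < role_purity) sample(pool_pref, 1) else sample(nodes, 1)
    }, character(1))
    sort(unique(draws))
  }

  drug_ids <- sprintf("D%02d", seq_len(n_drugs))
  drug_role <- setNames(sample(0:(motif_size - 1L), n_drugs, replace = TRUE),
                        drug_ids)
  drug_map <- setNames(lapply(drug_ids, function(d)
    draw_targets(drug_role[[d]], targets_per_drug)), drug_ids)

  cell_ids <- sprintf("C%02d", seq_len(n_cells))
  cell_role <- setNames(sample(0:(motif_size - 1L), n_cells, replace = TRUE),
                        cell_ids)
  cell_map <- setNames(lapply(cell_ids, function(cc)
    draw_targets(cell_role[[cc]], targets_per_cell)), cell_ids)
  attr(cell_map, "tissue") <- setNames(
    sprintf("T%d", ((seq_len(n_cells) - 1L) %% n_tissues) + 1L), cell_ids)

  if (is.null(cell_effect)) cell_effect <- rep(1, n_cells)
  stopifnot(length(cell_effect) == n_cells)
  cell_effect <- setNames(as.numeric(cell_effect), cell_ids)

  set.seed(derive_seed(seed, 43L))
  ab <- t(vapply(seq_len(n_records), function(i)
    sample(drug_ids, 2L), character(2)))
  cell <- sample(cell_ids, n_records, replace = TRUE)
  va <- v_role[as.character(drug_role[ab[, 1]])]
  vb <- v_role[as.character(drug_role[ab[, 2]])]
  vc <- v_role[as.character(cell_role[cell])]
  stat <- vc * pmax(va, vb)
  latent <- effect * cell_effect[cell] * stat + rnorm(n_records, 0, noise)
  records <- make_synergy_records(ab[, 1], ab[, 2], cell, latent)

  structure(list(network = rg$graph, roles = roles, drug_map = drug_map,
                 cell_map = cell_map, records = records,
                 truth = list(stat = unname(stat), latent = unname(latent),
                              role_activity = v_role,
                              drug_role = drug_role, cell_role = cell_role,
                              cell_signal = effect * cell_effect),
                 seed = as.integer(seed),
                 params = list(n_drugs = n_drugs, n_cells = n_cells,
                               n_records = n_records, effect = effect,
                               noise = noise, n_motifs = n_motifs,
                               motif_size = motif_size,
                               bridge_prob = bridge_prob,
                               targets_per_drug = targets_per_drug,
                               targets_per_cell = targets_per_cell,
                               role_purity = role_purity)),
            class = "synergy_study")
}

#' @export
print.synergy_study <- function(x, ...) {
  cat("Synthetic synergy study (seed ", x$seed, "):\n", sep = "")
  cat("  network:", igraph::vcount(x$network), "proteins,",
      igraph::ecount(x$network), "interactions\n")
  cat("  entities:", length(x$drug_map), "drugs,", length(x$cell_map),
      "cell lines\n")
  cat("  records:", nrow(x$records), "(",
      sum(x$records$label == 1), "synergistic /",
      sum(x$records$label == 0), "antagonistic )\n")
  invisible(x)
}

#' Write a synthetic study as the four standard input files
#'
#' Emits `ppi_edges.tsv` (edge list), `drug_targets.tsv`,
#' `cell_targets.tsv` (with tissue column), `synergy.csv` and a
#' `truth.json` with the planted ground truth. Regenerating the study from
#' the same seed reproduces the files byte-identically.
#'
#' @param study A `"synergy_study"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "ppi_edges.tsv"),
             drugs = file.path(dir, "drug_targets.tsv"),
             cells = file.path(dir, "cell_targets.tsv"),
             synergy = file.path(dir, "synergy.csv"),
             truth = file.path(dir, "truth.json"))
  el <- igraph::as_edgelist(study$network)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), paths[["edges"]])
  assoc_lines <- function(map, tissue = NULL) {
    unlist(lapply(names(map), function(id) {
      if (is.null(tissue)) paste(id, map[[id]], sep = "\t")
      else paste(id, map[[id]], tissue[[id]], sep = "\t")
    }))
  }
  writeLines(assoc_lines(study$drug_map), paths[["drugs"]])
  writeLines(assoc_lines(study$cell_map, attr(study$cell_map, "tissue")),
             paths[["cells"]])
  rec <- study$records
  writeLines(c("drug_a,drug_b,cell,score",
               sprintf("%s,%s,%s,%.8f", rec$drug_a, rec$drug_b, rec$cell,
                       rec$score)), paths[["synergy"]])
  jsonlite::write_json(c(study$truth,
                         list(seed = study$seed, params = study$params)),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
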