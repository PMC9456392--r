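#' Read a protein-protein interaction network from an edge list
#'
#' Reads a whitespace/tab-delimited two-column edge list of protein (gene)
#' identifiers and returns a simple undirected [igraph][igraph::igraph-package]
#' graph. Duplicate edges (in either orientation) are collapsed, self-loops
#' are removed, and nodes left isolated after cleaning are dropped; counts of
#' removed elements are reported via [message()]. Identifiers are matched
#' exactly (case-sensitive), with no gene-symbol mapping.
#'
#' Isolated nodes cannot be embedded: the degree-ring alignment cost divides
#' by the minimum degree and is undefined at degree zero.
#'
#' @param path Path to the edge-list file. Lines starting with `#` and blank
#'   lines are ignored; the first two whitespace-delimited tokens of every
#'   other line are the edge endpoints.
#' @return An undirected simple `igraph` graph with named vertices, every
#'   vertex of degree >= 1.
#' @seealso [read_associations()], [read_synergy()]
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- vapply(toks, length, integer(1))
  if (any(nf < 2L)) {
    stop("edge-list parse error at line ", lineno[which(nf < 2L)[1]],
         ": fewer than 2 fields")
  }
  if (length(toks) == 0L) stop("edge-list file contains no edges: ", path)
  edges <- t(vapply(toks, function(x) x[1:2], character(2)))
  as_ppi_network(edges)
}

#' Build a clean PPI network from an edge matrix
#'
#' @param edges Two-column character matrix of endpoints.
#' @return Simple undirected named `igraph` graph; see [read_edge_list()].
#' @export
as_ppi_network <- function(edges) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  n_loop <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  iso <- which(igraph::degree(g) == 0)
  if (n_loop || n_multi || length(iso)) {
    message("network cleaning: removed ", n_loop, " self-loop(s), ",
            n_multi, " duplicate edge(s), ", length(iso),
            " isolated node(s)")
  }
  if (length(iso)) g <- igraph::delete_vertices(g, iso)
  if (igraph::vcount(g) == 0L) stop("network is empty after cleaning")
  g
}

#' Read a drug->protein or cell-line->protein association table
#'
#' Reads a delimited table with an entity identifier in column 1 and a protein
#' identifier in column 2 (optionally a tissue label in column 3, for cell
#' lines). Protein identifiers absent from the network are filtered out;
#' entities whose whole target set falls outside the network are dropped with
#' a warning. Duplicate rows collapse under set semantics.
#'
#' @param path Path to a TSV (or other single-character-delimited) file
#'   without a header.
#' @param universe The PPI network (`igraph`) whose vertex names define the
#'   admissible protein identifiers.
#' @param sep Field separator, default tab.
#' @return A named list mapping entity id to a character vector of target
#'   proteins (each non-empty), with attribute `"tissue"` (named character
#'   vector) when a third column is present.
#' @export
read_associations <- function(path, universe, sep = "\t") {
  if (!file.exists(path)) stop("association file not found: ", path)
  df <- read.delim(path, header = FALSE, sep = sep,
                   colClasses = "character", strip.white = TRUE,
                   blank.lines.skip = TRUE, comment.char = "#")
  if (ncol(df) < 2L) stop("association table needs >= 2 columns: ", path)
  build_association_map(entity = df[[1]], protein = df[[2]],
                        tissue = if (ncol(df) >= 3L) df[[3]] else NULL,
                        universe = universe)
}

#' Build an association map from vectors
#'
#' Programmatic counterpart of [read_associations()]; same filtering rules.
#'
#' @param entity,protein Character vectors of equal length (one association
#'   per element).
#' @param tissue Optional character vector of tissue labels per association
#'   (constant within an entity).
#' @param universe PPI network whose vertex names filter `protein`.
#' @return Named list of protein sets; see [read_associations()].
#' @export
build_association_map <- function(entity, protein, universe, tissue = NULL) {
  stopifnot(length(entity) == length(protein))
  nodes <- igraph::V(universe)$name
  ok <- protein %in% nodes
  map <- lapply(split(protein[ok], entity[ok]), function(p) sort(unique(p)))
  all_entities <- unique(entity)
  dropped <- setdiff(all_entities, names(map))
  if (length(dropped)) {
    warning(length(dropped), " entit(ies) dropped: no target protein in the ",
            "network (", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", ")")
  }
  if (length(map) == 0L) stop("no entity has any target in the network")
  map <- map[order(names(map))]
  if (!is.null(tissue)) {
    tl <- vapply(split(tissue, entity), function(x) x[[1]], character(1))
    attr(map, "tissue") <- tl[names(map)]
  }
  map
}

#' Read a drug-drug-cell-line synergy table
#'
#' Reads a delimited file with header columns `drug_a`, `drug_b`, `cell`,
#' `score`. The binary class label follows the sign of the synergy score
#' (Loewe or ZIP scale): positive scores are synergistic (`label = 1`),
#' negative scores antagonistic (`label = 0`). Records with score exactly
#' zero belong to neither class and are dropped (count reported). Row order
#' is preserved.
#'
#' @param path Path to a CSV or TSV file with a header. The separator is
#'   sniffed from the header line unless given.
#' @param sep Field separator; `NULL` (default) picks `","` or `"\t"` from
#'   the header.
#' @return A `data.frame` with columns `drug_a`, `drug_b`, `cell` (character),
#'   `score` (numeric) and `label` (integer 0/1), and attribute
#'   `"n_zero_dropped"`.
#' @export
read_synergy <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("synergy file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (lengths(regmatches(header, gregexpr(",", header))) >=
               lengths(regmatches(header, gregexpr("\t", header)))) "," else "\t"
  }
  df <- read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                   strip.white = TRUE)
  need <- c("drug_a", "drug_b", "cell", "score")
  if (!all(need %in% names(df))) {
    stop("synergy table must have columns: ", paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) {
    stop("non-numeric synergy score at line ",
         which(is.na(score))[1] + 1L, " of ", path)
  }
  make_synergy_records(df$drug_a, df$drug_b, df$cell, score)
}

#' Assemble synergy records from vectors
#'
#' Applies the sign-label rule of [read_synergy()] to in-memory vectors.
#'
#' @param drug_a,drug_b,cell Character vectors.
#' @param score Numeric synergy scores.
#' @return See [read_synergy()].
#' @export
make_synergy_records <- function(drug_a, drug_b, cell, score) {
  stopifnot(length(drug_a) == length(score), length(drug_b) == length(score),
            length(cell) == length(score))
  if (any(drug_a == drug_b)) stop("records with drug_a == drug_b are invalid")
  zero <- score == 0
  if (any(zero)) {
    message(sum(zero), " record(s) with synergy score 0 dropped ",
            "(neither synergistic nor antagonistic)")
  }
  out <- data.frame(drug_a = as.character(drug_a)[!zero],
                    drug_b = as.character(drug_b)[!zero],
                    cell = as.character(cell)[!zero],
                    score = score[!zero],
                    stringsAsFactors = FALSE)
  out$label <- as.integer(out$score > 0)
  attr(out, "n_zero_dropped") <- sum(zero)
  out
}

#' Write / read a node-embedding matrix as text
#'
#' Plain-text interchange format: a header line `n d`, then one line per node
#' holding the node id followed by `d` real values. Round-tripping preserves
#' values to at least 6 significant digits.
#'
#' @param emb Numeric matrix, one row per node, rownames = node ids.
#' @param path Output file path.
#' @return `write_embeddings()` returns `path` invisibly; `read_embeddings()`
#'   returns the matrix with node ids as rownames.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(is.matrix(emb), is.numeric(emb))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  if (nrow(emb) > 0) {
    ids <- rownames(emb)
    if (is.null(ids)) stop("embedding matrix must have rownames (node ids)")
    body <- vapply(seq_len(nrow(emb)), function(i) {
      paste(ids[i], paste(sprintf("%.10g", emb[i, ]), collapse = " "))
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed embedding header")
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) - 1L != n) {
    stop("embedding format error: header announces ", n, " rows, file has ",
         length(lines) - 1L)
  }
  if (n == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = d))
  }
  toks <- strsplit(trimws(lines[-1]), "\\s+")
  bad <- which(vapply(toks, length, integer(1)) != d + 1L)
  if (length(bad)) {
    stop("embedding format error at line ", bad[1] + 1L,
         ": expected ", d + 1L, " fields")
  }
  ids <- vapply(toks, `[[`, character(1), 1L)
  vals <- t(vapply(toks, function(x) as.numeric(x[-1]), numeric(d)))
  if (d == 1L) vals <- matrix(as.numeric(vals), ncol = 1L)
  rownames(vals) <- ids
  vals
}
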