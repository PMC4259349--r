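#' Directed binary graphs
#'
#' A `digraph` is the single input object of the package: a loop-free binary
#' adjacency matrix (entry `(i, j) = 1` iff there is an edge `i -> j`)
#' together with optional unique node labels. Weighted or multi-edge inputs
#' are binarized (any nonzero entry becomes 1) with a warning, because every
#' statistic in the package is defined on binary adjacency.
#'
#' @param x An `N x N` numeric matrix, a two-column data frame of edges
#'   (columns interpreted as source, target), or an `igraph` object.
#' @param labels Optional character vector of `N` unique node labels.
#' @param n_nodes For edge-list input, the number of nodes (defaults to the
#'   largest index seen).
#' @param index_base For edge-list input, whether indices start at 0 or 1.
#' @param strict If `TRUE` (default) a self-loop is an error; otherwise
#'   self-loops are dropped with a warning.
#'
#' @return An object of class `digraph`: a list with elements `adj`
#'   (integer matrix) and `labels` (character or `NULL`).
#' @examples
#' g <- digraph(data.frame(from = c(1, 2, 3), to = c(2, 3, 1)))
#' n_nodes(g)
#' degree_table(g)
#' @export
digraph <- function(x, labels = NULL, n_nodes = NULL, index_base = 1,
                    strict = TRUE) {
  if (inherits(x, "digraph")) {
    return(x)
  }
  if (inherits(x, "igraph")) {
    adj <- as.matrix(igraph::as_adjacency_matrix(x, sparse = FALSE))
    if (is.null(labels) && !is.null(igraph::V(x)$name)) {
      labels <- igraph::V(x)$name
    }
    return(new_digraph(adj, labels, strict = strict))
  }
  if (is.data.frame(x)) {
    return(digraph_from_edges(x, n_nodes = n_nodes, index_base = index_base,
                              labels = labels, strict = strict))
  }
  if (is.matrix(x)) {
    return(new_digraph(x, labels, strict = strict))
  }
  abort("`x` must be a matrix, a two-column edge data frame, or an igraph.")
}

new_digraph <- function(adj, labels = NULL, strict = TRUE) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    abort("adjacency must be a square matrix")
  }
  if (anyNA(adj)) abort("adjacency contains missing values")
  storage.mode(adj) <- "double"
  if (any(adj != 0 & adj != 1)) {
    warn("non-binary adjacency entries were binarized (nonzero -> 1)")
    adj <- (adj != 0) + 0
  }
  if (any(diag(adj) != 0)) {
    if (strict) {
      abort("self-loop found on the adjacency diagonal (no self-connections allowed)")
    }
    warn("self-loops dropped from the adjacency diagonal")
    diag(adj) <- 0
  }
  storage.mode(adj) <- "integer"
  n <- nrow(adj)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) abort("`labels` must have one entry per node")
    if (anyDuplicated(labels)) abort("node labels must be unique")
  }
  dimnames(adj) <- NULL
  structure(list(adj = adj, labels = labels), class = "digraph")
}

digraph_from_edges <- function(edges, n_nodes = NULL, index_base = 1,
                               labels = NULL, strict = TRUE) {
  if (ncol(edges) < 2) abort("edge data frame needs two columns (source, target)")
  src <- as.integer(edges[[1]])
  dst <- as.integer(edges[[2]])
  if (anyNA(src) || anyNA(dst)) abort("non-integer entries in edge list")
  if (!index_base %in% c(0L, 1L)) abort("`index_base` must be 0 or 1")
  src <- src - index_base + 1L
  dst <- dst - index_base + 1L
  if (length(src) && min(c(src, dst)) < 1L) {
    abort("edge index below the declared index base")
  }
  n <- n_nodes %||% if (length(src)) max(src, dst) else 0L
  n <- as.integer(n)
  if (length(src) && max(src, dst) > n) abort("edge index exceeds `n_nodes`")
  loops <- src == dst
  if (any(loops)) {
    if (strict) {
      abort(sprintf("self-loop (%d -> %d) in edge list", src[which(loops)[1]],
                    dst[which(loops)[1]]))
    }
    warn(sprintf("dropped %d self-loop edge(s)", sum(loops)))
    src <- src[!loops]
    dst <- dst[!loops]
  }
  adj <- matrix(0L, n, n)
  adj[cbind(src, dst)] <- 1L # duplicate rows collapse to one edge
  new_digraph(adj, labels, strict = strict)
}

#' @export
print.digraph <- function(x, ...) {
  cat(sprintf("<digraph: %d nodes, %d edges, %d reciprocal pairs>\n",
              n_nodes(x), n_edges(x), sum(reciprocal_matrix(x)) / 2L))
  invisible(x)
}

#' Basic graph accessors
#'
#' @param g A [digraph()].
#' @return `n_nodes()` and `n_edges()` return single integers;
#'   `node_labels()` returns the stored labels, or `"1"..."N"` when none
#'   were supplied; `adjacency()` returns the integer adjacency matrix.
#' @export
n_nodes <- function(g) nrow(g$adj)

#' @rdname n_nodes
#' @export
n_edges <- function(g) sum(g$adj)

#' @rdname n_nodes
#' @export
node_labels <- function(g) g$labels %||% as.character(seq_len(n_nodes(g)))

#' @rdname n_nodes
#' @export
adjacency <- function(g) g$adj

#' Reciprocal-edge matrix
#'
#' The binary matrix with a 1 wherever a pair of nodes is joined by edges in
#' both directions, i.e. the elementwise product of the adjacency matrix and
#' its transpose. It is symmetric with zero diagonal and appears throughout
#' the fingerprint formulas.
#'
#' @param g A [digraph()].
#' @return An `N x N` integer matrix.
#' @export
reciprocal_matrix <- function(g) {
  A <- g$adj
  R <- A * t(A)
  storage.mode(R) <- "integer"
  R
}

#' Per-node degree statistics
#'
#' In-degree, out-degree, number of reciprocal partners (nodes connected by
#' edges in both directions) and total degree for each node.
#'
#' @param g A [digraph()].
#' @return A tibble with columns `node`, `label`, `d_in`, `d_out`,
#'   `d_recip`, `d_tot`.
#' @export
degree_table <- function(g) {
  A <- g$adj
  tibble(
    node = seq_len(n_nodes(g)),
    label = node_labels(g),
    d_in = as.integer(colSums(A)),
    d_out = as.integer(rowSums(A)),
    d_recip = as.integer(rowSums(reciprocal_matrix(g))),
  ) |>
    dplyr::mutate(d_tot = .data$d_in + .data$d_out)
}

#' Convert to an igraph object
#'
#' @param g A [digraph()].
#' @return An `igraph` directed graph carrying the node labels as vertex
#'   names.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "directed")
  igraph::V(ig)$name <- node_labels(g)
  ig
}

#' Packaged three-node fixtures
#'
#' Small named graphs used in examples and tests: `two_path` (A->B->C),
#' `cycle3` (A->B->C->A), `ffl` (the feed-forward triangle A->B, A->C,
#' B->C), `recip_plus_out` (A<->B, B->C) and `complete_triad` (all six
#' directed edges).
#'
#' @param name One of `"two_path"`, `"cycle3"`, `"ffl"`,
#'   `"recip_plus_out"`, `"complete_triad"`.
#' @return A [digraph()] with labels `A`, `B`, `C`.
#' @export
toy_graph <- function(name) {
  edges <- switch(name,
    two_path = rbind(c(1, 2), c(2, 3)),
    cycle3 = rbind(c(1, 2), c(2, 3), c(3, 1)),
    ffl = rbind(c(1, 2), c(1, 3), c(2, 3)),
    recip_plus_out = rbind(c(1, 2), c(2, 1), c(2, 3)),
    complete_triad = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)),
    abort(sprintf(
      "unknown toy graph '%s'; valid names: two_path, cycle3, ffl, recip_plus_out, complete_triad",
      name
    ))
  )
  digraph_from_edges(as.data.frame(edges), n_nodes = 3L, labels = c("A", "B", "C"))
}

#' Seeded Erdos-Renyi-style random digraphs
#'
#' Without `reciprocity`, every ordered pair `(i, j)`, `i != j`, carries an
#' edge independently with probability `p`. With `reciprocity = rho`,
#' unordered pairs are assigned states none / single (random direction) /
#' reciprocal such that the marginal probability of any directed edge is
#' still `p` while the probability that a present edge is reciprocated is
#' `rho`. That requires `p * (2 - rho) <= 1`.
#'
#' @param n Number of nodes (>= 2).
#' @param p Marginal directed-edge probability in `[0, 1]`.
#' @param reciprocity Optional conditional reciprocation probability.
#' @param seed Optional integer seed; given the same seed the same graph is
#'   returned and the caller's RNG state is left untouched.
#' @return A [digraph()].
#' @export
random_digraph <- function(n, p, reciprocity = NULL, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) abort("`n` must be an integer >= 2")
  if (!is.numeric(p) || p < 0 || p > 1) abort("`p` must be a probability")
  gen <- function() {
    if (is.null(reciprocity)) {
      adj <- matrix(rbinom(n * n, 1L, p), n, n)
      diag(adj) <- 0L
      return(adj)
    }
    rho <- reciprocity
    if (!is.numeric(rho) || rho < 0 || rho > 1) {
      abort("`reciprocity` must be a probability")
    }
    q2 <- p * rho           # P(pair reciprocal)
    q1 <- 2 * p * (1 - rho) # P(pair single edge)
    if (q1 + q2 > 1 + 1e-12) {
      abort("infeasible (p, reciprocity): requires p * (2 - reciprocity) <= 1")
    }
    adj <- matrix(0L, n, n)
    pair <- which(upper.tri(adj), arr.ind = TRUE)
    u <- runif(nrow(pair))
    flip <- runif(nrow(pair)) < 0.5
    recip <- u < q2
    single <- !recip & u < q2 + q1
    i <- pair[, 1]; j <- pair[, 2]
    adj[cbind(i, j)[recip, , drop = FALSE]] <- 1L
    adj[cbind(j, i)[recip, , drop = FALSE]] <- 1L
    fwd <- single & flip
    bwd <- single & !flip
    adj[cbind(i, j)[fwd, , drop = FALSE]] <- 1L
    adj[cbind(j, i)[bwd, , drop = FALSE]] <- 1L
    adj
  }
  adj <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  new_digraph(adj)
}

# ---- file input / output ---------------------------------------------------

#' Read and write graphs as plain-text files
#'
#' Edge lists are two-column TSV (or CSV) files, one `source, target` pair
#' per line, with an optional `source<TAB>target` header. Adjacency files
#' are dense CSV matrices of 0/1 values, optionally with a leading label row
#' and column. Node-label tables are two-column `id<TAB>label` TSV files.
#'
#' @param path File path.
#' @param index_base Whether edge-list indices are 0- or 1-based.
#' @param n_nodes Optional node count (otherwise the largest index is used).
#' @param strict If `TRUE`, a self-loop row is an error; otherwise it is
#'   dropped with a warning.
#' @param g A [digraph()] to write.
#' @return `load_edge_list()` and `load_adjacency()` return a [digraph()];
#'   the writers return the path invisibly.
#' @export
load_edge_list <- function(path, index_base = 1, n_nodes = NULL, strict = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sep <- if (length(lines) && grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (length(parts) && identical(tolower(trimws(parts[[1]][1])), "source")) {
    parts <- parts[-1]
  }
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) {
    abort(sprintf("malformed edge-list line %d in '%s'", bad[1], path))
  }
  src <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  dst <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(src) || anyNA(dst)) {
    abort(sprintf("malformed edge-list line %d in '%s'",
                  which(is.na(src) | is.na(dst))[1], path))
  }
  digraph_from_edges(data.frame(src, dst), n_nodes = n_nodes,
                     index_base = index_base, strict = strict)
}

#' @rdname load_edge_list
#' @export
write_edge_list <- function(g, path, index_base = 1) {
  e <- which(g$adj == 1L, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  df <- tibble(source = e[, 1] - 1L + as.integer(index_base),
               target = e[, 2] - 1L + as.integer(index_base))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname load_edge_list
#' @export
load_adjacency <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  labels <- NULL
  num <- suppressWarnings(vapply(raw[1, ], function(x) as.numeric(x), 0))
  if (anyNA(num)) { # leading label row (and possibly label column)
    header <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    first_col <- suppressWarnings(as.numeric(raw[[1]]))
    if (anyNA(first_col)) {
      labels <- as.character(raw[[1]])
      raw <- raw[, -1, drop = FALSE]
    } else {
      labels <- header
    }
  }
  adj <- apply(raw, c(1, 2), as.numeric)
  dimnames(adj) <- NULL
  new_digraph(adj, labels, strict = strict)
}

#' @rdname load_edge_list
#' @export
write_adjacency <- function(g, path) {
  df <- as.data.frame(g$adj)
  names(df) <- node_labels(g)
  utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname load_edge_list
#' @export
load_node_labels <- function(path) {
  df <- readr::read_tsv(path, col_names = c("id", "label"),
                        col_types = readr::cols(readr::col_integer(),
                                                readr::col_character()))
  df[order(df$id), ]$label
}
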