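# fixtures built in code; no data files

toy_names <- c("two_path", "cycle3", "ffl", "recip_plus_out", "complete_triad")

rg <- function(n, p, seed) random_digraph(n, p, seed = seed)

# independent reference for the functional count of a single role pattern:
# count edge-supersets directly from an explicit description
# (used for a handful of hand-checked spot values)
count_pattern <- function(g, required_edges) {
  A <- adjacency(g)
  n <- n_nodes(g)
  hits <- 0L
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    perms <- list(tri, tri[c(1, 3, 2)], tri[c(2, 1, 3)], tri[c(2, 3, 1)],
                  tri[c(3, 1, 2)], tri[c(3, 2, 1)])
    seen <- character()
    for (p in perms) {
      e <- cbind(p[required_edges[, 1]], p[required_edges[, 2]])
      if (all(A[e] == 1L)) {
        key <- paste(sort(paste(e[, 1], e[, 2])), collapse = ";")
        seen <- union(seen, key)
      }
    }
    hits <- hits + length(seen)
  }
  hits
}

# igraph triad census mapped onto the package's 13 motif ids: for each
# canonical class representative, find which census slot its own census
# lights up; gives an external oracle for structural motif counts
census_motif_map <- function() {
  vapply(1:13, function(m) {
    cl <- motifroles:::motif_catalog()$classes_by_id[[m]]
    ig <- igraph::graph_from_adjacency_matrix(cl$adj, mode = "directed")
    which(igraph::triad_census(ig) == 1L)
  }, 1L)
}
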