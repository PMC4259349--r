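#' Degree-preserving randomization by double-edge swaps
#'
#' Repeatedly picks two edges `a -> b`, `c -> d` and rewires them to
#' `a -> d`, `c -> b`, rejecting any swap that would create a self-loop or
#' a duplicate edge. Every node keeps its exact in- and out-degree;
#' reciprocal degree is *not* preserved (an optional mode that also
#' preserves it swaps single edges and reciprocal pairs within their own
#' pools, and is off by default).
#'
#' @param g A [digraph()] with at least 2 edges.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param attempts Attempted-swap budget; default `100 *` edge count.
#' @param preserve_reciprocal If `TRUE`, double swaps are performed
#'   separately within the single-edge set and the reciprocal-pair set so
#'   that each node's reciprocal degree is also invariant.
#' @return A rewired [digraph()] with attributes `swaps` (successful swap
#'   count) and `degenerate` (`TRUE`, with a warning, when no swap
#'   succeeded within the budget).
#' @export
rewire_degree_preserving <- function(g, seed = NULL, attempts = NULL,
                                     preserve_reciprocal = FALSE) {
  if (n_edges(g) < 2) abort("graph must have at least 2 edges")
  run <- function() {
    if (preserve_reciprocal) {
      rewire_two_pools(g, attempts)
    } else {
      rewire_pool(adjacency(g), attempts %||% (100L * n_edges(g)))
    }
  }
  res <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  out <- new_digraph(res$adj, g$labels)
  attr(out, "swaps") <- res$swaps
  attr(out, "degenerate") <- res$swaps == 0L
  if (res$swaps == 0L) {
    warn("no successful swaps within the attempt budget; returning an unchanged copy (graph likely too constrained)")
  }
  out
}

# double-edge swaps on a full adjacency matrix
rewire_pool <- function(adj, attempts) {
  edges <- which(adj == 1L, arr.ind = TRUE)
  m <- nrow(edges)
  swaps <- 0L
  if (m >= 2) {
    for (t in seq_len(attempts)) {
      idx <- sample.int(m, 2L)
      a <- edges[idx[1], 1]; b <- edges[idx[1], 2]
      cc <- edges[idx[2], 1]; d <- edges[idx[2], 2]
      if (a == d || cc == b) next          # would create self-loops
      if (adj[a, d] == 1L || adj[cc, b] == 1L) next # duplicates
      adj[a, b] <- 0L; adj[cc, d] <- 0L
      adj[a, d] <- 1L; adj[cc, b] <- 1L
      edges[idx[1], 2] <- d
      edges[idx[2], 2] <- b
      swaps <- swaps + 1L
    }
  }
  list(adj = adj, swaps = swaps)
}

# reciprocal-preserving variant: swap within the single-edge pool (as
# ordinary directed edges) and within the reciprocal-pair pool (as
# undirected pairs), so d_in, d_out and d_recip are all invariant
rewire_two_pools <- function(g, attempts) {
  A <- adjacency(g)
  R <- reciprocal_matrix(g)
  U <- A - R # unreciprocated edges
  m_u <- sum(U)
  m_r <- sum(R) / 2
  budget <- attempts %||% (100L * n_edges(g))
  swaps <- 0L
  if (m_u >= 2) {
    # singles: standard double swap, but collisions checked against the
    # full adjacency so no reciprocal pair is ever created or destroyed
    edges <- which(U == 1L, arr.ind = TRUE)
    for (t in seq_len(budget)) {
      idx <- sample.int(nrow(edges), 2L)
      a <- edges[idx[1], 1]; b <- edges[idx[1], 2]
      cc <- edges[idx[2], 1]; d <- edges[idx[2], 2]
      if (a == d || cc == b) next
      if (A[a, d] == 1L || A[d, a] == 1L || A[cc, b] == 1L || A[b, cc] == 1L) next
      A[a, b] <- 0L; A[cc, d] <- 0L; A[a, d] <- 1L; A[cc, b] <- 1L
      edges[idx[1], 2] <- d; edges[idx[2], 2] <- b
      swaps <- swaps + 1L
    }
  }
  if (m_r >= 2) {
    pairs <- which(R == 1L & upper.tri(R), arr.ind = TRUE)
    for (t in seq_len(budget)) {
      idx <- sample.int(nrow(pairs), 2L)
      a <- pairs[idx[1], 1]; b <- pairs[idx[1], 2]
      cc <- pairs[idx[2], 1]; d <- pairs[idx[2], 2]
      ends <- c(a, b, cc, d)
      if (anyDuplicated(ends)) next
      # rewire pairs {a,b},{c,d} -> {a,d},{c,b}
      if (A[a, d] == 1L || A[d, a] == 1L || A[cc, b] == 1L || A[b, cc] == 1L) next
      A[a, b] <- 0L; A[b, a] <- 0L; A[cc, d] <- 0L; A[d, cc] <- 0L
      A[a, d] <- 1L; A[d, a] <- 1L; A[cc, b] <- 1L; A[b, cc] <- 1L
      pairs[idx[1], ] <- sort(c(a, d)); pairs[idx[2], ] <- sort(c(cc, b))
      swaps <- swaps + 1L
    }
  }
  list(adj = A, swaps = swaps)
}

#' Null ensemble of network metrics
#'
#' Generates `n_random` independent degree-preserving randomizations of a
#' graph and records the requested metrics for each replicate:
#' transitivities, global clustering means (over defined nodes), and
#' optionally the full functional role-fingerprint matrix (needed by
#' [overabundance()]).
#'
#' @param g A [digraph()].
#' @param n_random Number of replicates (>= 1).
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @param metrics Character subset of `c("transitivity", "clustering",
#'   "role_fingerprints")`.
#' @param attempts Swap budget per replicate (see
#'   [rewire_degree_preserving()]).
#' @return An object of class `null_ensemble`: a list with the per-replicate
#'   records, summary tibbles (null mean and sd next to the observed value),
#'   and provenance (seed, swap budget, graph size).
#' @export
ensemble_metrics <- function(g, n_random = 20, seed = 1,
                             metrics = c("transitivity", "clustering"),
                             attempts = NULL) {
  if (n_random < 1) abort("`n_random` must be >= 1")
  metrics <- match.arg(metrics, c("transitivity", "clustering", "role_fingerprints"),
                       several.ok = TRUE)
  seed <- as.integer(seed)
  measure <- function(graph) {
    rec <- list()
    if ("transitivity" %in% metrics) rec$transitivity <- transitivities(graph)
    if ("clustering" %in% metrics) {
      gl <- attr(clustering_coefficients(graph), "global")
      rec$clustering <- stats::setNames(gl$mean_defined, paste0("C_", gl$subtype))
    }
    if ("role_fingerprints" %in% metrics) {
      rec$role_fp <- fp_matrix(role_fingerprints(graph, "functional"))
    }
    rec
  }
  observed <- measure(g)
  reps <- purrr::map(seq_len(n_random), function(i) {
    measure(rewire_degree_preserving(g, seed = seed + i, attempts = attempts))
  })
  summarise_metric <- function(extract, names) {
    obs <- extract(observed)
    mat <- do.call(rbind, purrr::map(reps, extract))
    tibble(
      metric = names,
      observed = as.numeric(obs),
      null_mean = colMeans(mat),
      null_sd = apply(mat, 2, sd)
    )
  }
  summary <- list()
  if ("transitivity" %in% metrics) {
    summary$transitivity <- summarise_metric(
      function(r) unlist(r$transitivity), names(observed$transitivity)
    )
  }
  if ("clustering" %in% metrics) {
    summary$clustering <- summarise_metric(
      function(r) r$clustering, names(observed$clustering)
    )
  }
  structure(
    list(
      observed = observed, replicates = reps, summary = summary,
      n_random = n_random, seed = seed, metrics = metrics,
      n_nodes = n_nodes(g), n_edges = n_edges(g), graph = g
    ),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null ensemble: %d degree-preserving replicates of a %d-node, %d-edge digraph (seed %d)>\n",
              x$n_random, x$n_nodes, x$n_edges, x$seed))
  for (s in x$summary) print(s)
  invisible(x)
}

#' Per-node role overabundance against a null ensemble
#'
#' For every (node, role) pair, compares the observed functional role
#' fingerprint with its mean and standard deviation across the ensemble's
#' degree-preserving replicates. The excess (observed minus null mean),
#' optionally scaled by the node's total degree, flags nodes participating
#' in anomalously many instances of a role; nodes with zero total degree
#' report a scaled excess of 0.
#'
#' @param g The original [digraph()] (must match the ensemble source).
#' @param ensemble A `null_ensemble` built with
#'   `metrics = "role_fingerprints"`.
#' @param scale_by_degree Include the degree-scaled excess column.
#' @return A tibble with columns `node`, `label`, `role_id`, `observed`,
#'   `null_mean`, `null_sd`, `excess` and (optionally) `scaled_excess`,
#'   sorted by role then decreasing excess.
#' @export
overabundance <- function(g, ensemble, scale_by_degree = TRUE) {
  if (!inherits(ensemble, "null_ensemble") ||
      !"role_fingerprints" %in% ensemble$metrics) {
    abort("`ensemble` must be a null_ensemble built with metrics = 'role_fingerprints'")
  }
  obs <- ensemble$observed$role_fp
  stack <- purrr::map(ensemble$replicates, "role_fp")
  mean_m <- Reduce(`+`, stack) / length(stack)
  sd_m <- sqrt(Reduce(`+`, purrr::map(stack, ~ (.x - mean_m)^2)) /
                 max(1L, length(stack) - 1L))
  deg <- degree_table(g)
  out <- tibble(
    node = rep(seq_len(ncol(obs)), each = 30L),
    label = rep(node_labels(g), each = 30L),
    role_id = rep(1:30, ncol(obs)),
    observed = as.vector(obs),
    null_mean = as.vector(mean_m),
    null_sd = as.vector(sd_m)
  ) |>
    dplyr::mutate(excess = .data$observed - .data$null_mean)
  if (scale_by_degree) {
    d_tot <- deg$d_tot[out$node]
    out$scaled_excess <- ifelse(d_tot == 0, 0, out$excess / d_tot)
  }
  dplyr::arrange(out, .data$role_id, dplyr::desc(.data$excess))
}
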