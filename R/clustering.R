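#' Closed and potential directed triangles per node
#'
#' `closed` is half the diagonal of the cube of the symmetrized adjacency
#' matrix `A + t(A)` -- the total number of directed triangles of any
#' orientation in which each node participates, with reciprocal edges
#' contributing their full multiplicity. `potential` is
#' `d_tot * (d_tot - 1) - 2 * d_recip`, the maximum the closed count can
#' reach given the node's degrees; their ratio is the total directed
#' clustering coefficient.
#'
#' @param g A [digraph()].
#' @return A tibble with columns `node`, `label`, `closed`, `potential`.
#' @export
triangle_potential <- function(g) {
  A <- adjacency(g)
  storage.mode(A) <- "double"
  S <- A + t(A)
  b <- diag3(S, S, S) / 2
  deg <- degree_table(g)
  tibble(
    node = deg$node, label = deg$label,
    closed = as.integer(round(b)),
    potential = as.integer(deg$d_tot * (deg$d_tot - 1) - 2 * deg$d_recip)
  )
}

# integer weights over the 30 functional roles reproducing the closed
# directed triangle count: derived once by brute force over all 64 triple
# configurations and cached
triangle_role_weights <- function() {
  if (!is.null(the$tri_weights)) return(the$tri_weights)
  lk <- motif_catalog()$lookups
  pairs <- pair_order(3)
  rows <- list()
  rhs <- c()
  for (code in 0:63) {
    adj <- adj_from_code(code, 3, pairs)
    S <- adj + t(adj)
    b <- diag(S %*% S %*% S) / 2
    for (pos in 1:3) {
      rows[[length(rows) + 1]] <- lk$f_contrib[code + 1, pos, ]
      rhs <- c(rhs, b[pos])
    }
  }
  X <- do.call(rbind, rows)
  w <- qr.solve(X, rhs)
  w <- round(w, 9)
  if (max(abs(X %*% w - rhs)) > 1e-8) {
    abort("internal: no exact role-weight representation of the triangle count")
  }
  the$tri_weights <- w
  w
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

rid <- function(key) motif_catalog()$role_by_key[[key]]

# numerator / denominator vectors of the five subtype clustering
# coefficients plus the total, from a 30 x N functional role matrix
clustering_parts <- function(g, Fm) {
  tp <- triangle_potential(g)
  list(
    tot = list(num = tp$closed, den = tp$potential),
    `in` = list(num = 0.5 * Fm[rid("in-in|1|"), ], den = Fm[rid("in-in|0|"), ]),
    out = list(num = 0.5 * Fm[rid("out-out|1|"), ], den = Fm[rid("out-out|0|"), ]),
    mid = list(num = Fm[rid("in-out|1|ffl_mid"), ], den = Fm[rid("in-out|0|"), ]),
    cyc = list(num = Fm[rid("in-out|1|cycle"), ], den = Fm[rid("in-out|0|"), ]),
    `3ff` = list(
      num = Fm[rid("in-in|1|"), ] + Fm[rid("out-out|1|"), ] +
        Fm[rid("in-out|1|ffl_mid"), ],
      den = 2 * Fm[rid("in-in|0|"), ] + 2 * Fm[rid("out-out|0|"), ] +
        Fm[rid("in-out|0|"), ]
    )
  )
}

#' Directed clustering coefficients per node
#'
#' The total coefficient is the ratio of closed to potential directed
#' triangles ([triangle_potential()]); the five subtypes restrict the
#' numerator to triangles of one orientation class and the denominator to
#' the matching open configurations, all read off the functional
#' role-fingerprint matrix: `C_in = 0.5 * role11 / role10`,
#' `C_out = 0.5 * role14 / role13`, `C_mid = role18 / role16`,
#' `C_cyc = role17 / role16`, and the 3-feedforward blend
#' `C_3ff = (role11 + role14 + role18) / (2 role10 + 2 role13 + role16)`
#' (role ids as in [role_registry()]). The factors 0.5 reflect the two
#' edges that can close an open in-in or out-out wedge into a
#' feed-forward triangle. Any division by zero yields 0.
#'
#' Global means are attached for each subtype both over all nodes and over
#' the `n*` nodes whose denominator is nonzero (the headline variant);
#' retrieve them with [glance()].
#'
#' @param g A [digraph()].
#' @param flavor `"functional"` (the standard definition) or, as an
#'   experimental variant, `"structural"`, which plugs structural role
#'   counts into the same subtype formulas (the total coefficient is
#'   unchanged).
#' @return A tibble of class `directed_clustering` with columns `node`,
#'   `label`, `C_tot`, `C_in`, `C_out`, `C_mid`, `C_cyc`, `C_3ff`.
#' @examples
#' clustering_coefficients(toy_graph("ffl"))
#' @export
clustering_coefficients <- function(g, flavor = c("functional", "structural")) {
  flavor <- match.arg(flavor)
  Fm <- fp_matrix(role_fingerprints(g, flavor))
  parts <- clustering_parts(g, Fm)
  vals <- purrr::map(parts, ~ safe_div(.x$num, .x$den))
  out <- dplyr::bind_cols(
    tibble(node = seq_len(n_nodes(g)), label = node_labels(g)),
    stats::setNames(as_tibble(vals), paste0("C_", names(parts)))
  )
  global <- purrr::imap_dfr(parts, function(p, nm) {
    cc <- safe_div(p$num, p$den)
    defined <- p$den > 0
    tibble(
      subtype = nm,
      mean_all = mean(cc),
      mean_defined = if (any(defined)) mean(cc[defined]) else 0,
      n_defined = sum(defined)
    )
  })
  class(out) <- c("directed_clustering", class(out))
  attr(out, "global") <- global
  attr(out, "flavor") <- flavor
  out
}

#' Directed and undirected transitivities
#'
#' Each directed transitivity is the ratio of network-wide totals of the
#' corresponding clustering numerator and denominator (not the mean of
#' per-node ratios): total, in, out, middleman, cycle and 3-feedforward.
#' The cycle denominator is the total two-path count, which is identical
#' whichever of the three two-path roles is summed. The undirected
#' transitivity is computed from structural motif counts -- three times
#' the total count of the seven triangle-projection classes over the
#' triangle-weighted census of connected triples -- and equals the
#' standard transitivity of the direction-collapsed graph. Empty
#' denominators report 0 with a message.
#'
#' @param g A [digraph()].
#' @return A one-row tibble: `T_tot`, `T_in`, `T_out`, `T_mid`, `T_cyc`,
#'   `T_3ff`, `T_undirected`.
#' @examples
#' transitivities(toy_graph("cycle3"))
#' @export
transitivities <- function(g) {
  Fm <- fp_matrix(role_fingerprints(g, "functional"))
  parts <- clustering_parts(g, Fm)
  ratio <- function(p, nm) {
    den <- sum(p$den)
    if (den == 0) {
      inform(sprintf("empty denominator for %s transitivity; reporting 0", nm))
      return(0)
    }
    sum(p$num) / den
  }
  s_counts <- structural_motif_count_vector(Fm)
  tri <- triangle_class_ids()
  n_tri <- sum(s_counts[tri])
  n_open <- sum(s_counts[-tri])
  t_und <- if (3 * n_tri + n_open == 0) {
    inform("no connected triples; undirected transitivity reported 0")
    0
  } else {
    3 * n_tri / (3 * n_tri + n_open)
  }
  tibble(
    T_tot = ratio(parts$tot, "total"),
    T_in = ratio(parts$`in`, "in"),
    T_out = ratio(parts$out, "out"),
    T_mid = ratio(parts$mid, "middleman"),
    T_cyc = ratio(parts$cyc, "cycle"),
    T_3ff = ratio(parts$`3ff`, "3-feedforward"),
    T_undirected = t_und
  )
}

structural_motif_count_vector <- function(Fm) {
  Sm <- structural_from_functional(Fm)
  grp <- motif_catalog()$motif_of_role[as.character(1:30)]
  tot <- rowsum(rowSums(Sm), group = grp)
  as.vector(tot) / 3
}

# motif ids whose undirected projection is the closed triangle
triangle_class_ids <- function() {
  cat <- motif_catalog()
  which(vapply(1:13, function(m) {
    u <- (cat$classes_by_id[[m]]$adj + t(cat$classes_by_id[[m]]$adj)) > 0
    u[1, 2] && u[1, 3] && u[2, 3]
  }, TRUE))
}
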