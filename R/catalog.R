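#' The directed triad catalog
#'
#' Everything about three-node (and, for enumeration only, four-node)
#' connected directed graph classes is derived from first principles:
#' classes are found by enumerating every edge configuration on labelled
#' nodes, grouping by an exhaustive-permutation canonical form, and keeping
#' the weakly connected ones; node roles are the orbits of each class under
#' its automorphism group. A numbering registry then maps the 13 classes to
#' motif ids 1..13 and the 30 orbits to role ids 1..30 (see
#' [role_registry()]).
#'
#' @name catalog
NULL

# ordered node pairs underlying the bitmask encoding of a k-node digraph,
# in a fixed order so that a configuration code is reproducible
pair_order <- function(k) {
  idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  idx <- idx[idx$i != idx$j, ]
  idx <- idx[order(pmax(idx$i, idx$j), idx$i, idx$j), ]
  as.matrix(idx)
}
# for k = 3 this yields (1,2),(2,1),(1,3),(2,3),(3,1),(3,2) with bit values
# 1,2,4,8,16,32 in that order

adj_from_code <- function(code, k, pairs = pair_order(k)) {
  adj <- matrix(0L, k, k)
  bits <- as.integer(intToBits(code))[seq_len(nrow(pairs))]
  adj[pairs[bits == 1L, , drop = FALSE]] <- 1L
  adj
}

code_from_adj <- function(adj, pairs = pair_order(nrow(adj))) {
  sum(adj[pairs] * 2^(seq_len(nrow(pairs)) - 1L))
}

is_weakly_connected <- function(adj) {
  k <- nrow(adj)
  u <- (adj + t(adj)) > 0
  reach <- diag(k) > 0
  for (step in seq_len(k - 1)) reach <- reach | (reach %*% u) > 0
  all(reach[1, ])
}

adj_key <- function(adj) paste(as.integer(adj), collapse = "")

#' Canonical form of a small directed edge set
#'
#' Two edge sets receive the same key iff they are isomorphic as directed
#' graphs; the key is the lexicographic minimum of the vectorized adjacency
#' matrix over all node permutations (exhaustive, so only `k <= 4` is
#' supported).
#'
#' @param edges A two-column matrix/data frame of ordered pairs on nodes
#'   `1..k`, or a `k x k` adjacency matrix.
#' @param k Number of nodes (inferred from an adjacency matrix).
#' @return A character key, invariant under relabeling.
#' @export
canonical_form <- function(edges, k = NULL) {
  if (is.matrix(edges) && nrow(edges) == ncol(edges) &&
      (is.null(k) || k == nrow(edges)) && all(edges %in% c(0L, 1L)) &&
      !(nrow(edges) == 2 && is.null(k))) {
    adj <- edges
    k <- nrow(adj)
  } else {
    edges <- as.matrix(edges)
    k <- k %||% max(edges)
    adj <- matrix(0L, k, k)
    if (nrow(edges)) adj[edges] <- 1L
  }
  if (k > 4) abort("canonical_form() supports at most 4 nodes")
  if (any(diag(adj) != 0)) abort("self-loops are not allowed")
  perms <- perms_of(k)
  min(vapply(seq_len(nrow(perms)), function(i) {
    p <- perms[i, ]
    adj_key(adj[p, p])
  }, ""))
}

perms_of <- function(k) {
  key <- paste0("perms", k)
  if (is.null(the[[key]])) {
    pl <- list(seq_len(k))
    if (k > 1) {
      pl <- do.call(rbind, lapply(seq_len(k), function(first) {
        rest <- perms_of(k - 1)
        cbind(first, matrix(setdiff(seq_len(k), first)[rest], nrow(rest)))
      }))
      the[[key]] <- unname(pl)
    } else {
      the[[key]] <- matrix(1L, 1, 1)
    }
  }
  the[[key]]
}

#' Enumerate connected motif classes
#'
#' Enumerates all `2^(k(k-1))` directed graphs on `k` labelled nodes, keeps
#' the weakly connected ones and groups them by [canonical_form()]. For
#' `k = 3` this yields the 13 triad classes; for `k = 4`, 199 classes.
#'
#' @param k Subgraph size, 3 or 4.
#' @return A list of motif classes sorted by (edge count, canonical key).
#'   Each class is a list with `canonical_key`, `adj` (canonical
#'   representative), `edges`, `edge_count`, `automorphisms` (list of
#'   permutations) and `n_labelled` (number of labelled configurations).
#' @export
enumerate_motif_classes <- function(k = 3) {
  if (!k %in% c(3, 4)) abort("`k` must be 3 or 4")
  cache_key <- paste0("classes", k)
  if (!is.null(the[[cache_key]])) return(the[[cache_key]])
  pairs <- pair_order(k)
  perms <- perms_of(k)
  groups <- new.env(parent = emptyenv())
  for (code in seq_len(2^nrow(pairs)) - 1L) {
    adj <- adj_from_code(code, k, pairs)
    if (!is_weakly_connected(adj)) next
    key <- min(vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      adj_key(adj[p, p])
    }, ""))
    groups[[key]] <- (groups[[key]] %||% 0L) + 1L
  }
  keys <- ls(groups)
  classes <- lapply(keys, function(key) {
    adj <- matrix(as.integer(strsplit(key, "")[[1]]), k, k)
    autos <- lapply(seq_len(nrow(perms)), function(i) perms[i, ])
    autos <- autos[vapply(autos, function(p) identical(adj[p, p], adj), TRUE)]
    e <- which(adj == 1L, arr.ind = TRUE)
    list(
      k = k,
      canonical_key = key,
      adj = adj,
      edges = unname(e[order(e[, 1], e[, 2]), , drop = FALSE]),
      edge_count = sum(adj),
      automorphisms = autos,
      n_labelled = groups[[key]]
    )
  })
  ord <- order(
    vapply(classes, `[[`, 0L, "edge_count"),
    vapply(classes, `[[`, "", "canonical_key")
  )
  classes <- classes[ord]
  the[[cache_key]] <- classes
  classes
}

#' Node orbits of a motif class
#'
#' Partitions the nodes of the canonical representative into equivalence
#' classes (orbits) under the automorphism group. The orbit sizes are the
#' role pluralities and always sum to `k`.
#'
#' @param motif A motif class from [enumerate_motif_classes()].
#' @return A list of orbits, each with `positions`, `plurality`, and (for
#'   `k = 3`) the ego-pattern descriptor used by the numbering registry.
#' @export
orbits_of <- function(motif) {
  k <- motif$k
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (p in motif$automorphisms) {
    for (v in seq_len(k)) {
      a <- find(v); b <- find(p[v])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  lapply(sort(unique(roots)), function(r) {
    pos <- which(roots == r)
    orb <- list(positions = pos, plurality = length(pos))
    if (k == 3) orb <- c(orb, orbit_descriptor(motif$adj, pos[1]))
    orb
  })
}

# ego-pattern descriptor of a node within a 3-node motif: the multiset of
# the reference node's pair states, the number of edges between the two
# non-reference nodes, and an orientation variant that distinguishes the
# two single-cross-edge roles of the asymmetric families
orbit_descriptor <- function(adj, v) {
  others <- setdiff(1:3, v)
  state <- vapply(others, function(u) {
    fw <- adj[v, u]; bw <- adj[u, v]
    if (fw & bw) "recip" else if (fw) "out" else if (bw) "in" else "none"
  }, "")
  ego <- state[state != "none"]
  # sort so that family strings read "in-out", "recip-out", "recip-in"
  ego <- ego[order(match(ego, c("recip", "in", "out")))]
  family <- paste(ego, collapse = "-")
  cross <- adj[others[1], others[2]] + adj[others[2], others[1]]
  variant <- ""
  if (cross == 1L) {
    if (length(ego) == 1L) {
      b <- others[state != "none"]
      cc <- others[state == "none"]
      variant <- if (adj[b, cc] == 1L) "b2c" else "c2b"
    } else if (family == "in-out") {
      b <- others[state == "in"]   # in-neighbor of the reference node
      cc <- others[state == "out"] # out-neighbor
      variant <- if (adj[b, cc] == 1L) "ffl_mid" else "cycle"
    } else if (family %in% c("recip-out", "recip-in")) {
      b <- others[state == "recip"] # reciprocal partner
      cc <- others[state != "recip"]
      variant <- if (adj[b, cc] == 1L) "p2o" else "o2p"
    }
    # symmetric families (in-in, out-out, recip-recip): both orientations
    # are the same orbit, no variant needed
  }
  list(family = family, cross_count = as.integer(cross), variant = variant,
       ego_pattern = paste(ego, collapse = "+"))
}

role_key <- function(family, cross_count, variant) {
  paste(family, cross_count, variant, sep = "|")
}

# canonical keys of the four prose-pinned motif classes
pinned_motif_keys <- function() {
  list(
    two_path = canonical_form(rbind(c(1, 2), c(2, 3)), k = 3),
    cycle = canonical_form(rbind(c(1, 2), c(2, 3), c(3, 1)), k = 3),
    ffl = canonical_form(rbind(c(1, 2), c(1, 3), c(2, 3)), k = 3),
    complete = canonical_form(rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1),
                                    c(2, 3), c(3, 2)), k = 3)
  )
}

#' Build the motif/role numbering registry
#'
#' Fixes the bijections from canonical triad classes to motif ids 1..13 and
#' from orbits to role ids 1..30. Anchors stated in prose are enforced and
#' violations raise an error naming the anchor: motif 2 is the two-path,
#' motif 5 the cyclic triangle, motif 9 the feed-forward triangle, motif 13
#' the fully reciprocal triad; role 10 (two in-edges), role 13 (two
#' out-edges) and role 16 (two-path middle) are the clustering
#' denominators, role 14 adds the destination-destination edge to role 13,
#' role 28 is the open two-reciprocal-partner role and role 30 the complete
#' triad role. Unpinned motif ids fill the remaining slots by (edge count,
#' canonical key); role ids follow the nine ego-pattern families, ordered
#' within a family by (cross-edge count, motif id).
#'
#' @param classes Output of [enumerate_motif_classes()] for `k = 3`.
#' @return A list with `motif_map` (canonical key -> motif id), `registry`
#'   (a tibble, see [role_registry()]) and `classes`.
#' @export
build_numbering <- function(classes = enumerate_motif_classes(3)) {
  if (length(classes) != 13) {
    abort(sprintf("expected 13 triad classes, got %d", length(classes)))
  }
  keys <- vapply(classes, `[[`, "", "canonical_key")
  pins <- pinned_motif_keys()
  pinned_ids <- c(two_path = 2L, cycle = 5L, ffl = 9L, complete = 13L)
  motif_id <- rep(NA_integer_, 13)
  for (nm in names(pins)) {
    hit <- which(keys == pins[[nm]])
    if (length(hit) != 1) abort(sprintf("anchor violated: motif '%s' not found", nm))
    motif_id[hit] <- pinned_ids[[nm]]
  }
  free_slots <- setdiff(1:13, pinned_ids)
  motif_id[is.na(motif_id)] <- free_slots # classes already sorted
  names(motif_id) <- keys

  fam_order <- c("out", "in", "recip", "in-in", "out-out", "in-out",
                 "recip-out", "recip-in", "recip-recip")
  rows <- purrr::map2_dfr(classes, motif_id, function(cl, mid) {
    purrr::map_dfr(orbits_of(cl), function(orb) {
      tibble(
        motif_id = mid,
        motif_key = cl$canonical_key,
        edge_count = cl$edge_count,
        family = orb$family,
        cross_count = orb$cross_count,
        variant = orb$variant,
        ego_pattern = orb$ego_pattern,
        plurality = orb$plurality,
        position = orb$positions[1]
      )
    })
  })
  if (nrow(rows) != 30) abort(sprintf("expected 30 orbits, got %d", nrow(rows)))
  rows <- rows |>
    dplyr::mutate(fam_rank = match(.data$family, fam_order)) |>
    dplyr::arrange(.data$fam_rank, .data$cross_count, .data$motif_id) |>
    dplyr::mutate(role_id = dplyr::row_number()) |>
    dplyr::select(-"fam_rank") |>
    dplyr::relocate("role_id")

  anchor <- function(id, family, cross, what) {
    row <- rows[rows$role_id == id, ]
    if (row$family != family || row$cross_count != cross) {
      abort(sprintf("anchor violated: role %d should be %s", id, what))
    }
  }
  anchor(10L, "in-in", 0L, "two in-edges, no cross edge")
  anchor(13L, "out-out", 0L, "two out-edges, no cross edge")
  anchor(14L, "out-out", 1L, "two out-edges plus destination-destination edge")
  anchor(16L, "in-out", 0L, "two-path middle, no cross edge")
  anchor(28L, "recip-recip", 0L, "two reciprocal partners, no cross edge")
  anchor(30L, "recip-recip", 2L, "complete-triad role")
  if (rows$motif_id[rows$role_id == 30L] != 13L) {
    abort("anchor violated: role 30 must belong to motif 13")
  }
  rkeys <- role_key(rows$family, rows$cross_count, rows$variant)
  if (anyDuplicated(rkeys)) {
    abort("role descriptor keys are not unique; registry is ill-formed")
  }
  list(motif_map = motif_id, registry = rows, classes = classes)
}

# full cached catalog: classes, numbering, descriptor lookups, and the
# 64-configuration role lookup tables used by the brute-force counters
motif_catalog <- function() {
  if (!is.null(the$catalog)) return(the$catalog)
  num <- build_numbering(enumerate_motif_classes(3))
  reg <- num$registry
  role_by_key <- stats::setNames(
    reg$role_id, role_key(reg$family, reg$cross_count, reg$variant)
  )
  motif_of_role <- stats::setNames(reg$motif_id, reg$role_id)
  plurality <- stats::setNames(reg$plurality, reg$role_id)
  # classes indexed by motif id
  classes_by_id <- vector("list", 13)
  for (cl in num$classes) classes_by_id[[num$motif_map[[cl$canonical_key]]]] <- cl

  cat <- list(
    classes = num$classes,
    classes_by_id = classes_by_id,
    motif_map = num$motif_map,
    registry = reg,
    role_by_key = role_by_key,
    motif_of_role = motif_of_role,
    plurality = plurality
  )
  cat$lookups <- build_config_lookups(cat)
  the$catalog <- cat
  cat
}

# role id of node `pos` in the 3-node graph encoded by `adj`, or NA if the
# graph is not weakly connected
role_of_position <- function(adj, pos, cat) {
  if (!is_weakly_connected(adj)) return(NA_integer_)
  d <- orbit_descriptor(adj, pos)
  unname(cat$role_by_key[[role_key(d$family, d$cross_count, d$variant)]])
}

# For each of the 64 labelled triple configurations, precompute
#  * structural role of each of the 3 positions (NA when disconnected), and
#  * the functional role contribution vector of each position, obtained by
#    enumerating every connected spanning edge subset of the configuration.
# These tables make the O(N^3) brute-force counter a pure lookup and are
# fully independent of the algebraic fast path.
build_config_lookups <- function(cat) {
  pairs <- pair_order(3)
  s_role <- matrix(NA_integer_, 64, 3)
  f_contrib <- array(0L, dim = c(64, 3, 30))
  motif_of_code <- rep(NA_integer_, 64)
  for (code in 0:63) {
    adj <- adj_from_code(code, 3, pairs)
    if (is_weakly_connected(adj)) {
      motif_of_code[code + 1] <- cat$motif_map[[canonical_form(adj)]]
      for (pos in 1:3) s_role[code + 1, pos] <- role_of_position(adj, pos, cat)
    }
    sub <- code
    repeat {
      sadj <- adj_from_code(sub, 3, pairs)
      if (is_weakly_connected(sadj)) {
        for (pos in 1:3) {
          rid <- role_of_position(sadj, pos, cat)
          f_contrib[code + 1, pos, rid] <- f_contrib[code + 1, pos, rid] + 1L
        }
      }
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, code)
    }
  }
  list(s_role = s_role, f_contrib = f_contrib, motif_of_code = motif_of_code)
}

#' The role numbering registry as a table
#'
#' One row per role id 1..30: the motif it belongs to, the ego pattern of
#' the reference node (its connections to the two other nodes, each `out`,
#' `in` or `recip`), the number of required cross edges between the two
#' non-reference nodes, the orientation variant for the asymmetric
#' single-cross roles, and the plurality (number of nodes of one motif
#' occurrence playing this role). The same table is shipped, bit-exact, as
#' `extdata/role_registry.tsv`.
#'
#' @return A tibble with 30 rows.
#' @export
role_registry <- function() {
  motif_catalog()$registry |>
    dplyr::select("role_id", "motif_id", "ego_pattern", "cross_count",
                  "variant", "plurality", "motif_key")
}

#' @rdname role_registry
#' @param path Output TSV path.
#' @export
write_role_registry <- function(path) {
  readr::write_tsv(role_registry(), path)
  invisible(path)
}
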