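#' Motif-role fingerprints per node
#'
#' The role fingerprint of node *i* is the 30-vector counting, for every
#' role id, the subgraph occurrences on node triples containing *i* in
#' which *i* plays that role. Two flavors exist: `functional` counts
#' partial (edge-subset) occurrences -- every connected pattern whose edges
#' are present counts, one per distinct edge set -- while `structural`
#' counts induced occurrences -- each connected triple is classified by
#' exactly the edges present. Structural counts are therefore never larger
#' than functional ones, and the two are linked by the exact conversion
#' matrix of [role_conversion_matrix()].
#'
#' The default method computes functional fingerprints by dense matrix
#' algebra (at most one `N x N` matrix product plus a Hadamard product per
#' role family, using the reciprocal-edge matrix) and obtains structural
#' fingerprints through the integer conversion matrix; `method =
#' "bruteforce"` enumerates all node triples and is the independent oracle
#' the fast path is tested against.
#'
#' @param g A [digraph()].
#' @param flavor `"functional"` or `"structural"`.
#' @param method `"fast"` (default) or `"bruteforce"`.
#' @param max_bruteforce_nodes Guard for the `O(N^3)` path.
#' @return A tibble of class `role_fp` with columns `node`, `label`,
#'   `role_1` ... `role_30`, and attribute `flavor`.
#' @examples
#' role_fingerprints(toy_graph("ffl"))
#' @export
role_fingerprints <- function(g, flavor = c("functional", "structural"),
                              method = c("fast", "bruteforce"),
                              max_bruteforce_nodes = 2000) {
  flavor <- match.arg(flavor)
  method <- match.arg(method)
  m <- switch(method,
    fast = {
      f <- functional_fp_matrix(adjacency(g))
      if (flavor == "structural") structural_from_functional(f) else f
    },
    bruteforce = bruteforce_fp_matrix(g, flavor, max_bruteforce_nodes)
  )
  fp_tibble(m, g, flavor)
}

fp_tibble <- function(m, g, flavor) {
  df <- as_tibble(as.data.frame(t(m)), .name_repair = "minimal")
  names(df) <- paste0("role_", seq_len(30))
  out <- dplyr::bind_cols(
    tibble(node = seq_len(n_nodes(g)), label = node_labels(g)), df
  )
  class(out) <- c("role_fp", class(out))
  attr(out, "flavor") <- flavor
  out
}

#' Extract the numeric matrix from a fingerprint table
#'
#' @param x A `role_fp` or `motif_fp` tibble.
#' @return An `L x N` (roles by nodes) or `M x N` (motifs by nodes) integer
#'   matrix.
#' @export
fp_matrix <- function(x) {
  cols <- grep("^(role|motif)_", names(x))
  m <- t(as.matrix(x[, cols]))
  storage.mode(m) <- "integer"
  rownames(m) <- names(x)[cols]
  colnames(m) <- NULL
  m
}

fp_flavor <- function(x) attr(x, "flavor")

# diag(X %*% Y %*% Z) without forming the triple product
diag3 <- function(X, Y, Z) rowSums((X %*% Y) * t(Z))

# Functional role-fingerprint matrix (30 x N) by dense matrix algebra.
# One closed-form expression per (family, variant) cell of the registry;
# row placement is looked up from the registry so the formulas stay valid
# whatever the tie-break numbering.
functional_fp_matrix <- function(A) {
  storage.mode(A) <- "double"
  tA <- t(A)
  R <- A * tA
  d_out <- rowSums(A)
  d_in <- colSums(A)
  r <- rowSums(R)
  ones <- rep(1, nrow(A))

  vals <- list(
    # single-connection families: reference node touches one node b; the
    # third node c hangs off b
    "out|1|b2c" = as.vector(A %*% d_out) - r,        # i->b->c
    "out|1|c2b" = as.vector(A %*% (d_in - 1)),        # i->b<-c
    "out|2|" = as.vector(A %*% r) - r,             # i->b<->c
    "in|1|c2b" = as.vector(tA %*% d_in) - r,          # c->b->i
    "in|1|b2c" = as.vector(tA %*% (d_out - 1)),       # i<-b->c
    "in|2|" = as.vector(tA %*% r) - r,             # c<->b->i
    "recip|1|b2c" = as.vector(R %*% d_out) - r,       # i<->b->c
    "recip|1|c2b" = as.vector(R %*% d_in) - r,        # i<->b<-c
    "recip|2|" = as.vector(R %*% r) - r,           # i<->b<->c
    # two-in family
    "in-in|0|" = choose(d_in, 2),
    "in-in|1|" = diag3(tA, A, A),                     # feed-forward sink
    "in-in|2|" = 0.5 * diag3(tA, R, A),
    # two-out family
    "out-out|0|" = choose(d_out, 2),
    "out-out|1|" = diag3(A, A, tA),                   # feed-forward source
    "out-out|2|" = 0.5 * diag3(A, R, tA),
    # through-flow family b -> i -> c
    "in-out|0|" = d_in * d_out - r,
    "in-out|1|cycle" = diag3(A, A, A),
    "in-out|1|ffl_mid" = diag3(tA, A, tA),            # feed-forward middle
    "in-out|2|" = diag3(tA, R, tA),
    # reciprocal partner + plain out-neighbor
    "recip-out|0|" = r * (d_out - 1),
    "recip-out|1|p2o" = diag3(R, A, tA),
    "recip-out|1|o2p" = diag3(R, tA, tA),
    "recip-out|2|" = diag3(R, R, tA),
    # reciprocal partner + plain in-neighbor
    "recip-in|0|" = r * (d_in - 1),
    "recip-in|1|p2o" = diag3(R, A, A),
    "recip-in|1|o2p" = diag3(R, tA, A),
    "recip-in|2|" = diag3(R, R, A),
    # two reciprocal partners
    "recip-recip|0|" = choose(r, 2),
    "recip-recip|1|" = diag3(R, A, R),
    "recip-recip|2|" = 0.5 * diag3(R, R, R)
  )
  cat <- motif_catalog()
  out <- matrix(0L, 30, nrow(A))
  for (key in names(vals)) {
    rid <- cat$role_by_key[[key]]
    if (is.null(rid)) abort(sprintf("internal: no registry role for '%s'", key))
    out[rid, ] <- as.integer(round(vals[[key]]))
  }
  out
}

structural_from_functional <- function(f_mat) {
  Tinv <- invert_conversion(role_conversion_matrix())
  s <- conversion_values(Tinv) %*% f_mat
  if (any(abs(s - round(s)) > 1e-9) || any(round(s) < 0)) {
    abort("conversion produced negative or non-integer structural counts; input was not a realizable functional fingerprint")
  }
  s <- round(s)
  storage.mode(s) <- "integer"
  s
}

# Brute-force oracle: enumerate all C(N,3) node triples, encode each as a
# 6-bit configuration, and accumulate the precomputed per-position role
# contributions (structural: the induced class's orbit; functional: every
# connected spanning edge subset).
bruteforce_fp_matrix <- function(g, flavor, max_nodes = 2000) {
  n <- n_nodes(g)
  if (n > max_nodes) {
    abort(sprintf(
      "brute-force fingerprints guard: %d nodes > limit %d; use method = 'fast'",
      n, max_nodes
    ))
  }
  counts <- matrix(0L, 30, n)
  if (n < 3) return(counts)
  A <- adjacency(g)
  lk <- motif_catalog()$lookups
  tri <- combn(n, 3)
  i <- tri[1, ]; j <- tri[2, ]; k <- tri[3, ]
  code <- A[cbind(i, j)] + 2L * A[cbind(j, i)] + 4L * A[cbind(i, k)] +
    8L * A[cbind(j, k)] + 16L * A[cbind(k, i)] + 32L * A[cbind(k, j)]
  nodes_at <- list(i, j, k)
  for (pos in 1:3) {
    node <- nodes_at[[pos]]
    if (flavor == "structural") {
      rid <- lk$s_role[code + 1L, pos]
      ok <- !is.na(rid)
      if (any(ok)) {
        tab <- tabulate((node[ok] - 1L) * 30L + rid[ok], nbins = 30L * n)
        counts <- counts + matrix(tab, 30, n)
      }
    } else {
      contrib <- lk$f_contrib[code + 1L, pos, , drop = FALSE]
      dim(contrib) <- c(length(code), 30)
      agg <- rowsum(contrib, group = node)
      counts[, as.integer(rownames(agg))] <-
        counts[, as.integer(rownames(agg))] + t(agg)
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

# bit layout used above must match pair_order(3); checked in the tests

#' Aggregate role fingerprints to motif fingerprints
#'
#' Sums, for every motif, the counts of its roles; entry `(m, i)` is then
#' the number of (functional or structural) occurrences of motif `m` in
#' which node `i` participates.
#'
#' @param rfp A `role_fp` tibble from [role_fingerprints()].
#' @return A tibble of class `motif_fp` with columns `node`, `label`,
#'   `motif_1` ... `motif_13`, same flavor attribute.
#' @export
motif_fingerprints <- function(rfp) {
  cat <- motif_catalog()
  m <- fp_matrix(rfp)
  agg <- rowsum(m, group = cat$motif_of_role[as.character(1:30)])
  df <- as_tibble(as.data.frame(t(agg)), .name_repair = "minimal")
  names(df) <- paste0("motif_", 1:13)
  out <- dplyr::bind_cols(tibble(node = rfp$node, label = rfp$label), df)
  class(out) <- c("motif_fp", "tbl_df", "tbl", "data.frame")
  attr(out, "flavor") <- fp_flavor(rfp)
  out
}

#' Global motif and motif-role counts
#'
#' `motif_counts()` sums motif fingerprints over all nodes and divides by
#' three (each motif occurrence appears in exactly three fingerprints); a
#' non-integral result signals a counting bug and is an error.
#' `role_counts()` sums role fingerprints over nodes.
#'
#' @param mfp A `motif_fp` tibble.
#' @param rfp A `role_fp` tibble.
#' @return A tibble of class `count_vector` with columns `id`, `count`;
#'   attributes `level` (`"motif"`/`"role"`) and `flavor`.
#' @export
motif_counts <- function(mfp) {
  tot <- rowSums(fp_matrix(mfp))
  if (any(tot %% 3 != 0)) {
    abort("motif fingerprint row sums not divisible by 3; counting bug")
  }
  count_vector(as.integer(tot / 3), "motif", fp_flavor(mfp))
}

#' @rdname motif_counts
#' @export
role_counts <- function(rfp) {
  count_vector(as.integer(rowSums(fp_matrix(rfp))), "role", fp_flavor(rfp))
}

count_vector <- function(counts, level, flavor) {
  out <- tibble(id = seq_along(counts), count = counts)
  class(out) <- c("count_vector", class(out))
  attr(out, "level") <- level
  attr(out, "flavor") <- flavor
  out
}

#' Role-layout matrix linking role counts and motif counts
#'
#' A 13 x 3 table whose row *m* holds the global counts of motif *m*'s
#' roles (up to three orbits, zero-padded). Because a role's global count
#' equals its plurality times the motif count, rows with three nonzero
#' entries have all entries equal, two-entry rows have one entry twice the
#' other, and single-entry rows carry a factor 3. Dividing the row sums by
#' three recovers the motif counts ([layout_motif_counts()]), and motif
#' counts expand back to role counts via the pluralities
#' ([role_counts_from_motif_counts()]).
#'
#' @param counts A role-level `count_vector`.
#' @return A tibble of class `role_layout`: `motif_id`, `role_id_1..3`,
#'   `count_1..3`.
#' @export
role_layout <- function(counts) {
  stopifnot(attr(counts, "level") == "role")
  reg <- motif_catalog()$registry
  slots <- reg |>
    dplyr::left_join(counts, by = c(role_id = "id")) |>
    dplyr::arrange(.data$motif_id, .data$role_id) |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::summarise(
      role_ids = list(.data$role_id),
      counts = list(.data$count)
    )
  pad <- function(x) c(x, rep(0L, 3 - length(x)))
  out <- tibble(
    motif_id = slots$motif_id,
    role_id_1 = purrr::map_int(slots$role_ids, ~ pad(.x)[1]),
    role_id_2 = purrr::map_int(slots$role_ids, ~ pad(.x)[2]),
    role_id_3 = purrr::map_int(slots$role_ids, ~ pad(.x)[3]),
    count_1 = purrr::map_int(slots$counts, ~ pad(.x)[1]),
    count_2 = purrr::map_int(slots$counts, ~ pad(.x)[2]),
    count_3 = purrr::map_int(slots$counts, ~ pad(.x)[3])
  )
  class(out) <- c("role_layout", class(out))
  attr(out, "flavor") <- attr(counts, "flavor")
  out
}

#' @rdname role_layout
#' @param layout A `role_layout` tibble.
#' @export
layout_motif_counts <- function(layout) {
  tot <- layout$count_1 + layout$count_2 + layout$count_3
  if (any(tot %% 3 != 0)) abort("layout row sums not divisible by 3")
  count_vector(as.integer(tot / 3), "motif", attr(layout, "flavor"))
}

#' @rdname role_layout
#' @param motif A motif-level `count_vector`.
#' @export
role_counts_from_motif_counts <- function(motif) {
  stopifnot(attr(motif, "level") == "motif")
  cat <- motif_catalog()
  reg <- cat$registry
  counts <- reg$plurality[order(reg$role_id)] *
    motif$count[reg$motif_id[order(reg$role_id)]]
  count_vector(as.integer(counts), "role", attr(motif, "flavor"))
}

#' Write a fingerprint table as TSV
#'
#' Columns `node_id`, `node_label`, then `role_1..role_30` (or
#' `motif_1..motif_13`); the flavor is recorded in a `#` header comment.
#'
#' @param fp A `role_fp` or `motif_fp` tibble.
#' @param path Output path.
#' @export
write_fingerprints <- function(fp, path) {
  out <- dplyr::rename(fp, node_id = "node", node_label = "label")
  readr::write_lines(sprintf("# flavor: %s", fp_flavor(fp)), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
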