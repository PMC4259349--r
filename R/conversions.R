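#' Functional/structural conversion matrices
#'
#' A structural occurrence of a motif contains, as edge subsets, one or
#' more functional occurrences of (usually smaller) motifs. Counting those
#' containments per role gives a 30 x 30 integer matrix `T` with
#' `functional = T %*% structural` for every role-fingerprint column, and
#' analogously a 13 x 13 matrix at motif level. Both matrices have unit
#' diagonal, are triangular once roles/motifs are sorted by edge count of
#' the source motif, and have determinant +-1 (unimodular), so their
#' inverses are integer matrices and a unique structural statistic exists
#' for every functional one.
#'
#' `role_conversion_matrix()` and `motif_conversion_matrix()` derive the
#' structural-to-functional matrices by exhaustive edge-subset enumeration
#' (at most `2^6` subsets per motif); [invert_conversion()] returns the
#' exact integer inverse; [apply_conversion()] applies a matrix to a
#' fingerprint table or count vector; [empirical_conversion()] re-derives
#' the matrices blindly from random-network data.
#'
#' @return A square integer matrix of class `conversion_matrix` with
#'   attributes `level` (`"role"`/`"motif"`) and `direction`
#'   (`"structural_to_functional"` or `"functional_to_structural"`).
#' @examples
#' T_R <- role_conversion_matrix()
#' all(diag(T_R) == 1)
#' @export
role_conversion_matrix <- function() {
  if (is.null(the$role_conv)) {
    the$role_conv <- derive_conversion("role")
  }
  the$role_conv
}

#' @rdname role_conversion_matrix
#' @export
motif_conversion_matrix <- function() {
  if (is.null(the$motif_conv)) {
    the$motif_conv <- derive_conversion("motif")
  }
  the$motif_conv
}

new_conversion <- function(values, level, direction) {
  storage.mode(values) <- "integer"
  structure(values, class = "conversion_matrix", level = level,
            direction = direction)
}

conversion_values <- function(x) {
  v <- unclass(x)
  attributes(v) <- list(dim = dim(x), dimnames = dimnames(x))
  v
}

#' @export
print.conversion_matrix <- function(x, ...) {
  cat(sprintf("<%s-level conversion matrix, %s>\n", attr(x, "level"),
              gsub("_", " ", attr(x, "direction"))))
  print(conversion_values(x))
  invisible(x)
}

# exhaustive derivation: for every structural role (motif class + orbit
# representative), enumerate the connected spanning edge subsets of the
# motif and classify the reference node's role in each subset
derive_conversion <- function(level = c("role", "motif")) {
  level <- match.arg(level)
  cat <- motif_catalog()
  pairs <- pair_order(3)
  if (level == "motif") {
    M <- matrix(0L, 13, 13)
    for (s in 1:13) {
      code <- code_from_adj(cat$classes_by_id[[s]]$adj, pairs)
      sub <- code
      repeat {
        f <- cat$lookups$motif_of_code[sub + 1L]
        if (!is.na(f)) M[f, s] <- M[f, s] + 1L
        if (sub == 0L) break
        sub <- bitwAnd(sub - 1L, code)
      }
    }
    dimnames(M) <- list(paste0("f", 1:13), paste0("s", 1:13))
    return(new_conversion(M, "motif", "structural_to_functional"))
  }
  reg <- cat$registry
  M <- matrix(0L, 30, 30)
  for (idx in seq_len(nrow(reg))) {
    s_id <- reg$role_id[idx]
    cl_adj <- matrix(as.integer(strsplit(reg$motif_key[idx], "")[[1]]), 3, 3)
    ref <- reg$position[idx]
    code <- code_from_adj(cl_adj, pairs)
    sub <- code
    repeat {
      sadj <- adj_from_code(sub, 3, pairs)
      if (is_weakly_connected(sadj)) {
        f_id <- role_of_position(sadj, ref, cat)
        M[f_id, s_id] <- M[f_id, s_id] + 1L
      }
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, code)
    }
  }
  dimnames(M) <- list(paste0("f", 1:30), paste0("s", 1:30))
  new_conversion(M, "role", "structural_to_functional")
}

#' Exact integer inverse of a conversion matrix
#'
#' Errors if the input is not unimodular (determinant +-1), which would
#' signal a derivation bug; the returned inverse satisfies
#' `T %*% invert_conversion(T) == I` exactly in integer arithmetic.
#'
#' @param x A `conversion_matrix`.
#' @return The inverse `conversion_matrix` with the opposite direction.
#' @export
invert_conversion <- function(x) {
  v <- conversion_values(x)
  dt <- round(det(v))
  if (abs(dt) != 1) {
    abort(sprintf("conversion matrix is not unimodular (det = %g)", dt))
  }
  inv <- round(solve(v))
  if (any(inv %*% v != diag(nrow(v)))) {
    abort("integer inverse failed exact verification")
  }
  direction <- if (attr(x, "direction") == "structural_to_functional") {
    "functional_to_structural"
  } else {
    "structural_to_functional"
  }
  new_conversion(inv, attr(x, "level"), direction)
}

#' Convert a statistic between the functional and structural flavors
#'
#' Left-multiplies the role/motif dimension of a fingerprint table or
#' count vector by a conversion matrix. The matrix direction must match
#' the statistic's flavor (a structural-to-functional matrix applies to a
#' structural statistic). Converting towards the structural flavor
#' validates that the result is nonnegative integer; a violation means the
#' input was not a realizable functional statistic and is an error.
#'
#' @param stat A `role_fp`, `motif_fp` or `count_vector`.
#' @param conversion A `conversion_matrix`; by default the correct
#'   derived matrix for the statistic's level and flavor.
#' @return The same-shaped statistic with the opposite flavor.
#' @examples
#' f <- role_fingerprints(toy_graph("cycle3"), "functional")
#' s <- apply_conversion(f)
#' attr(s, "flavor")
#' @export
apply_conversion <- function(stat, conversion = NULL) {
  level <- if (inherits(stat, "count_vector")) {
    attr(stat, "level")
  } else if (inherits(stat, "role_fp")) "role" else if (inherits(stat, "motif_fp")) {
    "motif"
  } else {
    abort("`stat` must be a role_fp, motif_fp or count_vector")
  }
  flavor <- attr(stat, "flavor")
  base <- if (level == "role") role_conversion_matrix() else motif_conversion_matrix()
  if (is.null(conversion)) {
    conversion <- if (flavor == "structural") base else invert_conversion(base)
  }
  if (attr(conversion, "level") != level) {
    abort(sprintf("conversion level '%s' does not match statistic level '%s'",
                  attr(conversion, "level"), level))
  }
  from <- sub("_to.*", "", attr(conversion, "direction"))
  if (from != flavor) {
    abort(sprintf("conversion converts from '%s' but statistic is '%s'", from, flavor))
  }
  to <- sub(".*_to_", "", attr(conversion, "direction"))
  v <- conversion_values(conversion)
  if (inherits(stat, "count_vector")) {
    res <- as.vector(v %*% stat$count)
    check_integral(res, to)
    out <- count_vector(as.integer(round(res)), level, to)
    return(out)
  }
  m <- v %*% fp_matrix(stat)
  check_integral(m, to)
  m <- round(m)
  out <- stat
  cols <- grep(paste0("^", level, "_"), names(stat))
  out[, cols] <- as.data.frame(t(m))
  attr(out, "flavor") <- to
  out
}

check_integral <- function(x, to) {
  if (any(abs(x - round(x)) > 1e-9) || (to == "structural" && any(round(x) < 0))) {
    abort("conversion produced negative or non-integer counts; the input was not a realizable statistic of its declared flavor")
  }
}

#' Empirical derivation of a conversion matrix from random networks
#'
#' Re-derives the structural-to-functional conversion matrix without any
#' subset enumeration, the way one would for subgraph sizes where the
#' combinatorial derivation is unavailable: sample random digraphs, count
#' both flavors per node with the brute-force counter, and solve the
#' linear system `functional = X %*% structural` across all node columns.
#' Entries are rounded to integers and, at the three-node level, must
#' reproduce the exact derivation.
#'
#' @param level `"role"` or `"motif"`.
#' @param n_graphs,n,p Sampling protocol for [random_digraph()].
#' @param seed Integer seed for the sampler.
#' @return A `conversion_matrix`.
#' @export
empirical_conversion <- function(level = c("role", "motif"), n_graphs = 100,
                                 n = 15, p = 0.3, seed = 1) {
  level <- match.arg(level)
  cols_f <- list()
  cols_s <- list()
  for (gi in seq_len(n_graphs)) {
    g <- random_digraph(n, p, seed = seed + gi)
    f <- bruteforce_fp_matrix(g, "functional")
    s <- bruteforce_fp_matrix(g, "structural")
    if (level == "motif") {
      grp <- motif_catalog()$motif_of_role[as.character(1:30)]
      f <- rowsum(f, group = grp)
      s <- rowsum(s, group = grp)
    }
    cols_f[[gi]] <- f
    cols_s[[gi]] <- s
  }
  Fm <- do.call(cbind, cols_f)
  Sm <- do.call(cbind, cols_s)
  L <- nrow(Fm)
  if (qr(Sm)$rank < L) {
    abort(sprintf(
      "structural fingerprint sample is rank-deficient (rank %d < %d); use more or denser random graphs",
      qr(Sm)$rank, L
    ))
  }
  X <- t(solve(tcrossprod(Sm), Sm %*% t(Fm)))
  X <- round(X)
  dimnames(X) <- list(paste0("f", seq_len(L)), paste0("s", seq_len(L)))
  new_conversion(X, level, "structural_to_functional")
}

#' Write a conversion matrix as TSV
#'
#' @param x A `conversion_matrix`.
#' @param path Output path.
#' @export
write_conversion <- function(x, path) {
  df <- as.data.frame(conversion_values(x))
  df <- dplyr::bind_cols(tibble(functional_id = seq_len(nrow(df))), df)
  readr::write_lines(
    sprintf("# %s-level conversion matrix, %s", attr(x, "level"),
            gsub("_", " ", attr(x, "direction"))), path
  )
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
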