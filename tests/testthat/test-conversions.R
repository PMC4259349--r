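test_that("derived conversion matrices are unimodular with unit diagonal", {
  for (conv in list(role_conversion_matrix(), motif_conversion_matrix())) {
    v <- motifroles:::conversion_values(conv)
    expect_true(all(diag(v) == 1L))
    expect_equal(abs(round(det(v))), 1)
    expect_true(all(v >= 0L)) # structural-to-functional direction
  }

  # triangular once sorted by the edge count of the source motif
  reg <- role_registry()
  cat <- motifroles:::motif_catalog()
  edge_count_of_motif <- vapply(1:13, function(m) cat$classes_by_id[[m]]$edge_count, 0L)
  ord <- order(edge_count_of_motif[reg$motif_id[order(reg$role_id)]])
  v <- motifroles:::conversion_values(role_conversion_matrix())[ord, ord]
  expect_true(all(v[lower.tri(v)] == 0L))

  vm <- motifroles:::conversion_values(motif_conversion_matrix())
  ordm <- order(edge_count_of_motif)
  vm <- vm[ordm, ordm]
  expect_true(all(vm[lower.tri(vm)] == 0L))
})

test_that("pinned containment counts match the subset census", {
  T_R <- motifroles:::conversion_values(role_conversion_matrix())
  expect_equal(T_R[16, 30], 2L) # complete triad holds 2 two-path-middles per node
  T_M <- motifroles:::conversion_values(motif_conversion_matrix())
  expect_equal(T_M[2, 13], 6L) # ...and 6 two-paths, 2 cycles in total
  expect_equal(T_M[5, 13], 2L)
  expect_equal(T_M[2, 5], 3L) # the cycle contains 3 two-paths
  expect_equal(sum(T_M[, 2] != 0L), 1L) # the two-path only contains itself
})

test_that("integer inversion is exact and detects non-unimodular input", {
  T_R <- role_conversion_matrix()
  T_Rinv <- invert_conversion(T_R)
  expect_true(all(
    motifroles:::conversion_values(T_R) %*% motifroles:::conversion_values(T_Rinv) ==
      diag(30)
  ))
  T_M <- motif_conversion_matrix()
  T_Minv <- invert_conversion(T_M)
  expect_true(all(
    motifroles:::conversion_values(T_M) %*% motifroles:::conversion_values(T_Minv) ==
      diag(13)
  ))
  expect_true(is.integer(motifroles:::conversion_values(T_Minv)))

  bad <- motifroles:::new_conversion(diag(2L) * 2L, "motif", "structural_to_functional")
  expect_error(invert_conversion(bad), "unimodular")
})

test_that("functional fingerprints convert exactly to brute-force structural ones", {
  for (seed in 1:8) {
    g <- rg(16, c(0.1, 0.3, 0.5)[(seed %% 3) + 1], seed + 7)
    f <- role_fingerprints(g, "functional")
    s_conv <- apply_conversion(f)
    expect_identical(fp_matrix(s_conv),
                     fp_matrix(role_fingerprints(g, "structural", "bruteforce")))
    expect_equal(attr(s_conv, "flavor"), "structural")

    # round trip is the identity
    back <- apply_conversion(s_conv)
    expect_identical(fp_matrix(back), fp_matrix(f))
  }
})

test_that("conversion commutes with aggregation to motif level and counts", {
  g <- rg(20, 0.3, 31)
  f <- role_fingerprints(g, "functional")
  s_then_agg <- motif_fingerprints(apply_conversion(f))
  agg_then_s <- apply_conversion(motif_fingerprints(f))
  expect_identical(fp_matrix(s_then_agg), fp_matrix(agg_then_s))

  fc <- motif_counts(motif_fingerprints(f))
  sc <- apply_conversion(fc)
  expect_equal(sc$count,
               motif_counts(motif_fingerprints(role_fingerprints(g, "structural")))$count)
})

test_that("apply_conversion validates level, direction and realizability", {
  f <- role_fingerprints(toy_graph("ffl"), "functional")
  expect_error(apply_conversion(f, motif_conversion_matrix()), "level")
  expect_error(apply_conversion(f, role_conversion_matrix()), "converts from")

  # a functional count vector claiming one full triad but no two-paths is
  # unrealizable: the triad alone implies six of them
  impossible <- motifroles:::count_vector(
    c(rep(0L, 12), 1L), "motif", "functional"
  )
  expect_error(apply_conversion(impossible), "realizable")
})

test_that("empirical derivation from random graphs reproduces both matrices", {
  emp_role <- empirical_conversion("role", n_graphs = 40, n = 12, p = 0.3, seed = 2)
  expect_identical(motifroles:::conversion_values(emp_role),
                   motifroles:::conversion_values(role_conversion_matrix()))
  emp_motif <- empirical_conversion("motif", n_graphs = 40, n = 12, p = 0.3, seed = 2)
  expect_identical(motifroles:::conversion_values(emp_motif),
                   motifroles:::conversion_values(motif_conversion_matrix()))

  # constant (all-empty) samples cannot identify the matrix
  expect_error(empirical_conversion("motif", n_graphs = 5, n = 8, p = 0, seed = 1),
               "rank")
})

test_that("shipped conversion TSVs are bit-exact with the derivation", {
  for (nm in c("role_conversion", "motif_conversion")) {
    shipped <- system.file("extdata", paste0(nm, ".tsv"), package = "motifroles")
    expect_true(nzchar(shipped))
    tmp <- withr::local_tempfile(fileext = ".tsv")
    conv <- if (nm == "role_conversion") role_conversion_matrix() else motif_conversion_matrix()
    write_conversion(conv, tmp)
    expect_identical(readLines(tmp), readLines(shipped))
  }
})
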