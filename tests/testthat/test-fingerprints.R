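test_that("fast functional fingerprints equal the brute-force oracle", {
  for (seed in 1:10) {
    p <- c(0.05, 0.2, 0.5)[(seed %% 3) + 1]
    g <- rg(18, p, seed)
    expect_identical(
      fp_matrix(role_fingerprints(g, "functional", "fast")),
      fp_matrix(role_fingerprints(g, "functional", "bruteforce"))
    )
  }
})

test_that("toy fingerprints match hand-derived values", {
  f_cyc <- fp_matrix(role_fingerprints(toy_graph("cycle3"), "functional"))
  expect_equal(f_cyc[16, ], rep(1L, 3)) # each node is one two-path middle
  expect_equal(f_cyc[17, ], rep(1L, 3)) # and sits on the one cycle

  f_ct <- fp_matrix(role_fingerprints(toy_graph("complete_triad"), "functional"))
  expect_equal(f_ct[16, ], rep(2L, 3)) # d_in*d_out - d_recip = 2*2 - 2

  f_ffl <- fp_matrix(role_fingerprints(toy_graph("ffl"), "functional"))
  expect_equal(f_ffl[14, 1], 1L, ignore_attr = TRUE) # A: two out-edges plus destination edge

  s_ct <- fp_matrix(role_fingerprints(toy_graph("complete_triad"), "structural"))
  expect_equal(s_ct[30, ], rep(1L, 3))
  expect_equal(sum(s_ct[-30, ]), 0L)

  s_cyc <- fp_matrix(role_fingerprints(toy_graph("cycle3"), "structural"))
  expect_equal(s_cyc[17, ], rep(1L, 3))
  expect_equal(sum(s_cyc[-17, ]), 0L) # induced, so no open-triad roles
})

test_that("degree identities hold for the pure-degree roles", {
  for (seed in 1:6) {
    g <- rg(35, 0.15, seed + 100)
    d <- degree_table(g)
    f <- fp_matrix(role_fingerprints(g, "functional"))
    expect_equal(f[10, ], choose(d$d_in, 2), ignore_attr = TRUE)
    expect_equal(f[13, ], choose(d$d_out, 2), ignore_attr = TRUE)
    expect_equal(f[16, ], d$d_in * d$d_out - d$d_recip, ignore_attr = TRUE)
    expect_equal(f[28, ], choose(d$d_recip, 2), ignore_attr = TRUE)
  }
})

test_that("structural counts never exceed functional and agree on role 30", {
  for (seed in 1:6) {
    g <- rg(20, 0.35, seed + 50)
    f <- fp_matrix(role_fingerprints(g, "functional"))
    s <- fp_matrix(role_fingerprints(g, "structural"))
    expect_true(all(s <= f))
    expect_equal(s[30, ], f[30, ])
    expect_true(all(s >= 0L))
  }
})

test_that("structural columns sum to connected-triple membership counts", {
  g <- rg(12, 0.3, 77)
  s <- fp_matrix(role_fingerprints(g, "structural"))
  ig <- as_igraph(g)
  per_node <- integer(n_nodes(g))
  total <- 0L
  for (tri in utils::combn(n_nodes(g), 3, simplify = FALSE)) {
    sub <- igraph::induced_subgraph(ig, tri)
    if (igraph::is_connected(sub, mode = "weak")) {
      per_node[tri] <- per_node[tri] + 1L
      total <- total + 1L
    }
  }
  expect_equal(colSums(s), per_node, ignore_attr = TRUE)
  expect_lte(total, choose(n_nodes(g), 3))
  expect_equal(sum(motif_counts(motif_fingerprints(
    role_fingerprints(g, "structural")
  ))$count), total)
})

test_that("motif fingerprints, counts and layouts are mutually consistent", {
  f_cyc <- role_fingerprints(toy_graph("cycle3"), "functional")
  mf <- motif_fingerprints(f_cyc)
  m <- fp_matrix(mf)
  expect_equal(m[2, ], rep(3L, 3)) # source, middle and sink of 3 two-paths
  mc <- motif_counts(mf)
  expect_equal(mc$count[2], 3L)
  expect_equal(mc$count[5], 1L)
  expect_equal(sum(mc$count[-c(2, 5)]), 0L)

  mc_s <- motif_counts(motif_fingerprints(
    role_fingerprints(toy_graph("cycle3"), "structural")
  ))
  expect_equal(mc_s$count[5], 1L)
  expect_equal(sum(mc_s$count[-5]), 0L)

  mc_ct <- motif_counts(motif_fingerprints(
    role_fingerprints(toy_graph("complete_triad"), "functional")
  ))
  expect_equal(mc_ct$count[2], 6L) # six partial two-paths in the full triad

  s_ct <- motif_fingerprints(role_fingerprints(toy_graph("complete_triad"), "structural"))
  expect_equal(fp_matrix(s_ct)[13, ], rep(1L, 3))
  expect_equal(sum(fp_matrix(s_ct)[-13, ]), 0L)

  empty <- digraph(matrix(0L, 5, 5))
  expect_true(all(fp_matrix(motif_fingerprints(
    role_fingerprints(empty, "functional")
  )) == 0L))
  expect_true(all(role_counts(role_fingerprints(empty, "functional"))$count == 0L))

  # conservation: plurality-weighted role counts give 3x the motif counts
  g <- rg(16, 0.3, 9)
  rfp <- role_fingerprints(g, "functional")
  rc <- role_counts(rfp)
  mc_g <- motif_counts(motif_fingerprints(rfp))
  reg <- role_registry()
  expect_equal(role_counts_from_motif_counts(mc_g)$count, rc$count)
  for (mid in 1:13) {
    expect_equal(sum(rc$count[reg$role_id[reg$motif_id == mid]]), 3L * mc_g$count[mid])
  }

  # a tampered fingerprint matrix trips the divisibility check
  bad <- motif_fingerprints(rfp)
  bad$motif_1[1] <- bad$motif_1[1] + 1L
  expect_error(motif_counts(bad), "divisible")
})

test_that("role layout recovers both count vectors", {
  rc <- role_counts(role_fingerprints(toy_graph("cycle3"), "functional"))
  lay <- role_layout(rc)
  row5 <- lay[lay$motif_id == 5, ]
  expect_equal(sort(c(row5$count_1, row5$count_2, row5$count_3)), c(0L, 0L, 3L))
  expect_equal(layout_motif_counts(lay)$count[5], 1L)

  rc2 <- role_counts(role_fingerprints(toy_graph("two_path"), "functional"))
  lay2 <- role_layout(rc2)
  row2 <- lay2[lay2$motif_id == 2, ]
  expect_equal(c(row2$count_1, row2$count_2, row2$count_3), c(1L, 1L, 1L))

  for (nm in toy_names) {
    rc_t <- role_counts(role_fingerprints(toy_graph(nm), "functional"))
    round_trip <- role_counts_from_motif_counts(layout_motif_counts(role_layout(rc_t)))
    expect_equal(round_trip$count, rc_t$count)
  }
})

test_that("functional motif counts agree with direct pattern-image counting", {
  g <- rg(14, 0.35, 123)
  mc <- motif_counts(motif_fingerprints(role_fingerprints(g, "functional")))
  expect_equal(mc$count[9], count_pattern(g, rbind(c(1, 2), c(1, 3), c(2, 3))))
  expect_equal(mc$count[5], count_pattern(g, rbind(c(1, 2), c(2, 3), c(3, 1))))
  expect_equal(mc$count[2], count_pattern(g, rbind(c(1, 2), c(2, 3))))
})

test_that("structural motif counts agree with the igraph triad census", {
  cmap <- census_motif_map()
  for (seed in c(5, 6)) {
    g <- rg(40, 0.15, seed)
    counts <- motif_counts(motif_fingerprints(role_fingerprints(g, "structural")))
    census <- igraph::triad_census(as_igraph(g))
    expect_equal(counts$count, as.integer(census[cmap]))
  }
})

test_that("fingerprint TSV writer records the flavor and the full table", {
  fp <- role_fingerprints(toy_graph("ffl"), "functional")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fp, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1], "flavor: functional")
  body <- readr::read_tsv(tmp, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(body), 3)
  expect_equal(body$role_14[body$node_label == "A"], 1)
})

test_that("the brute-force guard rejects oversized graphs", {
  g <- rg(12, 0.2, 1)
  expect_error(
    role_fingerprints(g, "functional", "bruteforce", max_bruteforce_nodes = 10),
    "fast"
  )
})
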