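test_that("triangle and potential counts match hand derivations", {
  tp <- triangle_potential(toy_graph("cycle3"))
  expect_equal(tp$closed, rep(1L, 3))
  expect_equal(tp$potential, rep(2L, 3))

  tp2 <- triangle_potential(toy_graph("complete_triad"))
  expect_equal(tp2$closed, rep(8L, 3)) # half of diag((A + t(A))^3) = 16/2
  expect_equal(tp2$potential, rep(8L, 3))

  tp3 <- triangle_potential(toy_graph("two_path"))
  expect_equal(tp3$closed[2], 0L)
  expect_equal(tp3$potential[2], 2L)
})

test_that("closed triangles are an integer-weighted sum of functional roles", {
  w <- motifroles:::triangle_role_weights()
  for (seed in 1:5) {
    g <- rg(25, 0.25, seed + 11)
    f <- fp_matrix(role_fingerprints(g, "functional"))
    expect_equal(as.vector(w %*% f), as.numeric(triangle_potential(g)$closed))
  }
})

test_that("toy clustering coefficients come out exactly as derived", {
  cc <- clustering_coefficients(toy_graph("ffl"))
  expect_equal(cc$C_out[cc$label == "A"], 0.5)
  expect_equal(cc$C_mid[cc$label == "B"], 1)
  expect_equal(cc$C_in[cc$label == "C"], 0.5)
  expect_true(all(cc$C_cyc == 0))
  expect_equal(cc$C_3ff[cc$label == "A"], 0.5)
  expect_equal(cc$C_3ff[cc$label == "B"], 1)

  cc2 <- clustering_coefficients(toy_graph("cycle3"))
  expect_true(all(cc2$C_cyc == 1))
  expect_true(all(cc2$C_in == 0 & cc2$C_out == 0 & cc2$C_mid == 0))

  # an isolated node has every coefficient zero, not NaN
  adj <- matrix(0L, 4, 4)
  adj[1:3, 1:3] <- adjacency(toy_graph("ffl"))
  cc3 <- clustering_coefficients(digraph(adj))
  expect_true(all(cc3[4, c("C_tot", "C_in", "C_out", "C_mid", "C_cyc", "C_3ff")] == 0))
  gl <- attr(cc3, "global")
  expect_equal(gl$n_defined[gl$subtype == "mid"], 1L)
  expect_equal(gl$mean_defined[gl$subtype == "mid"], 1)
  expect_equal(gl$mean_all[gl$subtype == "mid"], 0.25)
})

test_that("coefficients match the closed matrix forms of the directed-clustering literature", {
  for (seed in 1:8) {
    g <- rg(40, 0.12, seed + 20)
    A <- adjacency(g)
    storage.mode(A) <- "double"
    S <- A + t(A)
    d <- degree_table(g)
    z <- function(num, den) ifelse(den == 0, 0, num / den)
    cc <- clustering_coefficients(g)
    expect_equal(cc$C_tot, z(diag(S %*% S %*% S) / 2,
                             d$d_tot * (d$d_tot - 1) - 2 * d$d_recip))
    expect_equal(cc$C_cyc, z(diag(A %*% A %*% A), d$d_in * d$d_out - d$d_recip))
    expect_equal(cc$C_mid, z(diag(A %*% t(A) %*% A), d$d_in * d$d_out - d$d_recip))
    expect_equal(cc$C_in, z(diag(t(A) %*% S %*% A) / 2, d$d_in * (d$d_in - 1)))
    expect_equal(cc$C_out, z(diag(A %*% S %*% t(A)) / 2, d$d_out * (d$d_out - 1)))
  }
})

test_that("all coefficients and transitivities stay inside [0, 1]", {
  ps <- c(0.05, 0.1, 0.3, 0.5, 0.7, 0.9)
  for (i in 1:180) {
    g <- rg(12, ps[(i %% length(ps)) + 1], i)
    cc <- clustering_coefficients(g)
    vals <- as.matrix(cc[, c("C_tot", "C_in", "C_out", "C_mid", "C_cyc", "C_3ff")])
    expect_true(all(vals >= 0 & vals <= 1))
    tr <- suppressMessages(transitivities(g))
    expect_true(all(unlist(tr) >= 0 & unlist(tr) <= 1))
  }
})

test_that("toy transitivities match brute-force closures", {
  tr_cyc <- suppressMessages(transitivities(toy_graph("cycle3")))
  expect_equal(tr_cyc$T_cyc, 1)
  expect_equal(suppressMessages(transitivities(toy_graph("complete_triad")))$T_undirected, 1)
  tr_ffl <- transitivities(toy_graph("ffl"))
  expect_equal(tr_ffl$T_3ff, 3 / 5) # three closed positions over 2 + 1 + 2 openings
  expect_equal(tr_ffl$T_cyc, 0)
  expect_equal(tr_ffl$T_mid, 1)
})

test_that("mean of ratios equals ratio of totals on vertex-transitive fixtures", {
  for (nm in c("cycle3", "complete_triad")) {
    g <- toy_graph(nm)
    gl <- attr(clustering_coefficients(g), "global")
    tr <- suppressMessages(transitivities(g))
    pairs <- c(tot = "T_tot", `in` = "T_in", out = "T_out", mid = "T_mid",
               cyc = "T_cyc", `3ff` = "T_3ff")
    for (sub in names(pairs)) {
      expect_equal(gl$mean_all[gl$subtype == sub], tr[[pairs[[sub]]]],
                   info = paste(nm, sub))
    }
  }
})

test_that("undirected transitivity equals the collapsed-graph standard value", {
  for (seed in 1:6) {
    g <- rg(30, 0.12, seed + 40)
    t_und <- transitivities(g)$T_undirected
    u <- igraph::as_undirected(as_igraph(g), mode = "collapse")
    expect_equal(t_und, igraph::transitivity(u, type = "global"))
  }
  # degenerate empty graph reports 0 with a note
  expect_message(
    tr <- transitivities(digraph(matrix(0L, 4, 4))),
    "0"
  )
  expect_true(all(unlist(tr) == 0))
})

test_that("experimental structural-flavor clustering stays bounded and differs", {
  g <- rg(25, 0.3, 99)
  cs <- clustering_coefficients(g, flavor = "structural")
  vals <- as.matrix(cs[, c("C_in", "C_out", "C_mid", "C_cyc", "C_3ff")])
  expect_true(all(vals >= 0))
  expect_equal(attr(cs, "flavor"), "structural")
})
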