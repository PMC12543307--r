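test_that("generator is deterministic and satisfies the connectome invariants", {
  a <- conn40()
  b <- conn40()
  expect_identical(weightMatrix(a), weightMatrix(b))
  expect_identical(tractLengths(a), tractLengths(b))
  W <- weightMatrix(a); L <- tractLengths(a)
  expect_true(all(diag(W) == 0))
  expect_true(all(W >= 0))
  expect_identical(W, t(W))
  expect_identical(L, t(L))
  expect_true(all(L[W > 0] > 0))
  expect_equal(mean(rowSums(W)), 1)       # documented scale convention
})

test_that("degenerate single-module generator gives a complete equal-weight graph", {
  con <- generateConnectome(4, nModules = 1, hubFraction = 0,
                            weightDispersion = 0, seed = 1)
  W <- weightMatrix(con)
  expect_true(all(W[upper.tri(W)] > 0))
  expect_equal(length(unique(round(W[upper.tri(W)], 12))), 1)
  expect_true(all(diag(W) == 0))
})

test_that("modular generator concentrates weight inside modules", {
  con <- generateConnectome(40, nModules = 4, hubFraction = 0.1,
                            weightDispersion = 0.5, seed = 7)
  W <- weightMatrix(con)
  module <- sort(rep_len(1:4, 40))
  same <- outer(module, module, "==") & upper.tri(W)
  diff <- outer(module, module, "!=") & upper.tri(W)
  expect_gt(mean(W[same]), mean(W[diff]))
})

test_that("generator rejects invalid arguments", {
  expect_error(generateConnectome(3), "integer >= 4")
  expect_error(generateConnectome(10.5), "integer >= 4")
  expect_error(generateConnectome(10, hubFraction = 0.5), "hubFraction")
  expect_error(generateConnectome(10, nModules = 6), "nModules")
})

test_that("asymmetric weights are rejected, not symmetrised", {
  W <- weightMatrix(conn16())
  W[1, 2] <- W[1, 2] + 1e-3
  expect_error(connectome(W, tractLengths(conn16())), "symmetric")
})

test_that("shuffling preserves the weight multiset and reduces modularity", {
  con <- conn40()
  sh <- shuffleConnectome(con, seed = 3)
  expect_equal(sort(weightMatrix(sh)[upper.tri(weightMatrix(sh))]),
               sort(weightMatrix(con)[upper.tri(weightMatrix(con))]))
  expect_true(validObject(sh))
  # a 2-node connectome has one off-diagonal pair: shuffling is the identity
  c2 <- connectome(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 9, 9, 0), 2))
  expect_identical(weightMatrix(shuffleConnectome(c2, 1)), weightMatrix(c2))
  # modularity of the shuffled graph is lower in >= 9/10 seeds
  qOf <- function(cn) {
    g <- igraph::graph_from_adjacency_matrix(weightMatrix(cn),
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    cl <- igraph::cluster_fast_greedy(g)
    igraph::modularity(cl)
  }
  q0 <- qOf(con)
  wins <- sum(vapply(1:10, function(s) qOf(shuffleConnectome(con, s)) < q0,
                     logical(1)))
  expect_gte(wins, 9)
})

test_that("lesion zeroes exactly one row/column and conserves the rest", {
  con <- generateConnectome(4, 1, 0, 0, seed = 1)
  les <- applyLesion(con, 2)
  W0 <- weightMatrix(con); W1 <- weightMatrix(les)
  expect_true(all(W1[2, ] == 0) && all(W1[, 2] == 0))
  expect_identical(W1[-2, -2], W0[-2, -2])
  expect_equal(sum(W1), sum(W0) - 2 * sum(W0[2, ]))
  expect_identical(weightMatrix(con), W0)      # input not mutated
  expect_error(applyLesion(con, 5), "in 1..4")
  expect_error(applyLesion(con, 0), "in 1..4")
})

test_that("delay derivation satisfies the mean-delay identity", {
  con <- conn40()
  for (md in c(1, 4, 40)) {
    d <- delaysFromLengths(con, md)
    conn <- weightMatrix(con) > 0
    expect_equal(mean(delayValues(d)[conn]), md, tolerance = 1e-9)
  }
  d0 <- delaysFromLengths(con, 0)
  expect_true(all(delayValues(d0) == 0))
  expect_equal(d0@velocity, Inf)
  # uniform 100 mm tracts at mean delay 25 ms imply 4 m/s
  cu <- connectome(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 100, 100, 0), 2))
  du <- delaysFromLengths(cu, 25)
  expect_equal(du@velocity, 4)
  expect_equal(delayValues(du)[1, 2], 25)
  expect_error(delaysFromLengths(connectome(matrix(0, 2, 2), matrix(0, 2, 2)), 5),
               "all-zero")
})

test_that("TSV round trip preserves the connectome and validates on load", {
  con <- conn16()
  wf <- tempfile(fileext = ".tsv"); lf <- tempfile(fileext = ".tsv")
  writeConnectomeTSV(con, wf, lf)
  back <- readConnectomeTSV(wf, lf)
  expect_equal(weightMatrix(back), weightMatrix(con), tolerance = 1e-12)
  expect_equal(tractLengths(back), tractLengths(con), tolerance = 1e-12)
  expect_identical(regionLabels(back), regionLabels(con))
  unlink(c(wf, lf))
})
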