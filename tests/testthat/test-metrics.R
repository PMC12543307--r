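mkBold <- function(m, TR = 0.72, band = c(NA_real_, NA_real_))
  new("BoldTimeSeries", bold = m, TR = TR, band = band)

test_that("band-pass keeps the resting-state band and removes everything else", {
  TR <- 0.72
  tt <- seq_len(1200) * TR
  inband <- sin(2 * pi * 0.03 * tt)
  outband <- sin(2 * pi * 0.5 * tt)
  bp <- bandpassBold(mkBold(rbind(inband, outband)))
  expect_gt(max(boldMatrix(bp)[1, 200:1000]), 0.95)
  expect_lt(max(abs(boldMatrix(bp)[2, 200:1000])), 0.1)
  cst <- bandpassBold(mkBold(matrix(3.3, 2, 500)))
  expect_lt(max(abs(boldMatrix(cst))), 1e-9)
  expect_error(bandpassBold(mkBold(matrix(rnorm(200), 2)), low = 0.3,
                            high = 0.8), "band must satisfy")
})

test_that("FC is a Pearson matrix with the expected degenerate values", {
  x <- rnorm(400)
  fc <- fcValues(computeFC(mkBold(rbind(x, x, -x, rnorm(400)))))
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_true(all(diag(fc) == 1))
  expect_identical(fc, t(fc))
  # white noise over 1200 TRs: correlations concentrate near zero
  set.seed(2)
  wn <- matrix(rnorm(20 * 1200), 20)
  f <- fcValues(computeFC(mkBold(wn)))
  expect_gt(mean(abs(f[upper.tri(f)]) < 0.1), 0.95)
  # zero-variance node errors, naming the offender
  bad <- rbind(rnorm(100), rep(1, 100))
  expect_error(computeFC(mkBold(bad)), "zero-variance node.*2")
})

test_that("FC fit statistics behave on constructed references", {
  set.seed(3)
  m <- cor(matrix(rnorm(200 * 12), 200))
  ref <- new("FCMatrix", values = m, band = c(0.008, 0.08))
  expect_equal(unname(fcFit(ref, ref)), c(1, 0))
  shifted <- pmin(m + 0.1, 1); diag(shifted) <- 1
  sim <- new("FCMatrix", values = (shifted + t(shifted)) / 2,
             band = c(0.008, 0.08))
  ft <- fcFit(sim, ref)
  expect_equal(unname(ft["mseFC"]), 0.01, tolerance = 1e-6)
  expect_gt(ft["rFC"], 0.999)
  flipped <- -m; diag(flipped) <- 1
  expect_equal(unname(fcFit(new("FCMatrix", values = flipped,
                                band = c(0.008, 0.08)), ref)["rFC"]), -1)
})

test_that("FCD windowing matches brute-force enumeration", {
  nWin <- function(nTR, window = 80, overlap = 0.8) {
    step <- round(window * (1 - overlap))
    length(seq(1, nTR - window + 1, by = step))
  }
  # closed form floor((nTR - w)/step) + 1 against the enumeration
  for (nTR in c(80, 99, 150, 500, 1200))
    expect_equal(nWin(nTR), floor((nTR - 80) / 16) + 1)
  expect_equal(nWin(1200), 71)
  set.seed(4)
  bold <- mkBold(matrix(rnorm(6 * 200), 6))
  fcd <- computeFCD(bold)
  expect_equal(ncol(fcd@values), nWin(200))
  expect_true(all(abs(fcdValues(fcd)) <= 1))
  expect_error(computeFCD(mkBold(matrix(rnorm(6 * 50), 6))), "shorter")
})

test_that("statically coupled signals give a concentrated FCD distribution", {
  set.seed(5)
  mix <- matrix(rnorm(8 * 3), 8, 3)          # fixed mixing of 3 sources
  src <- matrix(rnorm(3 * 400), 3)
  x <- mix %*% src + 0.1 * matrix(rnorm(8 * 400), 8)
  vals <- fcdValues(computeFCD(mkBold(x)))
  expect_gt(median(vals), 0.8)
  expect_lt(mad(vals), 0.1)
})

test_that("KS distance equals the ECDF sup-difference", {
  expect_equal(ksDistance(1:10, 1:10), 0)
  expect_equal(ksDistance(1:5, 11:15), 1)    # disjoint supports
  # hand-computed 5-point example
  a <- c(0.1, 0.2, 0.4, 0.7, 0.9)
  b <- c(0.15, 0.35, 0.5, 0.55, 0.8)
  pts <- sort(unique(c(a, b)))
  hand <- max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), 0)))
  expect_equal(ksDistance(a, b), hand)
  # cross-check against the standard two-sample statistic
  set.seed(6)
  x <- rnorm(40); y <- rnorm(35, 0.4)
  expect_equal(ksDistance(x, y),
               unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
  expect_error(ksDistance(numeric(0), 1), "non-empty")
})

test_that("fitting score is normalised to [0, 1] with exact endpoints", {
  set.seed(7)
  m <- cor(matrix(rnorm(300 * 10), 300))
  ref <- new("FCMatrix", values = m, band = c(0.008, 0.08))
  expect_equal(fittingScore(1, 0, 0, ref), 1)
  maxMSE <- mean((abs(m[upper.tri(m)]) + 1)^2)
  expect_equal(fittingScore(-1, maxMSE, 1, ref), 0)
  for (k in 1:20) {
    s <- fittingScore(runif(1, -1, 1), runif(1, 0, maxMSE), runif(1), ref)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("Kuramoto order parameter recovers its analytic cases", {
  TR <- 0.72
  tt <- seq_len(600) * TR
  base <- sin(2 * pi * 0.03 * tt)
  same <- mkBold(rbind(base, base, base, base), band = c(0.008, 0.08))
  ph <- kuramoto(same)
  expect_gt(ph@synchrony, 0.99)
  expect_lt(ph@metastability, 0.01)
  anti <- mkBold(rbind(base, -base), band = c(0.008, 0.08))
  expect_lt(kuramoto(anti)@synchrony, 0.05)
  expect_true(all(ph@R >= 0 & ph@R <= 1))
  expect_error(kuramoto(mkBold(matrix(base, 1))), "at least 2 nodes")
})

test_that("random-phase oscillators give the finite-size synchrony floor", {
  TR <- 0.72
  tt <- seq_len(400) * TR
  N <- 12
  set.seed(8)
  syn <- vapply(1:40, function(k) {
    phis <- runif(N, 0, 2 * pi)
    x <- t(vapply(phis, function(p) sin(2 * pi * 0.03 * tt + p), tt))
    kuramoto(mkBold(x, band = c(0.008, 0.08)))@synchrony
  }, numeric(1))
  mc <- vapply(1:20000, function(k) Mod(mean(exp(1i * runif(N, 0, 2 * pi)))),
               numeric(1))
  expect_lt(abs(mean(syn) - mean(mc)), 0.05)
})

test_that("functional complexity matches hand-evaluated cases and is permutation-invariant", {
  # all entries identical -> 0
  m <- matrix(0.3, 10, 10); diag(m) <- 1
  fc <- new("FCMatrix", values = m, band = c(0.008, 0.08))
  expect_equal(functionalComplexity(fc), 0)
  # one value per bin, equally often -> 1
  mids <- rep(seq(-0.975, 0.975, by = 0.05), each = 3)
  expect_equal(functionalComplexity(mids), 1)
  # half the mass in each of two bins: 1 - 1.9/1.95
  twoBins <- c(rep(0.125, 20), rep(-0.325, 20))
  expect_equal(functionalComplexity(twoBins), 1 - 1.9 / 1.95)
  # node permutations leave the upper-triangle multiset unchanged
  set.seed(9)
  v <- cor(matrix(rnorm(120 * 8), 120))
  p <- sample(8)
  f1 <- functionalComplexity(new("FCMatrix", values = v, band = c(0, 1)))
  f2 <- functionalComplexity(new("FCMatrix", values = v[p, p], band = c(0, 1)))
  expect_equal(f1, f2)
  expect_error(functionalComplexity(v[upper.tri(v)], binSize = 0.07),
               "divide")
  # the boundary value 1 lands in the last bin, -1 in the first
  expect_equal(functionalComplexity(c(rep(1, 10), rep(-1, 10))), 1 - 1.9 / 1.95)
})

test_that("structural correlates behave on constructed FC matrices", {
  con <- conn16()
  W <- weightMatrix(con)
  fcw <- 0.8 * W / max(W); diag(fcw) <- 1
  fcw <- pmin(pmax((fcw + t(fcw)) / 2, -1), 1)
  fc <- new("FCMatrix", values = fcw, band = c(0.008, 0.08))
  st <- fcStructureMetrics(fc, con)
  expect_equal(st$fcScCorr, 1)
  expect_equal(fcDistance(fc, fc), 0)
  # two-block FC: modularity is high and the blocks are recovered
  blk <- matrix(0, 8, 8)
  blk[1:4, 1:4] <- 0.8; blk[5:8, 5:8] <- 0.8; diag(blk) <- 1
  fcb <- new("FCMatrix", values = blk, band = c(0.008, 0.08))
  stb <- fcStructureMetrics(fcb, connectome(matrix(0, 8, 8) + blk - diag(8),
                                            matrix(50, 8, 8) - diag(50, 8)))
  expect_gt(stb$modularity, 0.3)
  expect_equal(length(unique(stb$membership[1:4])), 1)
  expect_equal(length(unique(stb$membership[5:8])), 1)
  # exhaustive bipartition oracle at n = 8
  A <- blk; diag(A) <- 0
  best <- -Inf
  for (mask in 1:(2^7)) {
    memb <- c(1, as.integer(intToBits(mask)[1:7])) + 1
    best <- max(best, modularityQ(A, memb))
  }
  expect_equal(stb$modularity, best, tolerance = 1e-9)
  # distance obeys the triangle inequality on random triples
  set.seed(10)
  rfc <- function() new("FCMatrix", values = cor(matrix(rnorm(60 * 6), 60)),
                        band = c(0, 1))
  for (k in 1:5) {
    a <- rfc(); b <- rfc(); cc <- rfc()
    expect_lte(fcDistance(a, cc),
               fcDistance(a, b) + fcDistance(b, cc) + 1e-12)
  }
})
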