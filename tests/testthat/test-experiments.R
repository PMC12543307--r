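# a structured stand-in reference so fit metrics are non-degenerate without
# running a long surrogate simulation
fakeReference <- function(n = 16, seed = 11) {
  set.seed(seed)
  blk <- matrix(0.05, n, n)
  half <- seq_len(n / 2)
  blk[half, half] <- 0.5
  blk[-half, -half] <- 0.5
  blk <- blk + matrix(rnorm(n * n, 0, 0.03), n)
  blk <- pmin(pmax((blk + t(blk)) / 2, -1), 1)
  diag(blk) <- 1
  referenceSet(new("FCMatrix", values = blk, band = c(0.008, 0.08)),
               fcdValues = runif(300, 0.2, 0.8))
}

test_that("runPoint follows the two-step procedure and is reproducible", {
  con <- conn16()
  ref <- fakeReference()
  # uncoupled nodes are independent: FC carries no reference structure
  r0 <- runPoint(con, homeostasisSpec("WC", allMechWC, 0.12), C = 0,
                 rho = 0.12, meanDelay = 0, ref, duration = 120, seed = 1)
  expect_true(r0$valid)
  expect_lt(abs(r0$report@rFC), 0.2)
  # bit-identical reports under the same seed
  r1 <- runPoint(con, homeostasisSpec("WC", allMechWC, 0.12), C = 1,
                 rho = 0.12, meanDelay = 4, ref, duration = 120, seed = 3)
  r2 <- runPoint(con, homeostasisSpec("WC", allMechWC, 0.12), C = 1,
                 rho = 0.12, meanDelay = 4, ref, duration = 120, seed = 3)
  expect_true(r1$valid)
  expect_identical(as.data.frame(r1$report), as.data.frame(r2$report))
  # an infeasible set point is returned as invalid with its reason
  rBad <- runPoint(con, homeostasisSpec("WC", "GE", 0.05), C = 0.5,
                   rho = 0.05, meanDelay = 0, ref, duration = 120, seed = 1)
  expect_false(rBad$valid)
  expect_match(rBad$reason, "infeasible")
})

test_that("sweep tables are complete, reasoned and resumable", {
  con <- conn16()
  ref <- fakeReference()
  grid <- list(C = c(0.3, 1), rho = c(0.1, 0.12), meanDelay = 4)
  tab <- runSweep(con, homeostasisSpec("WC", allMechWC, 0.12), grid, ref,
                  duration = 90, seeds = 1L)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$valid | nzchar(tab$reason)))
  # resumption carries rows over without recomputation
  t0 <- Sys.time()
  tab2 <- runSweep(con, homeostasisSpec("WC", allMechWC, 0.12), grid, ref,
                   duration = 90, seeds = 1L, previous = tab)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 2)
  expect_equal(tab2$score, tab$score)
  da <- delayAveraged(tab)
  expect_equal(nrow(da), 4)
  expect_true(all(da$nValidDelays <= 1))
})

test_that("optimum selection maximises the delay-averaged score under the constraint", {
  # constructed table: no simulations needed
  mk <- function(C, rho, delays, score, valid = TRUE)
    data.frame(C = C, rho = rho, meanDelay = delays, seed = 1, valid = valid,
               reason = "", rFC = 0.5, mseFC = 0.1, ksFCD = 0.2,
               score = score, synchrony = 0.5, metastability = 0.15,
               complexity = 0.6, fcScCorr = 0.2, modularity = 0.3)
  tab <- rbind(mk(1, 0.1, 1:12, 0.9),          # dominant, 12 valid delays
               mk(2, 0.1, 1:12, 0.7),
               mk(3, 0.12, 1:9, 0.95))         # best score, only 9 delays
  opt <- selectOptimum(tab, minValidDelays = 10)
  expect_equal(opt$C, 1)
  expect_equal(opt$rho, 0.1)
  # brute-force oracle over the filtered table
  da <- delayAveraged(tab)
  da <- da[da$nValidDelays >= 10, ]
  expect_equal(opt$score, max(da$score))
  # the dominant point with 9 delays is excluded by the constraint
  expect_false(opt$C == 3)
  # ties break towards smaller C, then smaller rho
  tie <- rbind(mk(2, 0.1, 1:10, 0.8), mk(1, 0.2, 1:10, 0.8),
               mk(1, 0.1, 1:10, 0.8))
  optTie <- selectOptimum(tie)
  expect_equal(c(optTie$C, optTie$rho), c(1, 0.1))
  expect_error(selectOptimum(mk(1, 0.1, 1:3, 0.5)), "required number")
})

test_that("noise sweep spans the default variance grid and emits the observables", {
  expect_equal(eval(formals(noiseSweep)$variances),
               10^seq(-5, 1, length.out = 29))
  con <- conn16()
  ref <- fakeReference()
  tab <- noiseSweep(con, homeostasisSpec("WC", allMechWC, 0.12), C = 1,
                    rho = 0.12, delays = 4, variances = c(1e-4, 0.01),
                    reference = ref, duration = 90, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("noiseVariance", "score", "metastability",
                    "complexity") %in% names(tab)))
  expect_true(all(tab$valid))
})

test_that("strong noise degrades the rate-holding performance", {
  con <- conn16()
  simLo <- wcNetSim(con, allMechWC, 1, 0.12, 4, duration = 15, seed = 6)
  spec <- homeostasisSpec("WC", allMechWC, 0.12)
  sol <- solveSetPointWC(spec, estimateExternalInput(con, 1, 0.31, 0.12))
  pHi <- solvedParams(sol); pHi@noiseVariance <- 10
  simHi <- simulateWC(con, pHi,
                      simulationConfig(1, delaysFromLengths(con, 4),
                                       duration = 15, seed = 6, outDt = 10),
                      rho = 0.12)
  expect_lt(max(checkValidity(simLo, 0.12)$deviation),
            max(checkValidity(simHi, 0.12)$deviation))
})

test_that("an acutely lesioned node loses its input-driven BOLD variance", {
  con <- conn24()
  spec <- homeostasisSpec("WC", allMechWC, metaPoint$rho)
  sol <- solveSetPointWC(spec, estimateExternalInput(con, metaPoint$C, 0.31,
                                                     metaPoint$rho))
  node <- which.max(rowSums(weightMatrix(con)))
  cfg <- function(seed) simulationConfig(metaPoint$C,
                                         delaysFromLengths(con, 12),
                                         duration = 120, seed = seed,
                                         outDt = 10)
  bH <- boldFromRates(simulateWC(con, solvedParams(sol), cfg(1),
                                 rho = metaPoint$rho), baseline = metaPoint$rho)
  bA <- boldFromRates(simulateWC(applyLesion(con, node), solvedParams(sol),
                                 cfg(1), rho = metaPoint$rho),
                      baseline = metaPoint$rho)
  half <- function(b) { x <- bandpassBold(b)@bold[node, ]; x[-seq_len(length(x) %/% 2)] }
  expect_lt(var(half(bA)), var(half(bH)))
})

test_that("homeostatic re-balancing pulls FC back towards the healthy pattern", {
  con <- conn24()
  spec <- homeostasisSpec("WC", allMechWC, metaPoint$rho)
  wins <- 0
  for (node in c(3, 11, 19)) {
    out <- lesionProtocol(con, spec, C = metaPoint$C, rho = metaPoint$rho,
                          meanDelay = 12, node = node, duration = 180,
                          seeds = c(1L, 2L, 3L))
    expect_true(out@chronicFeasible)
    wins <- wins + (out@fcDistanceChronic < out@fcDistanceAcute)
  }
  expect_gte(wins, 2)
})

test_that("fast-excitation networks are more metastable than slow-NMDA ones", {
  con <- conn24()
  metWC <- vapply(1:2, function(s) {
    sim <- wcNetSim(con, allMechWC, metaPoint$C, metaPoint$rho, 12,
                    duration = 240, seed = s)
    kuramoto(bandpassBold(boldFromRates(sim, baseline = metaPoint$rho)))@metastability
  }, numeric(1))
  specW <- homeostasisSpec("WW", c("GE", "JGABA"), 3.0631)
  solW <- solveSetPointWW(specW, con, 0.2)
  metWW <- vapply(1:2, function(s) {
    sim <- simulateWW(con, solvedParams(solW),
                      simulationConfig(0.2, NULL, duration = 240, dt = 1,
                                       seed = s, outDt = 10), rho = 3.0631)
    kuramoto(bandpassBold(boldFromRates(sim, baseline = 3.0631)))@metastability
  }, numeric(1))
  expect_gt(mean(metWC), mean(metWW))
})

test_that("rank-based group comparisons report exact p-values and effect sizes", {
  cg <- compareGroups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(cg$p, 0.9)
  expect_equal(cg$d, 0)
  # fully separated samples attain the minimal two-sided exact p
  a <- 1:10; b <- 21:30
  cg2 <- compareGroups(a, b)
  expect_equal(cg2$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(cg2$d, 0)
  # all-tied samples are flagged degenerate
  cg3 <- compareGroups(rep(1, 5), rep(1, 5))
  expect_true(cg3$degenerate)
  # Benjamini-Hochberg step-up over a batch: (0.01, 0.02, 0.04) all <= 0.05
  set.seed(12)
  ps <- p.adjust(c(0.01, 0.02, 0.04), "BH")
  expect_true(all(ps <= 0.05))
  expect_equal(ps, c(0.03, 0.03, 0.04))
  # paired mode uses the signed-rank test
  x <- rnorm(12); y <- x + 0.5
  cgp <- compareGroups(x, y, paired = TRUE)
  expect_equal(cgp$p,
               suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value))
})
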