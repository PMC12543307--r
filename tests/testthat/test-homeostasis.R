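test_that("external-input estimate follows the set-point coupling equation", {
  con <- conn16()
  expect_equal(estimateExternalInput(con, 0, 0.31, 0.1),
               rep(0.31, nNodes(con)))
  # forced arithmetic: P = 0.31, C = 2, rho = 0.1, row sum 1.5 -> 0.61
  c2 <- connectome(matrix(c(0, 1.5, 1.5, 0), 2), matrix(c(0, 50, 50, 0), 2))
  expect_equal(estimateExternalInput(c2, 2, 0.31, 0.1), c(0.61, 0.61))
  # ordering of inputs equals ordering of row sums (hubs receive the most)
  iExt <- estimateExternalInput(con, 1.7, 0.31, 0.12)
  expect_identical(order(iExt), order(rowSums(weightMatrix(con))))
  expect_error(estimateExternalInput(con, -1, 0.31, 0.1), "C must be")
  expect_error(estimateExternalInput(con, 1, 0.31, 0), "rho must be")
})

wcMechs <- list("GE", "cEI", "muE", c("muE", "sigmaE"), c("GE", "cEI"),
                c("GE", "cEI", "muE"), c("GE", "cEI", "muE", "sigmaE"))

test_that("all seven WC mechanism combinations solve the set point exactly", {
  con <- conn24()
  set.seed(1)
  draws <- data.frame(C = runif(3, 0.3, 1.5), rho = runif(3, 0.115, 0.15))
  for (k in seq_len(nrow(draws))) {
    iExt <- estimateExternalInput(con, draws$C[k], 0.31, draws$rho[k])
    sols <- lapply(wcMechs, function(m)
      solveSetPointWC(homeostasisSpec("WC", m, draws$rho[k]), iExt))
    for (s in sols) {
      expect_true(all(isFeasible(s)))
      expect_lt(max(s@residual), 1e-10)
      expect_true(all(s@locallyStable))
    }
    # mechanisms share the steady rate but differ in the solved parameters
    sig <- vapply(sols, function(s) {
      p <- solvedParams(s)
      paste(signif(c(p@GE[1], p@cEI[1], p@muE[1], p@sigmaE[1]), 8),
            collapse = ",")
    }, "")
    expect_equal(length(unique(sig)), length(wcMechs))
  }
})

test_that("excitatory scaling decreases with external input under GE homeostasis", {
  spec <- homeostasisSpec("WC", "GE", 0.12)
  iExt <- seq(0.31, 1.2, length.out = 10)
  sol <- solveSetPointWC(spec, iExt)
  expect_true(all(diff(solvedParams(sol)@GE) < 0))
})

test_that("infeasible configurations are flagged per node, not silently accepted", {
  # at rho = 0.05 the required excitatory drive under GE-only scaling is
  # negative for the default baseline: the node must be flagged
  sol <- solveSetPointWC(homeostasisSpec("WC", "GE", 0.05), iExt = c(0.31, 0.8))
  expect_false(all(isFeasible(sol)))
})

wwMechs <- list("GE", "JGABA", "bE", "aE", c("GE", "JGABA"),
                c("GE", "JGABA", "bE"), c("GE", "JGABA", "aE"))

test_that("all seven WW mechanism combinations solve the set point", {
  con <- conn24()
  for (rho in c(2, 3.0631, 6)) {
    sols <- lapply(wwMechs, function(m)
      solveSetPointWW(homeostasisSpec("WW", m, rho), con, 0.2))
    for (s in sols) {
      expect_true(all(isFeasible(s)))
      expect_lt(max(s@residual), 1e-10)
      expect_true(all(s@locallyStable))
    }
  }
})

test_that("the NMDA gating equilibrium vanishes in the gamma -> 0 limit", {
  p <- wwParams(gamma = 1e-12)
  fp <- eicortex:::.wwNodeFixedPoint(p)
  expect_lt(fp[["SE"]], 1e-9)
})

test_that("simulating with solved parameters recovers the target rates", {
  con <- conn24()
  # WC, all mechanisms, 1% criterion
  sim <- wcNetSim(con, allMechWC, validPoint$C, validPoint$rho,
                  validPoint$meanDelay, duration = 15, seed = 2)
  v <- checkValidity(sim, validPoint$rho)
  expect_true(v$overall)
  # WW, 15% criterion at the canonical target
  specW <- homeostasisSpec("WW", c("GE", "JGABA"), 3.0631)
  solW <- solveSetPointWW(specW, con, 0.2)
  simW <- simulateWW(con, solvedParams(solW),
                     simulationConfig(0.2, NULL, duration = 30, dt = 1,
                                      seed = 2, outDt = 10), rho = 3.0631)
  vW <- checkValidity(simW, 3.0631)
  expect_true(vW$overall)
  # the noisy node means lie inside the published acceptance band
  late <- rowMeans(excRates(simW)[, 1500:3000])
  expect_true(all(late > 2.63 & late < 3.55))
})

test_that("validity check applies the <= boundary convention", {
  mk <- function(vals) new("RateTimeSeries",
                           rE = matrix(vals, nrow = length(vals), ncol = 1500),
                           rI = matrix(0.1, length(vals), 1500),
                           dt = 10, t0 = 5, model = "WC", clamped = 0)
  rho <- 0.12
  expect_true(checkValidity(mk(rho), rho)$overall)
  expect_false(checkValidity(mk(c(rho, 1.012 * rho)), rho)$overall)
  expect_true(checkValidity(mk(1.01 * rho), rho)$overall)     # boundary passes
  expect_error(checkValidity(mk(rho), rho, discardS = 100), "no samples")
})
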