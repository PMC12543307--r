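# shared fixtures: small connectomes and canonical operating points

conn40 <- function() generateConnectome(40, nModules = 4, hubFraction = 0.1,
                                        weightDispersion = 0.5, seed = 7)
conn24 <- function() generateConnectome(24, nModules = 3, hubFraction = 0.1,
                                        weightDispersion = 0.5, seed = 7)
conn16 <- function() generateConnectome(16, nModules = 2, hubFraction = 0.1,
                                        weightDispersion = 0.5, seed = 5)

allMechWC <- c("GE", "cEI", "muE", "sigmaE")

# valid reference point (deviations well below the 1% criterion)
validPoint <- list(C = 1.5, rho = 0.12, meanDelay = 4)
# metastable operating point (strong collective dynamics, 24-node scaffold)
metaPoint <- list(C = 2, rho = 0.14, meanDelay = 12)

wcNetSim <- function(con, mech, C, rho, meanDelay, duration, seed,
                     outDt = 10, noiseMode = "sqrt-dt") {
  spec <- homeostasisSpec("WC", mech, rho)
  sol <- solveSetPointWC(spec, estimateExternalInput(con, C, 0.31, rho))
  stopifnot(all(isFeasible(sol)))
  simulateWC(con, solvedParams(sol),
             simulationConfig(C, delaysFromLengths(con, meanDelay),
                              duration = duration, seed = seed, outDt = outDt,
                              noiseMode = noiseMode),
             rho = rho)
}
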