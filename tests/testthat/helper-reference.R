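# independent reference implementations used as oracles

# plain-R Euler-Maruyama integrator for the delayed Wilson-Cowan network,
# replicating the RNG draw order of the compiled path (per step, per node,
# E draw then I draw) so trajectories can be compared bit for bit
wcEulerR <- function(W, Dsteps, pm, C, P, dt, nSteps, rE0, rI0,
                     noiseSd = 0, mode = c("sqrt-dt", "per-step")) {
  mode <- match.arg(mode)
  n <- nrow(W)
  rE <- rE0; rI <- rI0
  histE <- matrix(rE0, n, nSteps + 1)   # column t+1 = state at step t
  outE <- matrix(NA_real_, n, nSteps)
  outI <- matrix(NA_real_, n, nSteps)
  sig <- function(x, mu, s) 1 / (1 + exp(-(x - mu) / s))
  sq <- noiseSd * sqrt(dt / 1000)
  for (t in 0:(nSteps - 1)) {
    histE[, t + 1] <- rE
    rEn <- rE; rIn <- rI
    for (i in seq_len(n)) {
      acc <- 0
      for (j in which(W[i, ] > 0)) {
        tl <- t - Dsteps[i, j]
        acc <- acc + W[i, j] * (if (tl < 0) rE0[j] else histE[j, tl + 1])
      }
      iext <- C * acc + P
      argE <- pm[i, "GE"] * pm[i, "cEE"] * rE[i] - pm[i, "cEI"] * rI[i] +
        pm[i, "GE"] * iext
      argI <- pm[i, "cIE"] * rE[i]
      if (mode == "per-step") {
        dE <- dt / pm[i, "tauE"] *
          (-rE[i] + sig(argE, pm[i, "muE"], pm[i, "sigmaE"]) +
             noiseSd * rnorm(1))
        dI <- dt / pm[i, "tauI"] *
          (-rI[i] + sig(argI, pm[i, "muI"], pm[i, "sigmaI"]) +
             noiseSd * rnorm(1))
      } else {
        dE <- dt / pm[i, "tauE"] *
          (-rE[i] + sig(argE, pm[i, "muE"], pm[i, "sigmaE"])) +
          sq * rnorm(1)
        dI <- dt / pm[i, "tauI"] *
          (-rI[i] + sig(argI, pm[i, "muI"], pm[i, "sigmaI"])) +
          sq * rnorm(1)
      }
      rEn[i] <- min(max(rE[i] + dE, 0), 1)
      rIn[i] <- min(max(rI[i] + dI, 0), 1)
    }
    rE <- rEn; rI <- rIn
    outE[, t + 1] <- rE
    outI[, t + 1] <- rI
  }
  list(rE = outE, rI = outI)
}

# Balloon-Windkessel via deSolve's adaptive stiff solver, one node, input
# held piecewise-constant on the same grid as the package integrator
bwDeSolve <- function(z, baseline, dtS, constants = bwConstants()) {
  cc <- constants
  f0 <- 1 + baseline / cc$gamma
  v0 <- f0^cc$alpha
  E0f <- 1 - (1 - cc$E0)^(1 / f0)
  q0 <- f0 * E0f / cc$E0 * v0^(1 - 1 / cc$alpha)
  b0 <- 100 * cc$V0 * (cc$k1 * (1 - q0) + cc$k2 * (1 - q0 / v0) +
                         cc$k3 * (1 - v0))
  deriv <- function(t, x, parms) {
    zz <- z[min(length(z), floor(t / dtS) + 1)]
    fv <- x[3]^(1 / cc$alpha)
    Ef <- 1 - (1 - cc$E0)^(1 / x[2])
    list(c(zz - cc$kappa * x[1] - cc$gamma * (x[2] - 1),
           x[1],
           (x[2] - fv) / cc$tau,
           (x[2] * Ef / cc$E0 - fv * x[4] / x[3]) / cc$tau))
  }
  tt <- seq_len(length(z)) * dtS
  out <- deSolve::lsoda(c(s = 0, f = f0, v = v0, q = q0), c(0, tt), deriv,
                        NULL, rtol = 1e-10, atol = 1e-12)[-1, ]
  100 * cc$V0 * (cc$k1 * (1 - out[, "q"]) +
                   cc$k2 * (1 - out[, "q"] / out[, "v"]) +
                   cc$k3 * (1 - out[, "v"])) - b0
}

# finite-difference Jacobian of the single-node deterministic WC flow
wcNodeJacFD <- function(params, rE, rI, input, h = 1e-7) {
  flow <- function(s) {
    argE <- params@GE * (params@cEE * s[1] + input) - params@cEI * s[2]
    argI <- params@cIE * s[1]
    c((-s[1] + wcGain(argE, params@muE, params@sigmaE)) / params@tauE,
      (-s[2] + wcGain(argI, params@muI, params@sigmaI)) / params@tauI)
  }
  s0 <- c(rE, rI)
  vapply(1:2, function(k) {
    e <- numeric(2); e[k] <- h
    (flow(s0 + e) - flow(s0 - e)) / (2 * h)
  }, numeric(2))
}

# Newman modularity of a weighted undirected graph for a given 2-colouring
modularityQ <- function(A, memb) {
  m2 <- sum(A)
  k <- rowSums(A)
  sum((A - outer(k, k) / m2) * outer(memb, memb, "==")) / m2
}
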