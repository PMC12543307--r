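#' Reduced Wong-Wang parameter sets
#'
#' Defaults follow the source reduced mean-field model (Deco-style dynamic
#' mean field): background current I0 = 0.382 nA scaled by W^E = 1 / W^I =
#' 0.7, recurrent weight w+ = 1.4, J_NMDA = 0.15 nA, J_GABA = 1 nA, kinetic
#' rate gamma = 0.641, slow NMDA excitation (tauE = 100 ms) and fast GABA
#' inhibition (tauI = 10 ms), and the standard gain constants. At these
#' defaults the uncoupled node settles near the canonical ~3 Hz operating
#' point.
#'
#' @param I0,wPlus,jNMDA,jGABA,WE,WI,GE,aE,bE,dE,aI,bI,dI,gamma,tauE,tauI,noiseVariance
#'   see \code{\linkS4class{WWParams}}.
#' @return a \code{\linkS4class{WWParams}}.
#' @export
wwParams <- function(I0 = 0.382, wPlus = 1.4, jNMDA = 0.15, jGABA = 1,
                     WE = 1, WI = 0.7, GE = 1, aE = 310, bE = 125,
                     dE = 0.16, aI = 615, bI = 177, dI = 0.087,
                     gamma = 0.641, tauE = 100, tauI = 10,
                     noiseVariance = 0.01) {
  new("WWParams", I0 = I0, wPlus = wPlus, jNMDA = jNMDA, jGABA = jGABA,
      WE = WE, WI = WI, GE = GE, aE = aE, bE = bE, dE = dE, aI = aI,
      bI = bI, dI = dI, gamma = gamma, tauE = tauE, tauI = tauI,
      noiseVariance = noiseVariance)
}

#' Wong-Wang input-output function and its inverse
#'
#' \code{wwGain} maps a current x (nA) to a firing rate (Hz):
#' \code{(a*x - b) / (1 - exp(-d*(a*x - b)))}, continuous at \code{a*x = b}
#' where its value is \code{1/d}. \code{wwGainInverse} inverts it numerically
#' (the function is strictly increasing).
#'
#' @param x current (nA); \code{rate} firing rate (Hz, > 0).
#' @param rate firing rate to invert (Hz).
#' @param a,b,d gain parameters (\code{a, d > 0}).
#' @return firing rate in Hz, respectively the current giving \code{rate}.
#' @export
wwGain <- function(x, a, b, d) {
  if (any(a <= 0) || any(d <= 0)) stop("a and d must be > 0")
  z <- a * x - b
  u <- d * z
  out <- ifelse(abs(u) < 1e-8, 1 / d + z / 2, z / (1 - exp(-u)))
  # large negative z underflows cleanly to 0
  out[u < -700] <- 0
  out
}

#' @rdname wwGain
#' @export
wwGainInverse <- function(rate, a, b, d) {
  if (any(rate <= 0)) stop("rate must be > 0")
  vapply(rate, function(y) {
    g <- function(z) {
      u <- d * z
      v <- if (abs(u) < 1e-8) 1 / d + z / 2 else if (u < -700) 0
           else z / (1 - exp(-u))
      v - y
    }
    hi <- max(1, 2 * y)
    z <- uniroot(g, c(-1e4 / d, hi), tol = 1e-12)$root
    (z + b) / a
  }, numeric(1))
}

.wwexp <- function(p, n) {
  v <- vapply(c("I0", "wPlus", "jNMDA", "jGABA", "WE", "WI", "GE", "aE",
                "bE", "dE", "aI", "bI", "dI", "gamma", "tauE", "tauI"),
              function(s) rep_len(slot(p, s), n), numeric(n))
  if (n == 1) v <- matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
  v
}

# self-consistent inhibitory steady state given the excitatory gating SE
# (the inhibitory current depends on S^I which depends on r^I)
.wwInhSteady <- function(pm, SE) {
  n <- nrow(pm)
  rI <- numeric(n)
  for (i in seq_len(n)) {
    g <- function(r) {
      II <- pm[i, "WI"] * pm[i, "I0"] + pm[i, "jNMDA"] * SE[i] -
        pm[i, "jGABA"] * (pm[i, "tauI"] / 1000) * r
      wwGain(II, pm[i, "aI"], pm[i, "bI"], pm[i, "dI"]) - r
    }
    rI[i] <- uniroot(g, c(0, 2000), tol = 1e-12)$root
  }
  rI
}

#' Simulate a reduced Wong-Wang network
#'
#' Euler-Maruyama integration of the gating equations (no conduction delays;
#' the slow NMDA timescale makes them negligible), with firing rates computed
#' through the gain function at every step. With the \code{"at-set-point"}
#' policy the gating variables start at the equilibrium of the target rate:
#' \code{S^E* = gamma*rho*tauE / (1 + gamma*rho*tauE)}.
#'
#' @param con a \code{\linkS4class{Connectome}}.
#' @param params a \code{\linkS4class{WWParams}} (slots length 1 or n).
#' @param config a \code{\linkS4class{SimulationConfig}} (use \code{dt = 1}
#'   ms; \code{delay} must be NULL).
#' @param rho target rate (Hz) for the \code{"at-set-point"} policy.
#' @return a \code{\linkS4class{RateTimeSeries}} with rates in Hz.
#' @export
simulateWW <- function(con, params, config, rho = NULL) {
  stopifnot(is(con, "Connectome"), is(params, "WWParams"),
            is(config, "SimulationConfig"))
  if (!is.null(config@delay) && any(config@delay@delays > 0))
    stop("the reduced Wong-Wang model neglects conduction delays")
  n <- nNodes(con)
  pm <- .wwexp(params, n)
  dtS <- config@dt / 1000
  if (config@init == "at-set-point") {
    if (is.null(rho)) stop("init = 'at-set-point' requires rho")
    tE <- pm[, "tauE"] / 1000
    SE0 <- pm[, "gamma"] * rho * tE / (1 + pm[, "gamma"] * rho * tE)
    SI0 <- (pm[, "tauI"] / 1000) * .wwInhSteady(pm, SE0)
  } else {
    SE0 <- rep_len(config@initState$SE, n)
    SI0 <- rep_len(config@initState$SI, n)
  }
  outEvery <- as.integer(round(config@outDt / config@dt))
  nSteps <- floor(config@duration * 1000 / config@dt / outEvery) * outEvery
  set.seed(config@seed)
  res <- .ww_integrate(weightMatrix(con),
                       pm[, "I0"], pm[, "wPlus"], pm[, "jNMDA"], pm[, "jGABA"],
                       pm[, "WE"], pm[, "WI"], pm[, "GE"],
                       pm[, "aE"], pm[, "bE"], pm[, "dE"],
                       pm[, "aI"], pm[, "bI"], pm[, "dI"],
                       pm[, "gamma"], pm[, "tauE"] / 1000, pm[, "tauI"] / 1000,
                       config@coupling, sqrt(rep_len(params@noiseVariance, 1)),
                       if (config@noiseMode == "per-step") 1L else 0L,
                       dtS, as.integer(nSteps), outEvery, SE0, SI0)
  new("RateTimeSeries", rE = res$rE, rI = res$rI, dt = config@outDt,
      t0 = config@outDt / 2, model = "WW", clamped = 0)
}

# deterministic fixed point of the uncoupled node with extra E-current
.wwNodeFixedPoint <- function(params, inputE = 0) {
  pm <- .wwexp(params, 1)
  tE <- pm[1, "tauE"] / 1000
  g <- function(SE) {
    rI <- .wwInhSteady(pm, SE)
    SI <- (pm[1, "tauI"] / 1000) * rI
    IE <- pm[1, "GE"] * (pm[1, "WE"] * pm[1, "I0"] +
                         pm[1, "wPlus"] * pm[1, "jNMDA"] * SE) -
      pm[1, "jGABA"] * SI + inputE
    rE <- wwGain(IE, pm[1, "aE"], pm[1, "bE"], pm[1, "dE"])
    pm[1, "gamma"] * rE * tE / (1 + pm[1, "gamma"] * rE * tE) - SE
  }
  SE <- uniroot(g, c(0, 1 - 1e-9), tol = 1e-12)$root
  rI <- .wwInhSteady(pm, SE)
  SI <- (pm[1, "tauI"] / 1000) * rI
  IE <- pm[1, "GE"] * (pm[1, "WE"] * pm[1, "I0"] +
                       pm[1, "wPlus"] * pm[1, "jNMDA"] * SE) -
    pm[1, "jGABA"] * SI + inputE
  c(SE = unname(SE), SI = unname(SI),
    rE = unname(wwGain(IE, pm[1, "aE"], pm[1, "bE"], pm[1, "dE"])),
    rI = unname(rI))
}

# deterministic single-node simulation with extra E-current (for scans)
.wwSimNode <- function(params, inputE, duration, dt = 1, SE0, SI0) {
  p <- params
  p@noiseVariance <- 0
  # fold the probe current into the background term
  p@I0 <- params@I0
  pm <- .wwexp(p, 1)
  # shift WE*I0 by inputE/GE so the E population receives +inputE
  p@WE <- (pm[1, "WE"] * pm[1, "I0"] + inputE / pm[1, "GE"]) / pm[1, "I0"]
  cfg <- simulationConfig(coupling = 0, duration = duration, dt = dt,
                          init = "given",
                          initState = list(SE = SE0, SI = SI0))
  simulateWW(connectome(matrix(0, 1, 1), matrix(0, 1, 1)), p, cfg)
}

#' Scan the uncoupled Wong-Wang node for oscillatory regimes
#'
#' Classifies the asymptotic behaviour of the deterministic node at each
#' external-current level by the growth of the oscillation envelope of a run
#' started slightly off the fixed point. Because excitation (100 ms) is much
#' slower than inhibition (10 ms), the model has no Hopf bifurcation and
#' every input level is expected to be classified non-oscillatory, in
#' contrast with the Wilson-Cowan node.
#'
#' @param params a \code{\linkS4class{WWParams}}.
#' @param inputGrid extra currents (nA) injected into the E population.
#' @return data frame with columns \code{input} and \code{oscillatory}.
#' @export
wwHopfScan <- function(params, inputGrid = seq(-0.3, 0.6, length.out = 50)) {
  osc <- vapply(inputGrid, function(inp) {
    fp <- .wwNodeFixedPoint(params, inp)
    ts <- .wwSimNode(params, inp, duration = 10, dt = 1,
                     SE0 = min(fp["SE"] + 0.05, 1), SI0 = fp["SI"])
    x <- excRates(ts)[1, ]
    w1 <- x[2501:5000]; w2 <- x[7501:10000]
    s1 <- sd(w1); s2 <- sd(w2)
    s2 > 1e-7 && s2 / max(s1, 1e-12) > 0.999
  }, logical(1))
  data.frame(input = inputGrid, oscillatory = osc)
}
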