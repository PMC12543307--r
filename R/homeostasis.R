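# canonical mechanism-combination key (fixed order, locale-independent)
.mechKey <- function(mechanisms, model) {
  ord <- if (model == "WC") c("GE", "cEI", "muE", "sigmaE")
         else c("GE", "JGABA", "bE", "aE")
  paste(ord[ord %in% mechanisms], collapse = "+")
}

#' Specify a homeostasis configuration
#'
#' @param model \code{"WC"} or \code{"WW"}.
#' @param mechanisms character vector naming the active mechanisms, e.g.
#'   \code{c("GE","cEI","muE","sigmaE")}; see
#'   \code{\linkS4class{HomeostasisSpec}} for the supported combinations.
#' @param targetRate target mean excitatory rate rho (dimensionless for WC,
#'   Hz for WW).
#' @param baseline baseline parameter set; defaults to \code{wcParams()} or
#'   \code{wwParams()}.
#' @return a \code{\linkS4class{HomeostasisSpec}}.
#' @export
homeostasisSpec <- function(model = c("WC", "WW"), mechanisms, targetRate,
                            baseline = NULL) {
  model <- match.arg(model)
  if (is.null(baseline))
    baseline <- if (model == "WC") wcParams() else wwParams()
  new("HomeostasisSpec", model = model, mechanisms = mechanisms,
      targetRate = targetRate, baseline = baseline)
}

#' Estimate the external input of each node at the set point
#'
#' Homeostasis acts on timescales much slower than the neural dynamics, so
#' the set-point parameters can be computed from the \emph{average} external
#' input each node receives when the whole network sits at the target rate:
#' \code{I_i = P + C * rho * sum_j W_ij}.
#'
#' @param con a \code{\linkS4class{Connectome}}.
#' @param C global coupling (>= 0).
#' @param P background input.
#' @param rho target rate (> 0).
#' @return per-node external input vector.
#' @export
estimateExternalInput <- function(con, C, P, rho) {
  stopifnot(is(con, "Connectome"))
  if (rho <= 0) stop("rho must be > 0")
  if (C < 0) stop("C must be >= 0")
  P + C * rho * rowSums(weightMatrix(con))
}

#' Solve the Wilson-Cowan homeostatic set point analytically
#'
#' For each node, computes the parameter values placing the deterministic
#' steady state exactly at the target rate rho, given the node's average
#' external input. At the set point the inhibitory rate is
#' \code{rI* = F_I(c_IE * rho)} and the excitatory steady-state equation
#' \code{G^E (c_EE rho + I_ext) - c_EI rI* = F_E^{-1}(rho)} is solved for
#' the free parameters of the active mechanism combination: single-parameter
#' mechanisms in closed form; multi-parameter combinations by a closed-form
#' allocation applied in the order inhibition, excitation, excitability
#' (c_EI holds the inhibitory-to-excitatory current ratio of the baseline
#' uncoupled node; G^E normalises the total excitatory drive to the baseline
#' uncoupled drive; mu^E absorbs the remainder, with sigma^E scaled in
#' proportion to the raw input when the synergistic slope rule is active, so
#' strongly driven nodes are poised farther from the bifurcation).
#'
#' Nodes whose solution demands an inadmissible parameter (G^E <= 0,
#' c_EI < 0, sigma^E <= 0) are flagged infeasible rather than silently
#' accepted, mirroring the blank regions of the model's validity maps.
#'
#' @param spec a WC \code{\linkS4class{HomeostasisSpec}}.
#' @param iExt per-node external input, from
#'   \code{\link{estimateExternalInput}}.
#' @return a \code{\linkS4class{SetPointSolution}}.
#' @export
solveSetPointWC <- function(spec, iExt) {
  stopifnot(is(spec, "HomeostasisSpec"), spec@model == "WC")
  p0 <- spec@baseline
  rho <- spec@targetRate
  n <- length(iExt)
  key <- .mechKey(spec@mechanisms, "WC")
  L <- log(rho / (1 - rho))

  # baseline slots may be per-node (e.g. the chronic lesion re-solve anchors
  # at the prelesion solved parameters)
  GE0 <- rep_len(p0@GE, n); cEI0 <- rep_len(p0@cEI, n)
  muE0 <- rep_len(p0@muE, n); sigmaE0 <- rep_len(p0@sigmaE, n)
  cEE <- rep_len(p0@cEE, n); cIE0 <- rep_len(p0@cIE, n)
  muI0 <- rep_len(p0@muI, n); sigmaI0 <- rep_len(p0@sigmaI, n)
  P <- rep_len(p0@P, 1)
  GE <- GE0; cEI <- cEI0; muE <- muE0; sigmaE <- sigmaE0

  .bparam <- function(i)
    wcParams(tauE = rep_len(p0@tauE, n)[i], tauI = rep_len(p0@tauI, n)[i],
             cEE = cEE[i], cEI = cEI0[i], cIE = cIE0[i], GE = GE0[i],
             muE = muE0[i], sigmaE = sigmaE0[i], muI = muI0[i],
             sigmaI = sigmaI0[i], P = P)

  rIstar <- wcGain(cIE0 * rho, muI0, sigmaI0)         # per-node rI*
  X0 <- muE0 + sigmaE0 * L                            # baseline F_E^{-1}(rho)
  drive <- cEE * rho + iExt                           # raw excitatory drive
  scale <- drive / (cEE * rho + P)                    # raw input scale

  # baseline uncoupled node at its own fixed point: I/E current ratio
  uniformBase <- all(vapply(c("GE", "cEI", "muE", "sigmaE", "cEE", "cIE",
                              "muI", "sigmaI"),
                            function(s) length(unique(slot(p0, s))) == 1,
                            logical(1)))
  k0 <- if (uniformBase) {
    fp <- .wcNodeFixedPoint(.bparam(1), P)
    rep((cEI0[1] * fp["rI"]) / (GE0[1] * (cEE[1] * fp["rE"] + P)), n)
  } else {
    vapply(seq_len(n), function(i) {
      fp <- .wcNodeFixedPoint(.bparam(i), P)
      unname((cEI0[i] * fp["rI"]) / (GE0[i] * (cEE[i] * fp["rE"] + P)))
    }, numeric(1))
  }
  driveBase <- GE0 * (cEE * rho + P)

  if (key == "GE") {
    GE <- (X0 + cEI0 * rIstar) / drive
  } else if (key == "cEI") {
    cEI <- (GE0 * drive - X0) / rIstar
  } else if (key == "muE") {
    muE <- GE0 * drive - cEI0 * rIstar - sigmaE0 * L
  } else if (key == "muE+sigmaE") {
    a <- GE0 * drive - cEI0 * rIstar
    sigmaE <- sigmaE0 * sqrt(scale)
    muE <- a - sigmaE * L
  } else if (key == "GE+cEI") {
    cEI <- k0 * GE0 * drive / rIstar
    GE <- X0 / drive + k0 * GE0
  } else if (key == "GE+cEI+muE") {
    cEI <- k0 * GE0 * drive / rIstar
    GE <- driveBase / drive
    muE <- driveBase - k0 * GE0 * drive - sigmaE0 * L
  } else if (key == "GE+cEI+muE+sigmaE") {
    cEI <- k0 * GE0 * drive / rIstar
    GE <- X0 / drive + k0 * GE0
    sigmaE <- sigmaE0 * sqrt(scale)
    muE <- GE * drive - cEI * rIstar - sigmaE * L
  }
  feasible <- GE > 0 & cEI >= 0 & sigmaE > 0

  # plug the solution back into the steady-state equations
  residual <- abs(wcGain(GE * (cEE * rho + iExt) - cEI * rIstar, muE, sigmaE) -
                  rho)

  params <- p0
  params@GE <- unname(GE); params@cEI <- unname(cEI)
  params@muE <- unname(muE)
  params@sigmaE <- unname(pmax(sigmaE, 1e-12))  # keep class validity for
                                                # infeasible (flagged) nodes
  stable <- vapply(seq_len(n), function(i) {
    if (!feasible[i]) return(NA)
    pi <- wcParams(tauE = rep_len(p0@tauE, n)[i], tauI = rep_len(p0@tauI, n)[i],
                   cEE = cEE[i], cEI = cEI[i], cIE = cIE0[i],
                   GE = GE[i], muE = muE[i], sigmaE = max(sigmaE[i], 1e-12),
                   muI = muI0[i], sigmaI = sigmaI0[i])
    J <- .wcNodeJacobian(pi, rho, rIstar[i], iExt[i])
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }, logical(1))

  new("SetPointSolution", params = params, iExt = unname(iExt),
      residual = unname(residual), feasible = unname(feasible),
      locallyStable = unname(stable), spec = spec)
}

#' Solve the Wong-Wang homeostatic set point
#'
#' At equilibrium the excitatory gating is
#' \code{S^E* = gamma*rho*tauE / (1 + gamma*rho*tauE)} and the excitatory
#' current must satisfy \code{F^E(I^E*) = rho}; the free parameter of each
#' mechanism is solved in closed form or by 1-D root-finding on the monotone
#' gain. Combined mechanisms use the same allocation order as the
#' Wilson-Cowan solver (inhibition holds the baseline current ratio,
#' excitation normalises drive, excitability absorbs the remainder). The
#' inhibitory steady state is solved self-consistently because J_GABA also
#' enters the inhibitory population's own current.
#'
#' @param spec a WW \code{\linkS4class{HomeostasisSpec}} (targetRate in Hz).
#' @param con a \code{\linkS4class{Connectome}}.
#' @param C global coupling.
#' @return a \code{\linkS4class{SetPointSolution}}.
#' @export
solveSetPointWW <- function(spec, con, C) {
  stopifnot(is(spec, "HomeostasisSpec"), spec@model == "WW",
            is(con, "Connectome"))
  p0 <- spec@baseline
  rho <- spec@targetRate
  n <- nNodes(con)
  pm <- .wwexp(p0, n)
  key <- .mechKey(spec@mechanisms, "WW")

  tE <- pm[1, "tauE"] / 1000
  SEs <- pm[1, "gamma"] * rho * tE / (1 + pm[1, "gamma"] * rho * tE)
  rowW <- rowSums(weightMatrix(con))
  excRaw <- pm[, "WE"] * pm[, "I0"] + pm[, "wPlus"] * pm[, "jNMDA"] * SEs +
    C * pm[, "jNMDA"] * SEs * rowW                    # drive at GE = 1
  iExt <- C * pm[, "jNMDA"] * SEs * rowW              # network current (nA)

  # inhibitory steady state and S^I* as a function of J_GABA
  inh <- function(jG, i) {
    g <- function(r) {
      II <- pm[i, "WI"] * pm[i, "I0"] + pm[i, "jNMDA"] * SEs -
        jG * (pm[i, "tauI"] / 1000) * r
      wwGain(II, pm[i, "aI"], pm[i, "bI"], pm[i, "dI"]) - r
    }
    r <- uniroot(g, c(0, 2000), tol = 1e-13)$root
    (pm[i, "tauI"] / 1000) * r
  }

  GE <- pm[, "GE"]; jG <- pm[, "jGABA"]; bE <- pm[, "bE"]; aE <- pm[, "aE"]
  feasible <- rep(TRUE, n)
  IEstar <- wwGainInverse(rho, pm[1, "aE"], pm[1, "bE"], pm[1, "dE"])

  # baseline uncoupled node: inhibitory/excitatory current ratio
  fp0 <- .wwNodeFixedPoint(p0)
  excFp0 <- pm[1, "GE"] * (pm[1, "WE"] * pm[1, "I0"] +
                           pm[1, "wPlus"] * pm[1, "jNMDA"] * fp0["SE"])
  k0 <- unname(pm[1, "jGABA"] * fp0["SI"] / excFp0)
  excBase <- pm[1, "GE"] * (pm[1, "WE"] * pm[1, "I0"] +
                            pm[1, "wPlus"] * pm[1, "jNMDA"] * SEs)

  solveJG <- function(target, i) {
    # J_GABA with inhibitory current J*S^I*(J) equal to `target`
    h <- function(j) j * inh(j, i) - target
    if (target < 0) return(NA_real_)
    uniroot(h, c(0, 200), tol = 1e-13, extendInt = "upX")$root
  }
  zStar <- uniroot(function(z) {
    u <- pm[1, "dE"] * z
    v <- if (abs(u) < 1e-8) 1 / pm[1, "dE"] + z / 2 else z / (1 - exp(-u))
    v - rho
  }, c(-1e4, max(1, 2 * rho)), tol = 1e-13)$root     # a*I - b at rate rho

  for (i in seq_len(n)) {
    if (key == "GE") {
      SIs <- inh(jG[i], i)
      GE[i] <- (IEstar + jG[i] * SIs) / excRaw[i]
      feasible[i] <- GE[i] > 0
    } else if (key == "JGABA") {
      jG[i] <- solveJG(GE[i] * excRaw[i] - IEstar, i)
      feasible[i] <- !is.na(jG[i])
    } else if (key == "bE") {
      SIs <- inh(jG[i], i)
      IE0 <- GE[i] * excRaw[i] - jG[i] * SIs
      bE[i] <- aE[i] * IE0 - zStar
    } else if (key == "aE") {
      SIs <- inh(jG[i], i)
      IE0 <- GE[i] * excRaw[i] - jG[i] * SIs
      if (IE0 <= 0) { feasible[i] <- FALSE; next }
      aE[i] <- uniroot(function(a) wwGain(IE0, a, bE[i], pm[i, "dE"]) - rho,
                       c(1e-6, 1e6), tol = 1e-13)$root
    } else if (key == "GE+JGABA") {
      if (k0 >= 1 || IEstar <= 0) { feasible[i] <- FALSE; next }
      exc <- IEstar / (1 - k0)
      GE[i] <- exc / excRaw[i]
      jG[i] <- solveJG(k0 * exc, i)
      feasible[i] <- GE[i] > 0 && !is.na(jG[i])
    } else if (key %in% c("GE+JGABA+bE", "GE+JGABA+aE")) {
      jG[i] <- solveJG(k0 * pm[i, "GE"] * excRaw[i], i)
      GE[i] <- excBase / excRaw[i]
      IE0 <- excBase - k0 * pm[i, "GE"] * excRaw[i]
      if (key == "GE+JGABA+bE") {
        bE[i] <- aE[i] * IE0 - zStar
      } else {
        if (IE0 <= 0) { feasible[i] <- FALSE; next }
        aE[i] <- uniroot(function(a) wwGain(IE0, a, bE[i], pm[i, "dE"]) - rho,
                         c(1e-6, 1e6), tol = 1e-13)$root
      }
      feasible[i] <- feasible[i] && !is.na(jG[i]) && GE[i] > 0
    }
  }

  residual <- vapply(seq_len(n), function(i) {
    if (!feasible[i]) return(NA_real_)
    SIs <- inh(jG[i], i)
    IE <- GE[i] * excRaw[i] - jG[i] * SIs
    abs(wwGain(IE, aE[i], bE[i], pm[i, "dE"]) - rho)
  }, numeric(1))

  params <- p0
  params@GE <- unname(GE); params@jGABA <- unname(jG)
  params@bE <- unname(bE); params@aE <- unname(pmax(aE, 1e-12))

  stable <- vapply(seq_len(n), function(i) {
    if (!feasible[i]) return(NA)
    # finite-difference Jacobian of the gating flow at the set point
    SIs <- inh(jG[i], i)
    flow <- function(s) {
      IE <- GE[i] * (pm[i, "WE"] * pm[i, "I0"] +
                     pm[i, "wPlus"] * pm[i, "jNMDA"] * s[1] +
                     C * pm[i, "jNMDA"] * SEs * rowW[i]) - jG[i] * s[2]
      II <- pm[i, "WI"] * pm[i, "I0"] + pm[i, "jNMDA"] * s[1] - jG[i] * s[2]
      c(-s[1] / tE + (1 - s[1]) * pm[i, "gamma"] *
          wwGain(IE, aE[i], bE[i], pm[i, "dE"]),
        -s[2] / (pm[i, "tauI"] / 1000) + wwGain(II, pm[i, "aI"], pm[i, "bI"],
                                                pm[i, "dI"]))
    }
    s0 <- c(SEs, SIs); h <- 1e-7
    J <- vapply(1:2, function(k) {
      e <- numeric(2); e[k] <- h
      (flow(s0 + e) - flow(s0 - e)) / (2 * h)
    }, numeric(2))
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }, logical(1))

  new("SetPointSolution", params = params, iExt = unname(iExt),
      residual = unname(residual), feasible = unname(feasible),
      locallyStable = unname(stable), spec = spec)
}

#' Post-hoc validity check of the homeostatic set point
#'
#' A node passes when its mean excitatory rate over the kept window deviates
#' from the target by at most \code{tolerance} (relative; boundary cases
#' pass, i.e. the comparison is \code{<=}); the network passes when all
#' nodes pass. The standard criteria are a 15-s run with the first 5 s
#' discarded and tolerance 1\% for the Wilson-Cowan model, 15\% for the
#' Wong-Wang model (defaults chosen by the series' model tag).
#'
#' @param rates a \code{\linkS4class{RateTimeSeries}}.
#' @param rho target rate.
#' @param tolerance relative tolerance; defaults to 0.01 (WC) or 0.15 (WW).
#' @param discardS initial transient to discard (s).
#' @return list with \code{nodePass}, \code{deviation} (relative), and
#'   \code{overall}.
#' @export
checkValidity <- function(rates, rho, tolerance = NULL, discardS = 5) {
  stopifnot(is(rates, "RateTimeSeries"))
  if (is.null(tolerance))
    tolerance <- if (rates@model == "WW") 0.15 else 0.01
  tms <- rates@t0 + (seq_len(ncol(rates@rE)) - 1) * rates@dt
  keep <- tms > discardS * 1000
  if (!any(keep)) stop("no samples left after discarding the transient")
  m <- rowMeans(rates@rE[, keep, drop = FALSE])
  dev <- abs(m - rho) / rho
  ok <- dev <= tolerance + 1e-12          # boundary cases pass (<=)
  list(nodePass = ok, deviation = dev, overall = all(ok))
}
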