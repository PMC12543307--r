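#' @import methods
#' @importFrom stats fft rnorm runif sd cor quantile median mad p.adjust
#'   wilcox.test setNames ecdf spectrum nextn uniroot optimize var complete.cases
#' @importFrom utils head tail read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib eicortex, .registration = TRUE
NULL

.check_square <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    return(sprintf("%s must be a square numeric matrix", what))
  NULL
}

#' Structural connectome
#'
#' A weighted, undirected structural connectome: an \code{n x n} non-negative
#' weight matrix (DTI-style streamline weights, zero diagonal) together with a
#' matching tract-length matrix in millimetres, from which conduction delays
#' are derived. Asymmetric input is rejected rather than silently symmetrised,
#' and weights are used raw (not row-normalised) by the network models.
#'
#' @slot weights n x n non-negative symmetric numeric matrix, zero diagonal.
#' @slot tractLengths n x n non-negative symmetric numeric matrix (mm),
#'   strictly positive wherever \code{weights > 0}.
#' @slot labels character vector of region names.
#' @export
setClass("Connectome",
  representation(weights = "matrix", tractLengths = "matrix",
                 labels = "character"),
  validity = function(object) {
    W <- object@weights; L <- object@tractLengths
    msg <- c(.check_square(W, "weights"), .check_square(L, "tractLengths"))
    if (length(msg)) return(msg)
    if (nrow(W) != nrow(L)) return("weights and tractLengths dimensions differ")
    if (length(object@labels) != nrow(W))
      return("labels length must equal the number of nodes")
    if (any(!is.finite(W)) || any(W < 0)) return("weights must be finite and >= 0")
    if (any(diag(W) != 0)) return("weights diagonal must be zero")
    if (!isSymmetric(unname(W), tol = 0))
      return("weights must be symmetric (undirected connectome); refusing to symmetrise")
    if (any(!is.finite(L)) || any(L < 0))
      return("tractLengths must be finite and >= 0")
    if (!isSymmetric(unname(L), tol = 0)) return("tractLengths must be symmetric")
    if (any(L[W > 0] <= 0))
      return("tractLengths must be > 0 wherever weights > 0")
    TRUE
  })

#' Conduction-delay matrix
#'
#' Tract lengths scaled by a single global conduction velocity so that the
#' mean delay over connected pairs equals a prescribed value. A mean delay of
#' zero is the zero-delay (infinite-velocity) limit.
#'
#' @slot delays n x n non-negative matrix of delays (ms).
#' @slot meanDelay mean delay over connected pairs (ms).
#' @slot velocity implied conduction velocity (m/s); \code{Inf} when
#'   \code{meanDelay == 0}.
#' @export
setClass("DelayMatrix",
  representation(delays = "matrix", meanDelay = "numeric",
                 velocity = "numeric"),
  validity = function(object) {
    msg <- .check_square(object@delays, "delays")
    if (!is.null(msg)) return(msg)
    if (any(object@delays < 0)) return("delays must be >= 0")
    if (object@meanDelay < 0) return("meanDelay must be >= 0")
    if (object@meanDelay == 0 && any(object@delays != 0))
      return("meanDelay == 0 requires all delays to be zero")
    TRUE
  })

#' Wilson-Cowan local-circuit parameters
#'
#' Parameters of the excitatory-inhibitory neural mass used for every cortical
#' area. Each slot is a numeric vector of length 1 (shared) or n (per node);
#' \code{\link{solveSetPointWC}} returns per-node vectors for the slots a
#' homeostatic mechanism adjusts. Time constants are in ms; the sigmoid
#' input-output function is \code{1/(1 + exp(-(x - mu)/sigma))}.
#'
#' @slot tauE,tauI time constants of the E and I populations (ms).
#' @slot cEE,cEI,cIE dimensionless synaptic couplings (E->E, I->E, E->I).
#' @slot GE scaling of all excitatory inputs onto the E population.
#' @slot muE,sigmaE,muI,sigmaI sigmoid threshold/slope parameters.
#' @slot P background external input.
#' @slot noiseVariance variance of the additive Gaussian noise term.
#' @export
setClass("WCParams",
  representation(tauE = "numeric", tauI = "numeric", cEE = "numeric",
                 cEI = "numeric", cIE = "numeric", GE = "numeric",
                 muE = "numeric", sigmaE = "numeric", muI = "numeric",
                 sigmaI = "numeric", P = "numeric", noiseVariance = "numeric"),
  validity = function(object) {
    if (any(object@tauE <= 0) || any(object@tauI <= 0))
      return("tauE and tauI must be > 0")
    if (any(object@sigmaE <= 0) || any(object@sigmaI <= 0))
      return("sigmaE and sigmaI must be > 0")
    if (any(object@cEE < 0) || any(object@cEI < 0) || any(object@cIE < 0))
      return("couplings must be >= 0")
    if (any(object@GE <= 0)) return("GE must be > 0")
    if (any(object@noiseVariance < 0)) return("noiseVariance must be >= 0")
    TRUE
  })

#' Reduced Wong-Wang local-circuit parameters
#'
#' Parameters of the reduced Wong-Wang mass with slow NMDA-timescale
#' excitation. Currents are in nA, rates in Hz, time constants in ms. The
#' gain function is \code{(a*x - b) / (1 - exp(-d*(a*x - b)))}.
#'
#' @slot I0 background current (nA).
#' @slot wPlus recurrent excitatory weight.
#' @slot jNMDA,jGABA synaptic couplings (nA).
#' @slot WE,WI background-current scalings for the E and I populations.
#' @slot GE scaling of all excitatory synapses onto the E population.
#' @slot aE,bE,dE,aI,bI,dI gain-function parameters.
#' @slot gamma kinetic rate of NMDA gating.
#' @slot tauE,tauI synaptic time constants (ms; defaults 100 and 10).
#' @slot noiseVariance variance of the additive Gaussian noise (nA^2).
#' @export
setClass("WWParams",
  representation(I0 = "numeric", wPlus = "numeric", jNMDA = "numeric",
                 jGABA = "numeric", WE = "numeric", WI = "numeric",
                 GE = "numeric", aE = "numeric", bE = "numeric",
                 dE = "numeric", aI = "numeric", bI = "numeric",
                 dI = "numeric", gamma = "numeric", tauE = "numeric",
                 tauI = "numeric", noiseVariance = "numeric"),
  validity = function(object) {
    if (any(object@tauE <= object@tauI) || any(object@tauI <= 0))
      return("need tauE > tauI > 0 (slow excitation, fast inhibition)")
    if (any(object@aE <= 0) || any(object@aI <= 0) ||
        any(object@dE <= 0) || any(object@dI <= 0))
      return("gain parameters a and d must be > 0")
    if (any(object@GE <= 0)) return("GE must be > 0")
    if (any(object@noiseVariance < 0)) return("noiseVariance must be >= 0")
    TRUE
  })

#' Homeostasis specification
#'
#' Which model and which combination of homeostatic mechanisms is active, the
#' target mean excitatory rate rho, and the baseline (pre-homeostasis)
#' parameter set the solved parameters are anchored to. Supported mechanism
#' combinations: for the Wilson-Cowan model \code{GE}, \code{cEI}, \code{muE},
#' \code{muE+sigmaE}, \code{GE+cEI}, \code{GE+cEI+muE},
#' \code{GE+cEI+muE+sigmaE}; for the Wong-Wang model \code{GE}, \code{JGABA},
#' \code{bE}, \code{aE}, \code{GE+JGABA}, \code{GE+JGABA+bE},
#' \code{GE+JGABA+aE}.
#'
#' @slot model \code{"WC"} or \code{"WW"}.
#' @slot mechanisms character vector of mechanism names (one of the
#'   enumerated combinations).
#' @slot targetRate target mean excitatory rate rho: dimensionless in (0,1)
#'   for WC (sweep range [0.05, 0.2]); Hz for WW (sweep range [1, 10]).
#' @slot baseline a \code{WCParams} or \code{WWParams} object.
#' @export
setClass("HomeostasisSpec",
  representation(model = "character", mechanisms = "character",
                 targetRate = "numeric", baseline = "ANY"),
  validity = function(object) {
    if (!object@model %in% c("WC", "WW")) return("model must be 'WC' or 'WW'")
    ok <- if (object@model == "WC") .wc_mechanism_sets else .ww_mechanism_sets
    key <- .mechKey(object@mechanisms, object@model)
    if (!key %in% vapply(ok, function(m) .mechKey(m, object@model), "") ||
        !all(object@mechanisms %in% unlist(ok)))
      return(sprintf("unsupported mechanism combination '%s'",
                     paste(object@mechanisms, collapse = "+")))
    if (object@model == "WC" &&
        (object@targetRate <= 0 || object@targetRate >= 1))
      return("WC target rate must lie strictly inside (0, 1)")
    if (object@model == "WW" && object@targetRate <= 0)
      return("WW target rate (Hz) must be > 0")
    TRUE
  })

.wc_mechanism_sets <- list(
  "GE", "cEI", "muE", c("muE", "sigmaE"), c("GE", "cEI"),
  c("GE", "cEI", "muE"), c("GE", "cEI", "muE", "sigmaE"))
.ww_mechanism_sets <- list(
  "GE", "JGABA", "bE", "aE", c("GE", "JGABA"),
  c("GE", "JGABA", "bE"), c("GE", "JGABA", "aE"))

#' Analytically solved homeostatic set point
#'
#' Per-node parameter values placing the deterministic steady state of every
#' node exactly at the target rate, together with the estimated external
#' inputs, the residual of the fixed-point equations, per-node feasibility
#' flags (infeasible nodes mirror the blank regions of the model's validity
#' maps) and a numerical local-stability check of the set point.
#'
#' @slot params solved \code{WCParams}/\code{WWParams} with per-node vectors.
#' @slot iExt per-node external input at the set point.
#' @slot residual per-node absolute residual of the steady-state equations.
#' @slot feasible per-node logical; FALSE where the mechanism demands an
#'   inadmissible parameter (e.g. negative \code{cEI}).
#' @slot locallyStable per-node logical from linearising the uncoupled node
#'   (with its external input frozen) at the set point.
#' @slot spec the \code{HomeostasisSpec} that was solved.
#' @export
setClass("SetPointSolution",
  representation(params = "ANY", iExt = "numeric", residual = "numeric",
                 feasible = "logical", locallyStable = "logical",
                 spec = "HomeostasisSpec"))

#' Simulation configuration
#'
#' Global settings of one network simulation: global coupling \code{C},
#' conduction delays, duration, integration step, seed, initial-state policy
#' and the noise-increment convention.
#'
#' @slot coupling global coupling C (scales the raw weight matrix).
#' @slot delay a \code{DelayMatrix} (WC model) or NULL (zero delays / WW).
#' @slot duration simulated time (s).
#' @slot dt integration step (ms); 0.2 for WC, 1 for WW by default.
#' @slot seed integer RNG seed.
#' @slot init \code{"at-set-point"} or \code{"given"}.
#' @slot initState list with elements \code{rE}, \code{rI} (WC) or
#'   \code{SE}, \code{SI} (WW) when \code{init == "given"}.
#' @slot noiseMode \code{"per-step"} (default) or \code{"sqrt-dt"}.
#' @slot outDt sampling step of the recorded series (ms); block means of the
#'   integration grid, must be a multiple of \code{dt}.
#' @export
setClass("SimulationConfig",
  representation(coupling = "numeric", delay = "ANY", duration = "numeric",
                 dt = "numeric", seed = "integer", init = "character",
                 initState = "list", noiseMode = "character",
                 outDt = "numeric"),
  validity = function(object) {
    if (object@dt <= 0) return("dt must be > 0")
    if (object@duration <= 0) return("duration must be > 0")
    if (object@coupling < 0) return("coupling must be >= 0")
    if (!object@init %in% c("at-set-point", "given"))
      return("init must be 'at-set-point' or 'given'")
    if (!object@noiseMode %in% c("per-step", "sqrt-dt"))
      return("noiseMode must be 'per-step' or 'sqrt-dt'")
    if (object@outDt < object@dt ||
        abs(object@outDt / object@dt - round(object@outDt / object@dt)) > 1e-9)
      return("outDt must be a multiple of dt")
    # delays are read by nearest-sample lookup on the dt grid; delays below
    # dt/2 round to the undelayed sample
    TRUE
  })

#' Node-by-time firing-rate series
#'
#' Excitatory and inhibitory rate matrices sampled at \code{dt} ms (block
#' means of the integration grid when the simulation records at a coarser
#' step than it integrates). WC rates are dimensionless in [0,1]; WW rates
#' are in Hz.
#'
#' @slot rE,rI n_nodes x n_samples matrices.
#' @slot dt sampling step (ms).
#' @slot t0 time of the first sample (ms).
#' @slot model \code{"WC"} or \code{"WW"}.
#' @slot clamped number of clamp events during integration (WC).
#' @export
setClass("RateTimeSeries",
  representation(rE = "matrix", rI = "matrix", dt = "numeric",
                 t0 = "numeric", model = "character", clamped = "numeric"),
  validity = function(object) {
    if (!all(dim(object@rE) == dim(object@rI)))
      return("rE and rI must have identical dimensions")
    if (object@dt <= 0) return("dt must be > 0")
    if (object@model == "WC" &&
        (any(object@rE < -1e-9) || any(object@rE > 1 + 1e-9)))
      return("WC rates must lie in [0, 1]")
    TRUE
  })

#' BOLD time series
#'
#' Simulated BOLD (% signal change) at the empirical repetition time.
#'
#' @slot bold n_nodes x n_TR matrix.
#' @slot TR repetition time (s), default 0.72.
#' @slot band band-pass limits (Hz) applied to the series, or \code{c(NA, NA)}
#'   for an unfiltered series.
#' @export
setClass("BoldTimeSeries",
  representation(bold = "matrix", TR = "numeric", band = "numeric"),
  validity = function(object) {
    if (object@TR <= 0) return("TR must be > 0")
    if (any(!is.finite(object@bold))) return("BOLD values must be finite")
    TRUE
  })

#' Static functional-connectivity matrix
#'
#' @slot values n x n Pearson correlation matrix (symmetric, unit diagonal).
#' @slot band band-pass limits (Hz) of the underlying series.
#' @export
setClass("FCMatrix",
  representation(values = "matrix", band = "numeric"),
  validity = function(object) {
    v <- object@values
    msg <- .check_square(v, "values")
    if (!is.null(msg)) return(msg)
    if (any(abs(v) > 1 + 1e-8)) return("correlations must lie in [-1, 1]")
    if (any(abs(diag(v) - 1) > 1e-8)) return("diagonal must be 1")
    if (!isSymmetric(unname(v), tol = 1e-8)) return("FC must be symmetric")
    TRUE
  })

#' Functional-connectivity-dynamics matrix
#'
#' Correlations between the upper-triangular FC patterns of sliding windows
#' (80 samples, 80\% overlap by default). The distribution of its
#' upper-triangle values summarises switching between network states.
#'
#' @slot values w x w correlation matrix between windowed FC patterns.
#' @slot window window length (samples).
#' @slot overlapFraction fractional overlap between consecutive windows.
#' @export
setClass("FCDMatrix",
  representation(values = "matrix", window = "numeric",
                 overlapFraction = "numeric"))

#' Instantaneous-phase series and Kuramoto order parameter
#'
#' @slot theta n x T matrix of Hilbert phases.
#' @slot R Kuramoto order parameter R(t) in [0, 1].
#' @slot Phi global phase.
#' @slot synchrony time-mean of R(t) (edge-trimmed).
#' @slot metastability time-SD of R(t) (edge-trimmed).
#' @export
setClass("PhaseSeries",
  representation(theta = "matrix", R = "numeric", Phi = "numeric",
                 synchrony = "numeric", metastability = "numeric"),
  validity = function(object) {
    if (any(object@R < -1e-9 | object@R > 1 + 1e-9))
      return("R(t) must lie in [0, 1]")
    TRUE
  })

#' Surrogate or user-supplied fitting reference
#'
#' The reference functional data a simulation is scored against: a static FC
#' matrix and a distribution of FCD values, either built from a held-out
#' simulation (\code{provenance = "surrogate"}) or supplied by the user.
#'
#' @slot fc reference \code{FCMatrix}.
#' @slot fcdValues non-empty numeric vector of FCD values in [-1, 1].
#' @slot provenance \code{"surrogate"} or \code{"user-supplied"}.
#' @export
setClass("ReferenceSet",
  representation(fc = "FCMatrix", fcdValues = "numeric",
                 provenance = "character"),
  validity = function(object) {
    if (!length(object@fcdValues)) return("fcdValues must be non-empty")
    if (any(abs(object@fcdValues) > 1 + 1e-8))
      return("fcdValues must lie in [-1, 1]")
    if (!object@provenance %in% c("surrogate", "user-supplied"))
      return("provenance must be 'surrogate' or 'user-supplied'")
    TRUE
  })

#' Observable suite of one simulation
#'
#' All scalar observables reported for one network simulation: fit to the
#' reference (r_FC, MSE_FC, KS_FCD, cross-feature score), Kuramoto synchrony
#' and metastability, functional complexity, FC-SC correlation and FC
#' modularity. The band-passed FC matrix is retained for lesion-stage
#' comparisons.
#'
#' @slot rFC,mseFC,ksFCD,score,synchrony,metastability,complexity,fcScCorr,modularity
#'   scalar observables.
#' @slot fc the band-passed simulated \code{FCMatrix}.
#' @slot fcdValues the simulated FCD value distribution.
#' @export
setClass("DynamicsReport",
  representation(rFC = "numeric", mseFC = "numeric", ksFCD = "numeric",
                 score = "numeric", synchrony = "numeric",
                 metastability = "numeric", complexity = "numeric",
                 fcScCorr = "numeric", modularity = "numeric",
                 fc = "FCMatrix", fcdValues = "numeric"))

#' Outcome of one focal-lesion experiment
#'
#' Reports for the healthy, acute (lesioned connectome, pre-lesion
#' parameters) and chronic (lesioned connectome, re-solved parameters)
#' stages, plus the FC distances and FCD KS distances of the lesioned stages
#' from the healthy stage.
#'
#' @slot node lesioned node index.
#' @slot healthy,acute,chronic per-stage \code{DynamicsReport}s.
#' @slot fcDistanceAcute,fcDistanceChronic Euclidean FC distance from healthy.
#' @slot ksAcute,ksChronic KS distance of the stage FCD distribution from the
#'   healthy FCD distribution.
#' @slot chronicFeasible FALSE when the lesioned network admits no feasible
#'   set point.
#' @export
setClass("LesionOutcome",
  representation(node = "integer", healthy = "DynamicsReport",
                 acute = "DynamicsReport", chronic = "ANY",
                 fcDistanceAcute = "numeric", fcDistanceChronic = "numeric",
                 ksAcute = "numeric", ksChronic = "numeric",
                 chronicFeasible = "logical"))
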