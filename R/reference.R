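#' Build a surrogate fitting reference from a held-out simulation
#'
#' Runs the full rate-to-BOLD pipeline once at a chosen operating point and
#' returns its static FC and FCD value distribution as the reference that
#' subsequent simulations are scored against. This stands in for
#' group-averaged empirical functional data, so every stage of the pipeline
#' is exercisable without any download; use \code{\link{referenceSet}} to
#' wrap user-supplied empirical matrices instead.
#'
#' @param con a \code{\linkS4class{Connectome}}.
#' @param spec a \code{\linkS4class{HomeostasisSpec}}.
#' @param config a \code{\linkS4class{SimulationConfig}} with its own
#'   (held-out) seed; at least 10 minutes of simulated time are required so
#'   the FCD distribution is informative.
#' @param TR repetition time (s).
#' @return a \code{\linkS4class{ReferenceSet}} with
#'   \code{provenance = "surrogate"}.
#' @export
makeSurrogateReference <- function(con, spec, config, TR = 0.72) {
  stopifnot(is(con, "Connectome"), is(spec, "HomeostasisSpec"),
            is(config, "SimulationConfig"))
  if (config@duration < 600)
    stop("surrogate reference needs >= 10 min of simulated time")
  rho <- spec@targetRate
  if (spec@model == "WC") {
    sol <- solveSetPointWC(spec, estimateExternalInput(
      con, config@coupling, rep_len(spec@baseline@P, 1), rho))
  } else {
    sol <- solveSetPointWW(spec, con, config@coupling)
  }
  if (!all(isFeasible(sol)))
    stop("reference operating point is infeasible for some nodes")
  sim <- if (spec@model == "WC")
    simulateWC(con, solvedParams(sol), config, rho = rho)
  else simulateWW(con, solvedParams(sol), config, rho = rho)
  bold <- boldFromRates(sim, TR = TR, baseline = rho)
  bp <- bandpassBold(bold)
  referenceSet(computeFC(bp), fcdValues(computeFCD(bp)),
               provenance = "surrogate")
}

#' Wrap a reference FC and FCD distribution
#'
#' @param fc an \code{\linkS4class{FCMatrix}}.
#' @param fcdValues numeric vector of FCD values in [-1, 1].
#' @param provenance \code{"surrogate"} or \code{"user-supplied"}.
#' @return a \code{\linkS4class{ReferenceSet}}.
#' @export
referenceSet <- function(fc, fcdValues, provenance = "user-supplied") {
  new("ReferenceSet", fc = fc, fcdValues = fcdValues,
      provenance = provenance)
}
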