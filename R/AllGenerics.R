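#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

#' @export
setGeneric("tractLengths", function(object) standardGeneric("tractLengths"))

#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' @export
setGeneric("delayValues", function(object) standardGeneric("delayValues"))

#' @export
setGeneric("excRates", function(object) standardGeneric("excRates"))

#' @export
setGeneric("inhRates", function(object) standardGeneric("inhRates"))

#' @export
setGeneric("boldMatrix", function(object) standardGeneric("boldMatrix"))

#' @export
setGeneric("fcValues", function(object) standardGeneric("fcValues"))

#' @export
setGeneric("fcdValues", function(object) standardGeneric("fcdValues"))

#' @export
setGeneric("solvedParams", function(object) standardGeneric("solvedParams"))

#' @export
setGeneric("isFeasible", function(object) standardGeneric("isFeasible"))

#' Accessors
#'
#' Small accessor family for the package's S4 containers: \code{nNodes} gives
#' the number of regions; \code{weightMatrix}, \code{tractLengths},
#' \code{regionLabels} and \code{delayValues} expose the structural scaffold;
#' \code{excRates}/\code{inhRates} and \code{boldMatrix} the simulated
#' activity; \code{fcValues} and \code{fcdValues} the functional matrices;
#' \code{solvedParams} and \code{isFeasible} the homeostatic solution.
#'
#' @param object one of the package's S4 objects.
#' @return The matrix, vector or scalar the accessor names.
#' @name accessors
#' @aliases nNodes weightMatrix tractLengths regionLabels delayValues
#'   excRates inhRates boldMatrix fcValues fcdValues solvedParams isFeasible
NULL

setMethod("nNodes", "Connectome", function(object) nrow(object@weights))
setMethod("weightMatrix", "Connectome", function(object) object@weights)
setMethod("tractLengths", "Connectome", function(object) object@tractLengths)
setMethod("regionLabels", "Connectome", function(object) object@labels)
setMethod("delayValues", "DelayMatrix", function(object) object@delays)
setMethod("excRates", "RateTimeSeries", function(object) object@rE)
setMethod("inhRates", "RateTimeSeries", function(object) object@rI)
setMethod("boldMatrix", "BoldTimeSeries", function(object) object@bold)
setMethod("nNodes", "BoldTimeSeries", function(object) nrow(object@bold))
setMethod("nNodes", "RateTimeSeries", function(object) nrow(object@rE))
setMethod("fcValues", "FCMatrix", function(object) object@values)
setMethod("fcdValues", "FCDMatrix", function(object)
  object@values[upper.tri(object@values)])
setMethod("fcdValues", "ReferenceSet", function(object) object@fcdValues)
setMethod("fcdValues", "DynamicsReport", function(object) object@fcdValues)
setMethod("solvedParams", "SetPointSolution", function(object) object@params)
setMethod("isFeasible", "SetPointSolution", function(object) object@feasible)

setMethod("show", "Connectome", function(object) {
  W <- object@weights
  con <- sum(W[upper.tri(W)] > 0)
  cat(sprintf("Connectome: %d nodes, %d undirected connections (density %.2f)\n",
              nrow(W), con, con / choose(nrow(W), 2)))
  cat(sprintf("  mean weight (connected) %.4g; mean tract length %.1f mm\n",
              mean(W[W > 0]), mean(object@tractLengths[W > 0])))
})

setMethod("show", "DelayMatrix", function(object) {
  cat(sprintf("DelayMatrix: mean delay %.3g ms, velocity %.3g m/s\n",
              object@meanDelay, object@velocity))
})

setMethod("show", "RateTimeSeries", function(object) {
  cat(sprintf("RateTimeSeries (%s): %d nodes x %d samples at %.3g ms (%.1f s)\n",
              object@model, nrow(object@rE), ncol(object@rE), object@dt,
              ncol(object@rE) * object@dt / 1000))
  if (object@model == "WC" && object@clamped > 0)
    cat(sprintf("  %d clamp events during integration\n", object@clamped))
})

setMethod("show", "BoldTimeSeries", function(object) {
  b <- if (all(is.na(object@band))) "unfiltered"
       else sprintf("band %.3g-%.3g Hz", object@band[1], object@band[2])
  cat(sprintf("BoldTimeSeries: %d nodes x %d TRs (TR = %.2f s, %s)\n",
              nrow(object@bold), ncol(object@bold), object@TR, b))
})

setMethod("show", "SetPointSolution", function(object) {
  cat(sprintf("SetPointSolution (%s, mechanisms %s, rho = %.4g)\n",
              object@spec@model,
              paste(object@spec@mechanisms, collapse = "+"),
              object@spec@targetRate))
  cat(sprintf("  %d/%d nodes feasible; max residual %.2e\n",
              sum(object@feasible), length(object@feasible),
              max(object@residual)))
})

setMethod("show", "DynamicsReport", function(object) {
  cat("DynamicsReport\n")
  cat(sprintf("  fit:       r_FC %.3f, MSE_FC %.4f, KS_FCD %.3f, score %.3f\n",
              object@rFC, object@mseFC, object@ksFCD, object@score))
  cat(sprintf("  dynamics:  synchrony %.3f, metastability %.3f\n",
              object@synchrony, object@metastability))
  cat(sprintf("  structure: complexity %.3f, FC-SC corr %.3f, modularity %.3f\n",
              object@complexity, object@fcScCorr, object@modularity))
})

setMethod("show", "LesionOutcome", function(object) {
  cat(sprintf("LesionOutcome: node %d\n", object@node))
  cat(sprintf("  FC distance from healthy: acute %.3f, chronic %s\n",
              object@fcDistanceAcute,
              if (object@chronicFeasible) sprintf("%.3f", object@fcDistanceChronic)
              else "infeasible"))
  cat(sprintf("  FCD KS from healthy:      acute %.3f, chronic %s\n",
              object@ksAcute,
              if (object@chronicFeasible) sprintf("%.3f", object@ksChronic)
              else "infeasible"))
})

#' Flatten a DynamicsReport to a one-row data frame
#'
#' @param x a \code{DynamicsReport}.
#' @param row.names,optional,... ignored (S3 contract).
#' @return data frame with the nine scalar observables.
#' @export
as.data.frame.DynamicsReport <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(rFC = x@rFC, mseFC = x@mseFC, ksFCD = x@ksFCD, score = x@score,
             synchrony = x@synchrony, metastability = x@metastability,
             complexity = x@complexity, fcScCorr = x@fcScCorr,
             modularity = x@modularity)
}
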