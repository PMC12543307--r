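.respec <- function(spec, rho = spec@targetRate, baseline = spec@baseline)
  new("HomeostasisSpec", model = spec@model, mechanisms = spec@mechanisms,
      targetRate = rho, baseline = baseline)

#' Run one grid point of the optimisation procedure
#'
#' The two-step optimisation procedure for one (C, rho, mean delay) combination:
#' solve the homeostatic set point; reject the point if any node is
#' infeasible; run the short validity pre-check (15 s, mean rates over the
#' last 10 s within 1\% of rho for WC, 15\% for WW); and only then run the
#' full simulation, pass it through the hemodynamic model and score it
#' against the reference. Invalid points are returned with their reason,
#' never dropped.
#'
#' @param con a \code{\linkS4class{Connectome}}.
#' @param spec a \code{\linkS4class{HomeostasisSpec}} (its target rate is
#'   overridden by \code{rho}).
#' @param C global coupling.
#' @param rho target rate.
#' @param meanDelay mean conduction delay (ms); ignored for WW.
#' @param reference a \code{\linkS4class{ReferenceSet}}.
#' @param duration full-simulation length (s); 1800 for production runs, 360 in
#'   fast mode.
#' @param seed integer seed (the pre-check derives its own from it).
#' @param noiseVariance optional override of the baseline noise variance.
#' @param TR repetition time (s).
#' @return list with \code{valid}; when valid, \code{report}
#'   (\code{\linkS4class{DynamicsReport}}) and \code{solution}; otherwise
#'   \code{reason}.
#' @export
runPoint <- function(con, spec, C, rho, meanDelay = 0, reference,
                     duration = 360, seed = 1, noiseVariance = NULL,
                     TR = 0.72) {
  spec <- .respec(spec, rho = rho)
  wc <- spec@model == "WC"
  sol <- if (wc)
    solveSetPointWC(spec, estimateExternalInput(
      con, C, rep_len(spec@baseline@P, 1), rho))
  else solveSetPointWW(spec, con, C)
  if (!all(isFeasible(sol)))
    return(list(valid = FALSE, reason = sprintf(
      "infeasible set point for node(s) %s",
      paste(which(!isFeasible(sol)), collapse = ","))))
  pars <- solvedParams(sol)
  if (!is.null(noiseVariance)) pars@noiseVariance <- noiseVariance
  dly <- if (wc) delaysFromLengths(con, meanDelay) else NULL
  dt <- if (wc) 0.2 else 1
  simFun <- if (wc) simulateWC else simulateWW

  pre <- simFun(con, pars,
                simulationConfig(C, dly, duration = 15, dt = dt,
                                 seed = seed + 10007L, outDt = 10),
                rho = rho)
  val <- checkValidity(pre, rho)
  if (!val$overall)
    return(list(valid = FALSE, reason = sprintf(
      "validity pre-check failed: max deviation %.3g", max(val$deviation))))

  sim <- simFun(con, pars,
                simulationConfig(C, dly, duration = duration, dt = dt,
                                 seed = seed, outDt = 10),
                rho = rho)
  bold <- boldFromRates(sim, TR = TR, baseline = rho)
  list(valid = TRUE, report = dynamicsReport(bold, con, reference),
       solution = sol)
}

#' Default sweep grids
#'
#' The hyper-parameter grids of the optimisation procedure: for the
#' Wilson-Cowan model 19 logarithmically spaced couplings up to 10 (the
#' uncoupled C = 0 end point included), 16 target rates in steps of 0.01
#' over [0.05, 0.2], and 41 mean delays in steps of 1 ms over [0, 40]; for
#' the Wong-Wang model 25 couplings up to 1, 10 target rates over [1, 10]
#' Hz, and no delays.
#'
#' @param model \code{"WC"} or \code{"WW"}.
#' @return list with components \code{C}, \code{rho}, \code{meanDelay}.
#' @export
sweepGrid <- function(model = c("WC", "WW")) {
  model <- match.arg(model)
  if (model == "WC")
    list(C = c(0, 10^seq(log10(0.05), 1, length.out = 18)),
         rho = seq(0.05, 0.2, by = 0.01),
         meanDelay = 0:40)
  else
    list(C = c(0, 10^seq(log10(0.005), 0, length.out = 24)),
         rho = seq(1, 10, length.out = 10),
         meanDelay = 0)
}

.reportRow <- function(rep) {
  if (is.null(rep))
    data.frame(rFC = NA_real_, mseFC = NA_real_, ksFCD = NA_real_,
               score = NA_real_, synchrony = NA_real_,
               metastability = NA_real_, complexity = NA_real_,
               fcScCorr = NA_real_, modularity = NA_real_)
  else as.data.frame(rep)
}

#' Sweep the hyper-parameter grid
#'
#' One \code{\link{runPoint}} per grid combination per seed, collected in a
#' long table with a validity flag and reason. The sweep is resumable: rows
#' already present in \code{previous} (matched on C, rho, meanDelay, seed)
#' are carried over and not recomputed.
#'
#' @param con,spec,reference,duration,TR as in \code{\link{runPoint}}.
#' @param grid list with \code{C}, \code{rho}, \code{meanDelay} vectors.
#' @param seeds integer vector of seeds.
#' @param previous optional result table from an earlier partial sweep.
#' @return data frame, one row per (C, rho, meanDelay, seed).
#' @export
runSweep <- function(con, spec, grid, reference, duration = 360,
                     seeds = 1L, previous = NULL, TR = 0.72) {
  pts <- expand.grid(C = grid$C, rho = grid$rho,
                     meanDelay = grid$meanDelay, seed = seeds,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]
    if (!is.null(previous)) {
      hit <- which(previous$C == p$C & previous$rho == p$rho &
                   previous$meanDelay == p$meanDelay & previous$seed == p$seed)
      if (length(hit)) { rows[[k]] <- previous[hit[1], ]; next }
    }
    res <- tryCatch(
      runPoint(con, spec, p$C, p$rho, p$meanDelay, reference,
               duration = duration, seed = p$seed, TR = TR),
      error = function(e) list(valid = FALSE,
                               reason = paste("error:", conditionMessage(e))))
    rows[[k]] <- cbind(data.frame(C = p$C, rho = p$rho,
                                  meanDelay = p$meanDelay, seed = p$seed,
                                  valid = res$valid,
                                  reason = if (res$valid) "" else res$reason),
                       .reportRow(if (res$valid) res$report else NULL))
  }
  do.call(rbind, rows)
}

#' Delay-averaged summaries of a sweep table
#'
#' Summarises each observable per (C, rho), averaged across the mean
#' delays yielding valid simulations.
#'
#' @param table a \code{\link{runSweep}} result.
#' @return data frame with one row per (C, rho) and a count of contributing
#'   valid delay entries.
#' @export
delayAveraged <- function(table) {
  keys <- unique(table[, c("C", "rho")])
  mets <- c("rFC", "mseFC", "ksFCD", "score", "synchrony", "metastability",
            "complexity", "fcScCorr", "modularity")
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- table[table$C == keys$C[k] & table$rho == keys$rho[k] &
                 table$valid, , drop = FALSE]
    m <- if (nrow(sub)) colMeans(sub[, mets, drop = FALSE])
         else setNames(rep(NA_real_, length(mets)), mets)
    cbind(keys[k, ], nValidDelays = length(unique(sub$meanDelay)),
          as.data.frame(as.list(m)))
  })
  do.call(rbind, out)
}

#' Select the optimal (C, rho) combination
#'
#' Among the (C, rho) combinations whose simulations are valid for at least
#' \code{minValidDelays} distinct mean delays, returns the maximiser of the
#' delay-averaged fitting score. Ties are broken by the smaller C, then the
#' smaller rho.
#'
#' @param table a \code{\link{runSweep}} result.
#' @param minValidDelays minimum number of valid mean-delay entries.
#' @return list with \code{C}, \code{rho}, \code{score},
#'   \code{nValidDelays}.
#' @export
selectOptimum <- function(table, minValidDelays = 10) {
  if (!nrow(table)) stop("empty sweep table")
  da <- delayAveraged(table)
  da <- da[da$nValidDelays >= minValidDelays & !is.na(da$score), ,
           drop = FALSE]
  if (!nrow(da))
    stop("no (C, rho) combination valid for the required number of delays")
  da <- da[order(-da$score, da$C, da$rho), ]
  list(C = da$C[1], rho = da$rho[1], score = da$score[1],
       nValidDelays = da$nValidDelays[1])
}

#' Sweep the noise variance
#'
#' Re-runs a fixed operating point across a grid of noise variances (29
#' logarithmically spaced values between 1e-5 and 10, the default) and mean
#' delays, emitting the same observable rows as \code{\link{runSweep}}.
#'
#' @param con,spec,reference,duration,TR as in \code{\link{runPoint}}.
#' @param C,rho the operating point.
#' @param delays mean delays (ms) to include.
#' @param variances noise-variance grid.
#' @param seed base seed.
#' @return data frame, one row per (variance, meanDelay).
#' @export
noiseSweep <- function(con, spec, C, rho, delays = c(4),
                       variances = 10^seq(-5, 1, length.out = 29),
                       reference, duration = 360, seed = 1, TR = 0.72) {
  pts <- expand.grid(noiseVariance = variances, meanDelay = delays,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(pts)), function(k) {
    res <- runPoint(con, spec, C, rho, pts$meanDelay[k], reference,
                    duration = duration, seed = seed + k,
                    noiseVariance = pts$noiseVariance[k], TR = TR)
    cbind(data.frame(noiseVariance = pts$noiseVariance[k],
                     meanDelay = pts$meanDelay[k], seed = seed + k,
                     valid = res$valid),
          .reportRow(if (res$valid) res$report else NULL))
  })
  do.call(rbind, rows)
}

#' Healthy / acute / chronic focal-lesion protocol
#'
#' (1) \emph{healthy}: solve the set point on the intact connectome and
#' simulate; (2) \emph{acute}: remove all connections of the chosen node,
#' keep the healthy parameters, simulate; (3) \emph{chronic}: re-solve the
#' set point on the lesioned connectome with the prelesion solved parameters
#' as the baseline anchor (homeostatic recovery of E-I balance), simulate.
#' Each stage is scored against the reference and compared with the healthy
#' stage via FC distance and the KS distance of FCD distributions.
#'
#' @param con the intact \code{\linkS4class{Connectome}} (never modified).
#' @param spec a \code{\linkS4class{HomeostasisSpec}}.
#' @param C,rho,meanDelay operating point (typically the optimum of the
#'   all-mechanisms model, with a long mean delay such as 40 ms).
#' @param node node to lesion.
#' @param reference optional \code{\linkS4class{ReferenceSet}}; defaults to
#'   the healthy stage's own FC/FCD.
#' @param duration per-stage simulation length (s).
#' @param seeds integer seeds for the three stages (fresh noise per stage).
#' @param TR repetition time (s).
#' @return a \code{\linkS4class{LesionOutcome}}.
#' @export
lesionProtocol <- function(con, spec, C, rho, meanDelay = 40, node,
                           reference = NULL, duration = 360,
                           seeds = c(1L, 2L, 3L), TR = 0.72) {
  spec <- .respec(spec, rho = rho)
  wc <- spec@model == "WC"
  dt <- if (wc) 0.2 else 1
  simFun <- if (wc) simulateWC else simulateWW
  solFun <- function(cn, sp) if (wc)
    solveSetPointWC(sp, estimateExternalInput(
      cn, C, rep_len(sp@baseline@P, 1), rho))
  else solveSetPointWW(sp, cn, C)

  stage <- function(cn, pars, seed, ref) {
    dly <- if (wc) delaysFromLengths(con, meanDelay) else NULL
    sim <- simFun(cn, pars,
                  simulationConfig(C, dly, duration = duration, dt = dt,
                                   seed = seed, outDt = 10), rho = rho)
    bold <- boldFromRates(sim, TR = TR, baseline = rho)
    dynamicsReport(bold, cn, ref)
  }

  solH <- solFun(con, spec)
  if (!all(isFeasible(solH))) stop("healthy configuration is infeasible")
  if (is.null(reference)) {
    # score stages against the healthy stage itself
    dlyH <- if (wc) delaysFromLengths(con, meanDelay) else NULL
    simH <- simFun(con, solvedParams(solH),
                   simulationConfig(C, dlyH, duration = duration, dt = dt,
                                    seed = seeds[1], outDt = 10), rho = rho)
    bpH <- bandpassBold(boldFromRates(simH, TR = TR, baseline = rho))
    reference <- referenceSet(computeFC(bpH), fcdValues(computeFCD(bpH)),
                              provenance = "surrogate")
  }
  healthy <- stage(con, solvedParams(solH), seeds[1], reference)
  lesioned <- applyLesion(con, node)
  acute <- stage(lesioned, solvedParams(solH), seeds[2], reference)

  # chronic stage: re-solve on the lesioned connectome from the same baseline
  # anchors as the healthy solve. Nodes whose external input is untouched by
  # the lesion therefore keep exactly their prelesion homeostatic parameters,
  # and only input-deprived nodes are re-balanced.
  solC <- solFun(lesioned, spec)
  feasC <- all(isFeasible(solC))
  chronic <- if (feasC) stage(lesioned, solvedParams(solC), seeds[3],
                              reference) else NULL

  new("LesionOutcome", node = as.integer(node), healthy = healthy,
      acute = acute, chronic = chronic,
      fcDistanceAcute = fcDistance(acute@fc, healthy@fc),
      fcDistanceChronic = if (feasC) fcDistance(chronic@fc, healthy@fc)
                          else NA_real_,
      ksAcute = ksDistance(fcdValues(acute), fcdValues(healthy)),
      ksChronic = if (feasC) ksDistance(fcdValues(chronic),
                                        fcdValues(healthy)) else NA_real_,
      chronicFeasible = feasC)
}

#' Rank-based group comparison with FDR correction
#'
#' Mann-Whitney U (unpaired) or Wilcoxon signed-rank (paired) tests with
#' Benjamini-Hochberg correction across a batch, plus Cohen's d effect
#' sizes. A reporting convenience for grouped simulation runs.
#'
#' @param a,b numeric vectors, or lists of numeric vectors for a batch.
#' @param paired logical.
#' @return data frame with \code{p}, \code{pAdj}, \code{d},
#'   \code{degenerate} (all values tied) per comparison.
#' @export
compareGroups <- function(a, b, paired = FALSE) {
  if (is.numeric(a)) { a <- list(a); b <- list(b) }
  stopifnot(length(a) == length(b))
  one <- function(x, y) {
    if (!length(x) || !length(y)) stop("samples must be non-empty")
    degen <- length(unique(c(x, y))) == 1
    p <- if (degen) 1 else
      suppressWarnings(wilcox.test(x, y, paired = paired)$p.value)
    d <- if (paired) {
      dd <- x - y
      if (sd(dd) == 0) 0 else mean(dd) / sd(dd)
    } else {
      sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
      if (sp == 0) 0 else (mean(x) - mean(y)) / sp
    }
    c(p = p, d = d, degenerate = degen)
  }
  res <- t(mapply(one, a, b))
  data.frame(p = res[, "p"], pAdj = p.adjust(res[, "p"], "BH"),
             d = res[, "d"], degenerate = as.logical(res[, "degenerate"]))
}
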