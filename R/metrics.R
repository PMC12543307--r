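#' Band-pass filter BOLD series
#'
#' Zero-phase (forward-backward) Butterworth band-pass with mirror padding;
#' the mean is removed. The conventional band for resting-state BOLD is
#' 0.008-0.08 Hz.
#'
#' @param bold a \code{\linkS4class{BoldTimeSeries}}.
#' @param low,high band edges (Hz); must satisfy 0 < low < high < fs/2.
#' @param order Butterworth order (applied twice by the zero-phase pass).
#' @return the filtered \code{BoldTimeSeries} with its \code{band} set.
#' @export
bandpassBold <- function(bold, low = 0.008, high = 0.08, order = 2) {
  stopifnot(is(bold, "BoldTimeSeries"))
  fs <- 1 / bold@TR
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2")
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  pad <- ceiling(1.5 / (low * bold@TR))       # ~1.5 periods of the low edge
  x <- t(apply(bold@bold, 1, function(v)
    .filtfiltPad(flt, v - mean(v), pad)))
  new("BoldTimeSeries", bold = x, TR = bold@TR, band = c(low, high))
}

#' Static functional connectivity
#'
#' Pairwise Pearson correlations between node BOLD time series.
#'
#' @param bold a \code{\linkS4class{BoldTimeSeries}} (band-pass first for
#'   the resting-state convention).
#' @return an \code{\linkS4class{FCMatrix}}.
#' @export
computeFC <- function(bold) {
  stopifnot(is(bold, "BoldTimeSeries"))
  x <- bold@bold
  if (ncol(x) < 3) stop("need at least 3 samples to correlate")
  v <- apply(x, 1, sd)
  if (any(v == 0))
    stop(sprintf("zero-variance node(s): %s",
                 paste(which(v == 0), collapse = ", ")))
  fc <- cor(t(x))
  diag(fc) <- 1
  new("FCMatrix", values = fc, band = bold@band)
}

.ut <- function(m) m[upper.tri(m)]

#' Fit of a simulated FC matrix to a reference
#'
#' Pearson correlation and mean squared error between the upper-triangular
#' (diagonal excluded) elements of the two matrices.
#'
#' @param sim,ref \code{\linkS4class{FCMatrix}} objects of equal dimension.
#' @return named vector \code{c(rFC, mseFC)}.
#' @export
fcFit <- function(sim, ref) {
  a <- fcValues(sim); b <- fcValues(ref)
  if (!all(dim(a) == dim(b))) stop("FC dimensions differ")
  ua <- .ut(a); ub <- .ut(b)
  c(rFC = cor(ua, ub), mseFC = mean((ua - ub)^2))
}

#' Functional connectivity dynamics
#'
#' FC matrices are computed in sliding windows (80 samples with 80\% overlap
#' by default, i.e. a step of 16 samples) on the already band-passed series;
#' the FCD matrix holds the Pearson correlations between the upper-triangle
#' FC vectors of every window pair. Its own upper-triangle values (including
#' near-diagonal overlapping-window pairs; an exclusion offset is available)
#' form the FCD value distribution compared across conditions.
#'
#' @param bold a band-passed \code{\linkS4class{BoldTimeSeries}}.
#' @param window window length in samples.
#' @param overlapFraction fractional overlap of consecutive windows.
#' @return an \code{\linkS4class{FCDMatrix}}; use \code{\link{fcdValues}}
#'   for the value distribution.
#' @export
computeFCD <- function(bold, window = 80, overlapFraction = 0.8) {
  stopifnot(is(bold, "BoldTimeSeries"))
  x <- bold@bold
  nT <- ncol(x)
  if (nT < window) stop("series shorter than one FCD window")
  step <- round(window * (1 - overlapFraction))
  starts <- seq(1, nT - window + 1, by = step)
  uts <- vapply(starts, function(s) .ut(cor(t(x[, s:(s + window - 1)]))),
                numeric(nrow(x) * (nrow(x) - 1) / 2))
  fcd <- cor(uts)
  diag(fcd) <- 1
  new("FCDMatrix", values = fcd, window = window,
      overlapFraction = overlapFraction)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum of the absolute difference between the two empirical CDFs.
#'
#' @param a,b non-empty numeric samples.
#' @return KS statistic in [0, 1].
#' @export
ksDistance <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
}

#' Cross-feature fitting score
#'
#' Normalises \code{r_FC - MSE_FC - KS_FCD} between its attainable extremes
#' given the reference: \code{S_max = 1} (perfect fit 1 - 0 - 0) and
#' \code{S_min = -1 - maxMSE(ref) - 1}, where \code{maxMSE(ref)} is the
#' largest MSE any FC matrix bounded in [-1, 1] can reach against the
#' reference (per-entry \code{(|ref| + 1)^2}, averaged). The score is 1 for
#' a perfect fit and 0 for the worst possible one.
#'
#' @param rFC,mseFC,ksFCD the three fit components.
#' @param ref the reference \code{\linkS4class{FCMatrix}} (or a
#'   \code{\linkS4class{ReferenceSet}}).
#' @return score in [0, 1].
#' @export
fittingScore <- function(rFC, mseFC, ksFCD, ref) {
  if (is(ref, "ReferenceSet")) ref <- ref@fc
  maxMSE <- mean((abs(.ut(fcValues(ref))) + 1)^2)
  sMin <- -1 - maxMSE - 1
  (rFC - mseFC - ksFCD - sMin) / (1 - sMin)
}

# analytic signal via FFT mask, mirror padding against edge artifacts
.analyticSignal <- function(x) {
  n <- length(x)
  pad <- min(n - 1, 100)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  m <- length(xp)
  X <- fft(xp - mean(xp))
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((m + 1) / 2)] <- 2
  }
  a <- fft(X * h, inverse = TRUE) / m
  a[(pad + 1):(pad + n)]
}

#' Kuramoto order parameter, synchrony and metastability
#'
#' Per-node instantaneous Hilbert phases of the (band-passed) BOLD series;
#' \code{R(t)} is the modulus of the mean unit phase vector across nodes.
#' Synchrony is the time-mean and metastability the time-SD of \code{R(t)},
#' with the first and last 10 samples trimmed to suppress Hilbert edge
#' artifacts.
#'
#' @param bold a band-passed \code{\linkS4class{BoldTimeSeries}}.
#' @param trim samples trimmed from each end for the summary statistics.
#' @return a \code{\linkS4class{PhaseSeries}}.
#' @export
kuramoto <- function(bold, trim = 10) {
  stopifnot(is(bold, "BoldTimeSeries"))
  x <- bold@bold
  if (nrow(x) < 2) stop("need at least 2 nodes")
  theta <- t(apply(x, 1, function(v) Arg(.analyticSignal(v))))
  z <- colMeans(exp(1i * theta))
  R <- Mod(z)
  keep <- seq_len(length(R))
  if (length(R) > 2 * trim + 2) keep <- (trim + 1):(length(R) - trim)
  new("PhaseSeries", theta = theta, R = pmin(R, 1), Phi = Arg(z),
      synchrony = mean(R[keep]), metastability = sd(R[keep]))
}

#' Functional complexity of an FC distribution
#'
#' Deviation of the FC weight distribution from uniformity:
#' \code{1 - (1/C_M) * sum_m |p_m - 1/M|} with \code{C_M = 2(M-1)/M}, over
#' \code{M} equal bins spanning [-1, 1] (M = 40 at the default bin size
#' 0.05). Equals 0 when all entries are identical and 1 when they populate
#' every bin equally. Bins are closed on the right, with -1 included in the
#' first bin.
#'
#' @param fc an \code{\linkS4class{FCMatrix}} (upper triangle used) or a
#'   numeric vector of FC values.
#' @param binSize histogram bin width; must divide the range 2 evenly.
#' @return complexity in [0, 1].
#' @export
functionalComplexity <- function(fc, binSize = 0.05) {
  v <- if (is(fc, "FCMatrix")) .ut(fcValues(fc)) else fc
  M <- 2 / binSize
  if (abs(M - round(M)) > 1e-9)
    stop("binSize must divide the FC range [-1, 1] evenly")
  M <- round(M)
  breaks <- seq(-1, 1, length.out = M + 1)
  p <- tabulate(findInterval(v, breaks, left.open = TRUE,
                             rightmost.closed = TRUE) + (v <= -1), M)
  p <- p / length(v)
  1 - sum(abs(p - 1 / M)) / (2 * (M - 1) / M)
}

.withSeed <- function(seed, expr) {
  glob <- globalenv()
  old <- if (exists(".Random.seed", envir = glob, inherits = FALSE))
    get(".Random.seed", envir = glob) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = glob)
    else if (exists(".Random.seed", envir = glob, inherits = FALSE))
      rm(".Random.seed", envir = glob)
  })
  set.seed(seed)
  force(expr)
}

#' Structural correlates of an FC matrix
#'
#' FC-SC correlation (Pearson between the upper triangles of FC and the
#' structural weights), Newman modularity of the positive-thresholded FC
#' graph under deterministic Louvain (fixed seed, resolution 1, negative
#' weights zeroed), and optionally the Euclidean distance of the FC pattern
#' from a baseline FC.
#'
#' @param fc an \code{\linkS4class{FCMatrix}}.
#' @param con the \code{\linkS4class{Connectome}}.
#' @param ref optional baseline \code{\linkS4class{FCMatrix}}.
#' @param seed seed fixed for the community search.
#' @return list with \code{fcScCorr}, \code{modularity}, \code{membership},
#'   and \code{fcDistance} (NA without \code{ref}).
#' @export
fcStructureMetrics <- function(fc, con, ref = NULL, seed = 1) {
  v <- fcValues(fc)
  W <- weightMatrix(con)
  if (!all(dim(v) == dim(W))) stop("FC and connectome dimensions differ")
  pos <- pmax(v, 0)
  diag(pos) <- 0
  g <- igraph::graph_from_adjacency_matrix(pos, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- .withSeed(seed, igraph::cluster_louvain(g, resolution = 1))
  list(fcScCorr = cor(.ut(v), .ut(W)),
       modularity = igraph::modularity(g, igraph::membership(cl),
                                       weights = igraph::E(g)$weight),
       membership = as.integer(igraph::membership(cl)),
       fcDistance = if (is.null(ref)) NA_real_ else fcDistance(fc, ref))
}

#' Euclidean distance between two FC patterns
#'
#' @param a,b \code{\linkS4class{FCMatrix}} objects of equal dimension.
#' @return Euclidean norm of the upper-triangle difference.
#' @export
fcDistance <- function(a, b) {
  ua <- .ut(fcValues(a)); ub <- .ut(fcValues(b))
  if (length(ua) != length(ub)) stop("FC dimensions differ")
  sqrt(sum((ua - ub)^2))
}

#' Full observable suite for one simulation
#'
#' Band-passes the BOLD series, computes FC, FCD, the fit against the
#' reference (r_FC, MSE_FC, KS_FCD and the cross-feature score), Kuramoto
#' synchrony/metastability, functional complexity, FC-SC correlation and FC
#' modularity, and bundles them in a \code{\linkS4class{DynamicsReport}}.
#'
#' @param bold an (unfiltered) \code{\linkS4class{BoldTimeSeries}}.
#' @param con the \code{\linkS4class{Connectome}}.
#' @param reference a \code{\linkS4class{ReferenceSet}}.
#' @param band band-pass limits (Hz).
#' @param window,overlapFraction FCD windowing.
#' @return a \code{\linkS4class{DynamicsReport}}.
#' @export
dynamicsReport <- function(bold, con, reference, band = c(0.008, 0.08),
                           window = 80, overlapFraction = 0.8) {
  stopifnot(is(reference, "ReferenceSet"))
  bp <- if (all(is.na(bold@band))) bandpassBold(bold, band[1], band[2])
        else bold
  fc <- computeFC(bp)
  fcd <- computeFCD(bp, window, overlapFraction)
  vals <- fcdValues(fcd)
  fit <- fcFit(fc, reference@fc)
  ks <- ksDistance(vals, reference@fcdValues)
  sc <- fittingScore(fit["rFC"], fit["mseFC"], ks, reference)
  ph <- kuramoto(bp)
  st <- fcStructureMetrics(fc, con)
  new("DynamicsReport", rFC = unname(fit["rFC"]),
      mseFC = unname(fit["mseFC"]), ksFCD = ks, score = unname(sc),
      synchrony = ph@synchrony, metastability = ph@metastability,
      complexity = functionalComplexity(fc), fcScCorr = st$fcScCorr,
      modularity = st$modularity, fc = fc, fcdValues = vals)
}
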