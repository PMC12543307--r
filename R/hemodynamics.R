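#' Hemodynamic constants
#'
#' Standard published Balloon-Windkessel constant set (signal decay kappa,
#' autoregulation gamma, transit time tau, Grubb exponent alpha, resting
#' oxygen extraction E0, resting venous volume V0); all overridable.
#'
#' @param kappa,gamma,tau,alpha,E0,V0,k1,k2,k3 model constants.
#' @return named list of constants.
#' @export
bwConstants <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                        alpha = 0.32, E0 = 0.34, V0 = 0.02,
                        k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2) {
  list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha, E0 = E0,
       V0 = V0, k1 = k1, k2 = k2, k3 = k3)
}

#' Balloon-Windkessel hemodynamic forward model
#'
#' Integrates, per node, the standard four-state system (vasodilatory
#' signal, inflow, venous volume, deoxyhemoglobin) driven by the excitatory
#' rate, followed by the nonlinear BOLD readout. States start at the resting
#' equilibrium of the per-node baseline drive, so a constant input equal to
#' its baseline yields a constant 0 (% change). Integration runs at a coarse
#' step (default 10 ms) on rates block-averaged from the neural sampling
#' grid, which is accurate because the hemodynamic timescales are ~1 s.
#'
#' @param rates a \code{\linkS4class{RateTimeSeries}} (its \code{dt} must
#'   divide \code{dtMs}) or a plain nodes x samples matrix.
#' @param dtMs integration/output step of the hemodynamic stage (ms).
#' @param constants from \code{\link{bwConstants}}.
#' @param baseline per-node baseline drive; defaults to the first sample.
#' @param rateDt sampling step of \code{rates} when given as a matrix (ms).
#' @return nodes x samples matrix of BOLD (% change) with attribute
#'   \code{"dtMs"}.
#' @export
balloonWindkessel <- function(rates, dtMs = 10, constants = bwConstants(),
                              baseline = NULL, rateDt = NULL) {
  if (is(rates, "RateTimeSeries")) {
    z <- rates@rE
    rateDt <- rates@dt
  } else z <- rates
  if (is.null(rateDt)) stop("rateDt required for matrix input")
  fac <- dtMs / rateDt
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("dtMs must be a positive multiple of the rate sampling step")
  fac <- as.integer(round(fac))
  if (fac > 1) {                      # block-average onto the coarse grid
    nb <- floor(ncol(z) / fac)
    z <- vapply(seq_len(nb), function(k)
      rowMeans(z[, ((k - 1) * fac + 1):(k * fac), drop = FALSE]),
      numeric(nrow(z)))
    if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  }
  if (any(!is.finite(z))) stop("rate series must be finite")
  if (is.null(baseline)) baseline <- z[, 1]
  baseline <- rep_len(baseline, nrow(z))
  cst <- constants
  bold <- .bw_integrate(z, baseline, dtMs / 1000, cst$kappa, cst$gamma,
                        cst$tau, cst$alpha, cst$E0, cst$V0,
                        cst$k1, cst$k2, cst$k3)
  attr(bold, "dtMs") <- dtMs
  bold
}

# zero-phase filtering with mirror padding to suppress edge transients
.filtfiltPad <- function(flt, x, pad) {
  n <- length(x)
  pad <- min(n - 1, pad)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(flt, xp)
  y[(pad + 1):(pad + n)]
}

#' Downsample high-rate BOLD to the scanner repetition time
#'
#' Anti-alias low-pass (zero-phase Butterworth below the TR Nyquist
#' frequency) followed by decimation on the TR grid. The guard filter is
#' harmless for the analyses downstream, which band-pass at 0.008-0.08 Hz.
#'
#' @param bold matrix from \code{\link{balloonWindkessel}} (attribute
#'   \code{"dtMs"}), or any nodes x samples matrix plus \code{dtMs}.
#' @param TR repetition time (s), default 0.72.
#' @param dtMs sampling step of \code{bold} (ms) if not carried as attribute.
#' @return a \code{\linkS4class{BoldTimeSeries}} with
#'   \code{floor(duration/TR)} samples.
#' @export
downsampleToTR <- function(bold, TR = 0.72, dtMs = attr(bold, "dtMs")) {
  if (is.null(dtMs)) stop("sampling step dtMs unknown")
  if (TR * 1000 < dtMs) stop("TR must not be finer than the input sampling")
  fs <- 1000 / dtMs
  nyqTR <- 1 / (2 * TR)
  nTR <- floor(ncol(bold) * dtMs / 1000 / TR)
  if (nTR < 1) stop("series shorter than one TR")
  flt <- signal::butter(2, 0.9 * nyqTR / (fs / 2), type = "low")
  sm <- t(apply(bold, 1, function(x) .filtfiltPad(flt, x, pad = 600)))
  idx <- pmin(round(seq_len(nTR) * TR * 1000 / dtMs), ncol(bold))
  new("BoldTimeSeries", bold = sm[, idx, drop = FALSE], TR = TR,
      band = c(NA_real_, NA_real_))
}

#' Rates to TR-sampled BOLD in one call
#'
#' @param rates a \code{\linkS4class{RateTimeSeries}}.
#' @param TR repetition time (s).
#' @param dtMs hemodynamic integration step (ms).
#' @param constants from \code{\link{bwConstants}}.
#' @param baseline per-node baseline drive (e.g. the target rate rho).
#' @return a \code{\linkS4class{BoldTimeSeries}}.
#' @export
boldFromRates <- function(rates, TR = 0.72, dtMs = 10,
                          constants = bwConstants(), baseline = NULL) {
  downsampleToTR(balloonWindkessel(rates, dtMs, constants, baseline), TR)
}
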