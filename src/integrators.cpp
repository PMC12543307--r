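// Euler-Maruyama integrators for the network models and an RK4 integrator for
// the hemodynamic forward model. All stochastic draws come from R's RNG so
// set.seed() on the R side fully determines trajectories.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double wc_sigmoid(double x, double mu, double sigma) {
  return 1.0 / (1.0 + std::exp(-(x - mu) / sigma));
}

// Wilson-Cowan network with conduction delays.
// Rates are clamped to [0,1] after each step (sigmoid-bounded targets; Euler
// can overshoot transiently); clamp events are counted.
// noiseMode: 0 = "sqrt-dt"  (variance per unit time (s), state increment
//                            sqrt(var*dt_s) * N(0,1); the default),
//            1 = "per-step" (xi ~ N(0, var) enters the Euler RHS each step)
// [[Rcpp::export(name = ".wc_integrate")]]
List wc_integrate(const arma::mat& W, const arma::imat& D,
                  const arma::vec& tauE, const arma::vec& tauI,
                  const arma::vec& cEE, const arma::vec& cEI,
                  const arma::vec& cIE, const arma::vec& GE,
                  const arma::vec& muE, const arma::vec& sigmaE,
                  const arma::vec& muI, const arma::vec& sigmaI,
                  double C, double P, double noiseSd, int noiseMode,
                  double dt, int nSteps, int outEvery,
                  const arma::vec& rE0, const arma::vec& rI0) {
  const int n = W.n_rows;
  const int L = D.max() + 1;           // ring-buffer length (delay steps)
  const int nOut = nSteps / outEvery;

  // adjacency lists over non-zero weights
  std::vector<std::vector<int>> nb(n);
  std::vector<std::vector<double>> wt(n);
  std::vector<std::vector<int>> dl(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (W(i, j) > 0.0) {
        nb[i].push_back(j);
        wt[i].push_back(W(i, j));
        dl[i].push_back(D(i, j));
      }

  arma::vec rE = rE0, rI = rI0;
  arma::mat hist(n, L);
  hist.each_col() = rE0;               // delayed terms start at the set point

  arma::mat outE(n, nOut, arma::fill::zeros);
  arma::mat outI(n, nOut, arma::fill::zeros);
  arma::vec accE(n, arma::fill::zeros), accI(n, arma::fill::zeros);

  long clamped = 0;
  const bool perStep = (noiseMode == 1);
  const double sqinc = noiseSd * std::sqrt(dt / 1000.0);  // dt is in ms

  for (int t = 0; t < nSteps; ++t) {
    hist.col(t % L) = rE;              // rE at time index t
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      const std::vector<int>& nbi = nb[i];
      const std::vector<double>& wti = wt[i];
      const std::vector<int>& dli = dl[i];
      for (size_t k = 0; k < nbi.size(); ++k) {
        int tl = (t - dli[k]) % L;
        if (tl < 0) tl += L;           // wraps onto a column still holding
                                       // the rE0 prehistory
        acc += wti[k] * hist(nbi[k], tl);
      }
      const double iext = C * acc + P;
      const double argE = GE(i) * cEE(i) * rE(i) - cEI(i) * rI(i) + GE(i) * iext;
      const double argI = cIE(i) * rE(i);
      double dE, dI;
      if (perStep) {
        const double xiE = noiseSd * norm_rand();
        const double xiI = noiseSd * norm_rand();
        dE = dt / tauE(i) * (-rE(i) + wc_sigmoid(argE, muE(i), sigmaE(i)) + xiE);
        dI = dt / tauI(i) * (-rI(i) + wc_sigmoid(argI, muI(i), sigmaI(i)) + xiI);
      } else {
        dE = dt / tauE(i) * (-rE(i) + wc_sigmoid(argE, muE(i), sigmaE(i))) +
             sqinc * norm_rand();
        dI = dt / tauI(i) * (-rI(i) + wc_sigmoid(argI, muI(i), sigmaI(i))) +
             sqinc * norm_rand();
      }
      rE(i) += dE;
      rI(i) += dI;
      if (!std::isfinite(rE(i)) || !std::isfinite(rI(i)))
        stop("non-finite state at node %d, t = %.3f ms", i + 1, (t + 1) * dt);
      if (rE(i) < 0.0) { rE(i) = 0.0; ++clamped; }
      else if (rE(i) > 1.0) { rE(i) = 1.0; ++clamped; }
      if (rI(i) < 0.0) { rI(i) = 0.0; ++clamped; }
      else if (rI(i) > 1.0) { rI(i) = 1.0; ++clamped; }
    }
    accE += rE;
    accI += rI;
    if ((t + 1) % outEvery == 0) {
      const int k = (t + 1) / outEvery - 1;
      outE.col(k) = accE / outEvery;
      outI.col(k) = accI / outEvery;
      accE.zeros();
      accI.zeros();
    }
  }

  return List::create(_["rE"] = outE, _["rI"] = outI,
                      _["clamped"] = (double)clamped,
                      _["rE_final"] = rE, _["rI_final"] = rI);
}

static inline double ww_gain(double x, double a, double b, double d) {
  const double z = a * x - b;
  const double u = d * z;
  if (std::fabs(u) < 1e-8) return 1.0 / d + z / 2.0;  // removable singularity
  return z / (1.0 - std::exp(-u));
}

// Reduced Wong-Wang network, no conduction delays, time in seconds, rates Hz.
// S^E clamped to [0,1], S^I to [0, inf).
// [[Rcpp::export(name = ".ww_integrate")]]
List ww_integrate(const arma::mat& W,
                  const arma::vec& I0, const arma::vec& wplus,
                  const arma::vec& JN, const arma::vec& JG,
                  const arma::vec& WE, const arma::vec& WI,
                  const arma::vec& GE,
                  const arma::vec& aE, const arma::vec& bE, const arma::vec& dE,
                  const arma::vec& aI, const arma::vec& bI, const arma::vec& dI,
                  const arma::vec& gamma,
                  const arma::vec& tauE, const arma::vec& tauI,
                  double C, double noiseSd, int noiseMode,
                  double dt, int nSteps, int outEvery,
                  const arma::vec& SE0, const arma::vec& SI0) {
  const int n = W.n_rows;
  const int nOut = nSteps / outEvery;
  arma::vec SE = SE0, SI = SI0;
  arma::mat outRE(n, nOut, arma::fill::zeros);
  arma::mat outRI(n, nOut, arma::fill::zeros);
  arma::vec accE(n, arma::fill::zeros), accI(n, arma::fill::zeros);
  const bool perStep = (noiseMode == 1);
  const double sqinc = noiseSd * std::sqrt(dt);   // dt is in seconds here

  for (int t = 0; t < nSteps; ++t) {
    const arma::vec net = W * SE;      // no delays in this model
    for (int i = 0; i < n; ++i) {
      const double IE = GE(i) * (WE(i) * I0(i) + wplus(i) * JN(i) * SE(i) +
                                 C * JN(i) * net(i)) - JG(i) * SI(i);
      const double II = WI(i) * I0(i) + JN(i) * SE(i) - JG(i) * SI(i);
      const double rE = ww_gain(IE, aE(i), bE(i), dE(i));
      const double rI = ww_gain(II, aI(i), bI(i), dI(i));
      double dSE, dSI;
      if (perStep) {
        dSE = dt * (-SE(i) / tauE(i) + (1.0 - SE(i)) * gamma(i) * rE +
                    noiseSd * norm_rand());
        dSI = dt * (-SI(i) / tauI(i) + rI + noiseSd * norm_rand());
      } else {
        dSE = dt * (-SE(i) / tauE(i) + (1.0 - SE(i)) * gamma(i) * rE) +
              sqinc * norm_rand();
        dSI = dt * (-SI(i) / tauI(i) + rI) + sqinc * norm_rand();
      }
      SE(i) += dSE;
      SI(i) += dSI;
      if (!std::isfinite(SE(i)) || !std::isfinite(SI(i)))
        stop("non-finite gating at node %d, t = %.3f s", i + 1, (t + 1) * dt);
      if (SE(i) < 0.0) SE(i) = 0.0;
      else if (SE(i) > 1.0) SE(i) = 1.0;
      if (SI(i) < 0.0) SI(i) = 0.0;
      accE(i) += rE;
      accI(i) += rI;
    }
    if ((t + 1) % outEvery == 0) {
      const int k = (t + 1) / outEvery - 1;
      outRE.col(k) = accE / outEvery;
      outRI.col(k) = accI / outEvery;
      accE.zeros();
      accI.zeros();
    }
  }
  return List::create(_["rE"] = outRE, _["rI"] = outRI,
                      _["SE_final"] = SE, _["SI_final"] = SI);
}

struct BWConst { double kappa, gam, tau, alpha, E0; };

static inline void bw_deriv(const double* x, double z, const BWConst& c,
                            double* dx) {
  const double s = x[0], f = x[1], v = x[2], q = x[3];
  const double fv = std::pow(v, 1.0 / c.alpha);
  const double Ef = 1.0 - std::pow(1.0 - c.E0, 1.0 / f);
  dx[0] = z - c.kappa * s - c.gam * (f - 1.0);
  dx[1] = s;
  dx[2] = (f - fv) / c.tau;
  dx[3] = (f * Ef / c.E0 - fv * q / v) / c.tau;
}

// Balloon-Windkessel model, one independent 4-state system per node, RK4 with
// the neural drive held constant within each input sample. States start at
// the equilibrium of the per-node baseline drive; the returned signal is the
// BOLD %-change relative to that equilibrium.
// [[Rcpp::export(name = ".bw_integrate")]]
arma::mat bw_integrate(const arma::mat& z, const arma::vec& baseline,
                       double dt, double kappa, double gam, double tau,
                       double alpha, double E0, double V0,
                       double k1, double k2, double k3) {
  const int n = z.n_rows, T = z.n_cols;
  const BWConst cc{kappa, gam, tau, alpha, E0};
  arma::mat bold(n, T);
  for (int i = 0; i < n; ++i) {
    // resting equilibrium for the baseline drive
    const double f0 = 1.0 + baseline(i) / gam;
    const double v0 = std::pow(f0, alpha);
    const double E0f = 1.0 - std::pow(1.0 - E0, 1.0 / f0);
    const double q0 = f0 * E0f / E0 * std::pow(v0, 1.0 - 1.0 / alpha);
    double x[4] = {0.0, f0, v0, q0};
    const double b0 = 100.0 * V0 *
      (k1 * (1.0 - q0) + k2 * (1.0 - q0 / v0) + k3 * (1.0 - v0));
    double d1[4], d2[4], d3[4], d4[4], xt[4];
    for (int t = 0; t < T; ++t) {
      const double zz = z(i, t);
      bw_deriv(x, zz, cc, d1);
      for (int k = 0; k < 4; ++k) xt[k] = x[k] + 0.5 * dt * d1[k];
      bw_deriv(xt, zz, cc, d2);
      for (int k = 0; k < 4; ++k) xt[k] = x[k] + 0.5 * dt * d2[k];
      bw_deriv(xt, zz, cc, d3);
      for (int k = 0; k < 4; ++k) xt[k] = x[k] + dt * d3[k];
      bw_deriv(xt, zz, cc, d4);
      for (int k = 0; k < 4; ++k)
        x[k] += dt / 6.0 * (d1[k] + 2.0 * d2[k] + 2.0 * d3[k] + d4[k]);
      if (!std::isfinite(x[2]) || x[2] <= 0.0)
        stop("hemodynamic state diverged at node %d, t = %.2f s",
             i + 1, (t + 1) * dt);
      bold(i, t) = 100.0 * V0 * (k1 * (1.0 - x[3]) +
                   k2 * (1.0 - x[3] / x[2]) + k3 * (1.0 - x[2])) - b0;
    }
  }
  return bold;
}
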