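// Discretized pairwise sequentially-Markovian-coalescent HMM.
//
// Hidden state: the atomic time interval containing the local TMRCA of one
// haplotype pair, on a grid of n intervals [T_0=0, T_1), ..., [T_{n-1}, inf)
// in coalescent units (2 N0 generations). Piecewise-constant coalescence
// intensity lambda_k per interval.
//
// Transitions follow the SMC' picture: with probability exp(-rho * t) the
// bin inherits the previous TMRCA t; otherwise a recombination occurs at a
// uniform height u in (0, t), and the floating lineage re-coalesces at rate
// 2*lambda(s) while s < t (half of those events restore the old TMRCA, half
// set the new TMRCA to s), or survives to t and coalesces at rate lambda(s)
// above. All u- and s-integrals are closed-form per grid piece, expressed in
// differences of cumulative hazard so no exponential ever overflows.
//
// Emissions: P(het | state j) = 1 - exp(-theta * tbar_j), with tbar_j the
// conditional mean TMRCA of interval j under the current lambda. Missing
// bins emit probability 1 in every state.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double expm1_ratio(double x) {
  // (1 - exp(-x)) / x, stable near 0
  if (std::fabs(x) < 1e-8) return 1.0 - x / 2.0;
  return -std::expm1(-x) / x;
}

// [[Rcpp::export(name = ".smcModel")]]
List smcModel(NumericVector bounds, NumericVector lambda, double rho,
              double theta) {
  const int n = lambda.size();
  if (bounds.size() != n)
    stop("bounds must hold the lower boundary of each interval");

  // cumulative hazard at lower boundaries
  std::vector<double> L(n + 1);
  L[0] = 0.0;
  for (int k = 1; k < n; ++k)
    L[k] = L[k - 1] + lambda[k - 1] * (bounds[k] - bounds[k - 1]);
  L[n] = R_PosInf;

  // conditional mean TMRCA per interval
  NumericVector tbar(n);
  for (int j = 0; j < n; ++j) {
    double a = bounds[j];
    double lam = lambda[j];
    if (j == n - 1) {
      tbar[j] = a + 1.0 / lam;
    } else {
      double d = bounds[j + 1] - a;
      double x = lam * d;
      if (x < 1e-8) tbar[j] = a + d / 2.0;
      else tbar[j] = a + 1.0 / lam - d * std::exp(-x) / (-std::expm1(-x));
    }
  }

  // prior (equilibrium TMRCA distribution)
  NumericVector prior(n);
  for (int j = 0; j < n; ++j) {
    double hi = (j == n - 1) ? 0.0 : std::exp(-L[j + 1]);
    prior[j] = std::exp(-L[j]) - hi;
  }

  // emissions
  NumericVector ehet(n);
  for (int j = 0; j < n; ++j) ehet[j] = -std::expm1(-theta * tbar[j]);

  // hazard value at an arbitrary time x (x within interval containing it)
  auto Lam = [&](double x) {
    int k = n - 1;
    for (int i = 0; i < n; ++i)
      if (i == n - 1 || x < bounds[i + 1]) { k = i; break; }
    return L[k] + lambda[k] * (x - bounds[k]);
  };

  NumericMatrix P(n, n);
  for (int i = 0; i < n; ++i) {
    double t = tbar[i];
    double Lt = Lam(t);
    std::vector<double> R(n, 0.0);
    // u-pieces below t
    for (int k = 0; k <= i; ++k) {
      double a = bounds[k];
      double b = (k == i) ? t : std::min(bounds[k + 1], t);
      if (b <= a) continue;
      double width = b - a;
      double Lbb = L[k] + lambda[k] * width; // hazard at b
      // Wk = (1 - exp(-2 lam width)) / (2 lam), stable for small rates
      double Wk = width * expm1_ratio(2.0 * lambda[k] * width);
      auto Eb = [&](double Lx) { // exp(-2 (Lam(x) - Lam(b))), Lx = Lam(x)
        double d = 2.0 * (Lx - Lbb);
        return (d > 700.0) ? 0.0 : std::exp(-d);
      };
      // same-interval target (s in (u, min(T_{k+1}, t)))
      double dSame = (k == i) ? t : std::min(bounds[k + 1], t);
      double LdSame = L[k] + lambda[k] * (dSame - bounds[k]);
      R[k] += 0.5 * (width - Wk * Eb(LdSame));
      // strictly higher targets below t
      for (int j = k + 1; j <= i; ++j) {
        double c = bounds[j];
        double d = (j == i) ? t : std::min(bounds[j + 1], t);
        if (d <= c) continue;
        double Lc = L[j];
        double Ld = L[j] + lambda[j] * (d - bounds[j]);
        R[j] += 0.5 * Wk * (Eb(Lc) - Eb(Ld));
      }
      // self-coalescence: restore TMRCA t (state i)
      R[i] += 0.5 * (width - Wk * Eb(Lt));
      // survive to t, then single-lineage coalescence above
      double surv = Wk * Eb(Lt);
      if (surv > 0) {
        for (int j = i; j < n; ++j) {
          double Fc = (j == i) ? 1.0 : std::exp(-std::min(L[j] - Lt, 700.0));
          double Fd = (j == n - 1) ? 0.0
                      : std::exp(-std::min(L[j + 1] - Lt, 700.0));
          R[j] += surv * (Fc - Fd);
        }
      }
    }
    // normalize over u (uniform on (0,t)) and guard drift
    double tot = 0.0;
    for (int j = 0; j < n; ++j) { R[j] /= t; tot += R[j]; }
    double prec = -std::expm1(-rho * t);
    for (int j = 0; j < n; ++j) {
      double rj = (tot > 0) ? R[j] / tot : prior[j];
      P(i, j) = prec * rj + ((i == j) ? (1.0 - prec) : 0.0);
    }
  }

  return List::create(_["P"] = P, _["prior"] = prior, _["tbar"] = tbar,
                      _["ehet"] = ehet);
}

// [[Rcpp::export(name = ".smcEstep")]]
List smcEstep(List obsList, NumericMatrix P, NumericVector prior,
              NumericVector ehet, bool stats = true) {
  const int n = prior.size();
  NumericMatrix xi(n, n);
  NumericVector gamma1(n), hetC(n), homC(n);
  double ll = 0.0, bll = 0.0;

  std::vector<double> ehom(n);
  for (int j = 0; j < n; ++j) ehom[j] = 1.0 - ehet[j];

  // row-major copy of P for cache-friendly backward/xi passes, and a
  // column-major view for the forward pass
  std::vector<double> Prow((size_t)n * n), Pcol((size_t)n * n);
  std::vector<double> xiAcc((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      Prow[(size_t)i * n + j] = P(i, j);
      Pcol[(size_t)j * n + i] = P(i, j);
    }

  for (int s = 0; s < obsList.size(); ++s) {
    IntegerVector obs = obsList[s];
    const int B = obs.size();
    if (B == 0) continue;
    std::vector<double> alpha((size_t)B * n);
    std::vector<double> scale(B);

    auto emit = [&](int o, int j) -> double {
      if (o == 1) return ehet[j];
      if (o == 0) return ehom[j];
      return 1.0;
    };

    // forward
    {
      double c = 0.0;
      for (int j = 0; j < n; ++j) {
        double v = prior[j] * emit(obs[0], j);
        alpha[j] = v; c += v;
      }
      scale[0] = c;
      for (int j = 0; j < n; ++j) alpha[j] /= c;
    }
    for (int t = 1; t < B; ++t) {
      double *prev = &alpha[(size_t)(t - 1) * n];
      double *cur = &alpha[(size_t)t * n];
      int o = obs[t];
      double c = 0.0;
      for (int j = 0; j < n; ++j) {
        const double *pc = &Pcol[(size_t)j * n];
        double acc = 0.0;
        for (int i = 0; i < n; ++i) acc += prev[i] * pc[i];
        double v = acc * emit(o, j);
        cur[j] = v; c += v;
      }
      scale[t] = c;
      for (int j = 0; j < n; ++j) cur[j] /= c;
    }
    for (int t = 0; t < B; ++t) ll += std::log(scale[t]);

    if (!stats) continue;

    // backward with the forward scale factors, accumulating xi and gamma
    std::vector<double> beta(n, 1.0), betaNext(n);
    {
      // t = B-1 contribution to gamma/emission counts
      double *aT = &alpha[(size_t)(B - 1) * n];
      int o = obs[B - 1];
      for (int j = 0; j < n; ++j) {
        double g = aT[j]; // beta = 1
        if (o == 1) hetC[j] += g;
        else if (o == 0) homC[j] += g;
        if (B == 1) gamma1[j] += g;
      }
    }
    std::vector<double> w(n);
    for (int t = B - 2; t >= 0; --t) {
      double *aPrev = &alpha[(size_t)t * n];
      int oNext = obs[t + 1];
      double cNext = scale[t + 1];
      for (int j = 0; j < n; ++j) w[j] = emit(oNext, j) * beta[j] / cNext;
      // fused: betaNext_i = sum_j P_ij w_j and xi_ij += alpha_i P_ij w_j
      for (int i = 0; i < n; ++i) {
        const double *pr = &Prow[(size_t)i * n];
        double *xr = &xiAcc[(size_t)i * n];
        const double ai = aPrev[i];
        double acc = 0.0;
        for (int j = 0; j < n; ++j) {
          double v = pr[j] * w[j];
          acc += v;
          xr[j] += ai * v;
        }
        betaNext[i] = acc;
      }
      std::swap(beta, betaNext);
      // gamma at t
      int o = obs[t];
      double norm = 0.0;
      for (int j = 0; j < n; ++j) norm += aPrev[j] * beta[j];
      for (int j = 0; j < n; ++j) {
        double g = aPrev[j] * beta[j] / norm;
        if (o == 1) hetC[j] += g;
        else if (o == 0) homC[j] += g;
        if (t == 0) gamma1[j] += g;
      }
    }
    // backward log-likelihood check
    double pb = 0.0;
    for (int j = 0; j < n; ++j) pb += prior[j] * emit(obs[0], j) * beta[j];
    double acc = std::log(pb);
    for (int t = 1; t < B; ++t) acc += std::log(scale[t]);
    bll += acc;
  }

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) xi(i, j) = xiAcc[(size_t)i * n + j];

  return List::create(_["loglik"] = ll, _["loglik_backward"] = bll,
                      _["xi"] = xi, _["gamma1"] = gamma1,
                      _["het"] = hetC, _["hom"] = homC);
}
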