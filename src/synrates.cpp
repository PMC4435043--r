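#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the single-compartment conductance model:
//   C dV/dt = -gL (V - EL) - gE(t) (V - VE) - gI(t) (V - VI)
// with the total synaptic conductance paths gE, gI precomputed on the grid.
// Units: nF, nS, mV, ms (nS * mV = pA; pA / nF * ms = 1e-3 mV, hence the
// 1e-3 factor folded into dt_over_C).
// [[Rcpp::export]]
NumericVector euler_voltage(NumericVector gE, NumericVector gI,
                            double C, double gL, double EL,
                            double VE, double VI, double dt, double V0) {
  int n = gE.size();
  if (gI.size() != n) stop("gE and gI must have equal length");
  NumericVector V(n);
  double v = V0;
  double dt_over_C = dt / C * 1e-3;
  V[0] = v;
  for (int j = 1; j < n; ++j) {
    double I = -gL * (v - EL) - gE[j - 1] * (v - VE) - gI[j - 1] * (v - VI);
    v += dt_over_C * I;
    if (v > 200.0 || v < -200.0)
      stop("Voltage exceeded 200 mV in magnitude: reduce the time step dt");
    V[j] = v;
  }
  return V;
}

// Bootstrap particle filter with systematic resampling plus a
// backward-simulation smoother for the state (M_j, S_j) with Gaussian
// random-walk transitions and observation Z_j ~ N(M dt, exp(S) dt).
// Invalid steps propagate without a weight update.  Uses R's RNG, so
// results are reproducible under set.seed().
//
// The backward pass reuses the stored filter clouds.  Per step the
// particles are kept sorted by S so that, given the next trajectory
// point, only particles inside +/- 6 transition-SD in S are examined
// (the Gaussian transition weight of anything outside is < 2e-8 of the
// peak); a cheap |dM| pre-test skips the exponential for particles far
// away in M.  Particle histories are stored in single precision to keep
// 1e5-particle runs within memory.
// [[Rcpp::export]]
List particle_smoother_cpp(NumericVector z, NumericVector dt,
                           LogicalVector valid,
                           double gamma_M, double gamma_S,
                           double m0, double s0, double v0m, double v0s,
                           int n_particles, int n_draws,
                           double ess_frac) {
  int K = z.size(), N = n_particles, B = n_draws;
  if (K < 2) stop("Need at least two steps");
  if (gamma_M < 0.0 || gamma_S < 0.0) stop("Hyperparameters must be >= 0");
  // a zero hyperparameter freezes that component (requires zero prior
  // spread so that all particles share its value and the degenerate
  // transition density cancels in the backward weights)
  if ((gamma_M == 0.0 && v0m > 0.0) || (gamma_S == 0.0 && v0s > 0.0))
    stop("A zero hyperparameter requires zero prior variance for that component");
  double qm = gamma_M * gamma_M, qs = gamma_S * gamma_S;
  // per-step history, sorted by S: S ascending, matching M and log-weight
  std::vector<std::vector<float> > Sh(K), Mh(K), LWh(K);
  std::vector<std::vector<double> > CWlast;  // filled only at K-1
  NumericVector mf1(K), mf2(K), ess_out(K);
  std::vector<double> M(N), S(N), W(N), cw(N);
  std::vector<int> ord(N);
  double sm0 = std::sqrt(v0m), ss0 = std::sqrt(v0s);
  for (int i = 0; i < N; ++i) {
    M[i] = m0 + sm0 * R::norm_rand();
    S[i] = s0 + ss0 * R::norm_rand();
    W[i] = 1.0 / N;
  }
  const double log2pi = std::log(2.0 * M_PI);
  for (int j = 0; j < K; ++j) {
    if (j > 0) {
      double sdm = std::sqrt(qm * dt[j - 1]), sds = std::sqrt(qs * dt[j - 1]);
      for (int i = 0; i < N; ++i) {
        if (sdm > 0.0) M[i] += sdm * R::norm_rand();
        if (sds > 0.0) S[i] += sds * R::norm_rand();
      }
    }
    if (valid[j]) {
      double d = dt[j], zz = z[j];
      double maxl = R_NegInf;
      std::vector<double> lw(N);
      for (int i = 0; i < N; ++i) {
        double r = zz - M[i] * d;
        double l = -0.5 * (r * r * std::exp(-S[i]) / d + S[i] + std::log(d) + log2pi);
        lw[i] = std::log(W[i]) + l;
        if (lw[i] > maxl) maxl = lw[i];
      }
      double tot = 0.0;
      for (int i = 0; i < N; ++i) { W[i] = std::exp(lw[i] - maxl); tot += W[i]; }
      for (int i = 0; i < N; ++i) W[i] /= tot;
    }
    double sw2 = 0.0, m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < N; ++i) {
      sw2 += W[i] * W[i];
      m1 += W[i] * M[i];
      m2 += W[i] * S[i];
    }
    ess_out[j] = 1.0 / sw2;
    mf1[j] = m1; mf2[j] = m2;
    // store the cloud sorted by S
    for (int i = 0; i < N; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return S[a] < S[b]; });
    Sh[j].resize(N); Mh[j].resize(N); LWh[j].resize(N);
    for (int i = 0; i < N; ++i) {
      int k = ord[i];
      Sh[j][i] = (float)S[k];
      Mh[j][i] = (float)M[k];
      LWh[j][i] = (float)std::log(W[k] + 1e-300);
    }
    if (ess_out[j] < ess_frac * N && j < K - 1) {  // systematic resampling
      double c = 0.0;
      for (int i = 0; i < N; ++i) { c += W[i]; cw[i] = c; }
      double u0 = R::unif_rand() / N;
      std::vector<double> Mn(N), Sn(N);
      int idx = 0;
      for (int i = 0; i < N; ++i) {
        double u = u0 + (double)i / N;
        while (idx < N - 1 && cw[idx] < u) ++idx;
        Mn[i] = M[idx]; Sn[i] = S[idx];
      }
      M = Mn; S = Sn;
      for (int i = 0; i < N; ++i) W[i] = 1.0 / N;
    }
  }
  // cumulative weights of the sorted final-step cloud
  std::vector<double> cwK(N);
  {
    double c = 0.0;
    for (int i = 0; i < N; ++i) { c += std::exp((double)LWh[K - 1][i]); cwK[i] = c; }
    for (int i = 0; i < N; ++i) cwK[i] /= c;
  }
  // backward simulation: B independent smoothed trajectories
  NumericVector ms1(K), ms2(K), vs1(K), vs2(K);
  std::vector<double> trajM(K), trajS(K), wbuf(N);
  std::vector<double> sum1(K, 0.0), sum2(K, 0.0), sq1(K, 0.0), sq2(K, 0.0);
  for (int b = 0; b < B; ++b) {
    {
      double u = R::unif_rand();
      int lo = 0, hi = N - 1;
      while (lo < hi) { int mid = (lo + hi) / 2; if (cwK[mid] < u) lo = mid + 1; else hi = mid; }
      trajM[K - 1] = Mh[K - 1][lo]; trajS[K - 1] = Sh[K - 1][lo];
    }
    for (int j = K - 2; j >= 0; --j) {
      double im = qm > 0.0 ? 0.5 / (qm * dt[j]) : 0.0;
      double is = qs > 0.0 ? 0.5 / (qs * dt[j]) : 0.0;
      double mS = trajS[j + 1], mM = trajM[j + 1];
      int lo = 0, hi = N;
      if (qs > 0.0) {  // restrict to the S window with non-negligible weight
        float sLo = (float)(mS - 6.0 * std::sqrt(qs * dt[j]));
        float sHi = (float)(mS + 6.0 * std::sqrt(qs * dt[j]));
        lo = (int)(std::lower_bound(Sh[j].begin(), Sh[j].end(), sLo) - Sh[j].begin());
        hi = (int)(std::upper_bound(Sh[j].begin(), Sh[j].end(), sHi) - Sh[j].begin());
        if (lo >= hi) { lo = 0; hi = N; }  // fallback: full scan
      }
      double tot = 0.0;
      // transition log-weights below -30 relative to the peak contribute
      // < 1e-13 of the mass; skip their exponentials
      for (int i = lo; i < hi; ++i) {
        double dM = mM - (double)Mh[j][i];
        double a = im * dM * dM;
        double w = 0.0;
        if (a < 30.0) {
          double dS = mS - (double)Sh[j][i];
          a += is * dS * dS;
          if (a < 30.0) w = std::exp((double)LWh[j][i] - a);
        }
        wbuf[i] = w;
        tot += w;
      }
      int pick;
      if (tot <= 0.0) {  // degenerate window: fall back to filter weights
        double t2 = 0.0;
        for (int i = lo; i < hi; ++i) { wbuf[i] = std::exp((double)LWh[j][i]); t2 += wbuf[i]; }
        double target = R::unif_rand() * t2, acc = 0.0;
        pick = hi - 1;
        for (int i = lo; i < hi; ++i) { acc += wbuf[i]; if (acc >= target) { pick = i; break; } }
      } else {
        double target = R::unif_rand() * tot, acc = 0.0;
        pick = hi - 1;
        for (int i = lo; i < hi; ++i) { acc += wbuf[i]; if (acc >= target) { pick = i; break; } }
      }
      trajM[j] = Mh[j][pick]; trajS[j] = Sh[j][pick];
    }
    for (int j = 0; j < K; ++j) {
      sum1[j] += trajM[j]; sum2[j] += trajS[j];
      sq1[j] += trajM[j] * trajM[j]; sq2[j] += trajS[j] * trajS[j];
    }
  }
  for (int j = 0; j < K; ++j) {
    ms1[j] = sum1[j] / B;
    ms2[j] = sum2[j] / B;
    vs1[j] = sq1[j] / B - ms1[j] * ms1[j];
    vs2[j] = sq2[j] / B - ms2[j] * ms2[j];
  }
  return List::create(_["m_hat"] = ms1, _["s_hat"] = ms2,
                      _["m_var"] = vs1, _["s_var"] = vs2,
                      _["m_filt"] = mf1, _["s_filt"] = mf2,
                      _["ess"] = ess_out);
}
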