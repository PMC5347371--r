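#include <Rcpp.h>
using namespace Rcpp;

// All hot-loop kernels work on the transposed field eT (n x T, one column
// per SNP) so that a SNP's indicator vector is contiguous in memory.
//
// lyT holds log(y) (R_NegInf where y <= 0) and hy2T holds y^2/2, both
// n x T; from these the signal-vs-null emission log-likelihood ratio
//   llr = -log y - log(sigma)/... - (log y - mu)^2/(2 sigma2) + y^2/2
// is a handful of flops per entry, no transcendentals inside the sweep.

// One or more systematic-scan Gibbs sweeps over the latent field,
// updating eT IN PLACE, followed by one stats pass. Returns the
// per-phenotype counts S, pair counts S_pair, sums of log y and (log y)^2
// over active entries (conjugate signal updates), and the summed active
// log-likelihood ratio (log-posterior bookkeeping). When accum is true,
// running sums accET (n x T) and accPT (P x T) are incremented in place.
// [[Rcpp::export(name = ".mcmc_sweep_cpp")]]
List mcmc_sweep_cpp(IntegerMatrix eT, NumericMatrix lyT, NumericMatrix hy2T,
                    NumericVector alpha, NumericMatrix beta,
                    NumericVector mu, NumericVector sigma2, int nsweep,
                    NumericMatrix accET, NumericMatrix accPT,
                    IntegerMatrix pairs0, bool accum) {
  const int n = eT.nrow(), T = eT.ncol(), P = pairs0.nrow();
  NumericMatrix llr(n, T);
  {
    std::vector<double> c0(n), inv2(n);
    for (int i = 0; i < n; ++i) {
      c0[i] = -0.5 * std::log(sigma2[i]);
      inv2[i] = 0.5 / sigma2[i];
    }
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < n; ++i) {
        const double ly = lyT(i, t);
        if (ly == R_NegInf) { llr(i, t) = R_NegInf; continue; }
        const double d = ly - mu[i];
        llr(i, t) = c0[i] - ly - d * d * inv2[i] + hy2T(i, t);
      }
  }

  for (int s = 0; s < nsweep; ++s) {
    for (int t = 0; t < T; ++t) {
      int *et = &eT(0, t);
      for (int i = 0; i < n; ++i) {
        const double L = llr(i, t);
        if (L == R_NegInf) { et[i] = 0; continue; }
        double eta = alpha[i] + L;
        for (int j = 0; j < n; ++j)
          if (et[j] && j != i) eta += beta(j, i);
        const double p = 1.0 / (1.0 + std::exp(-eta));
        et[i] = (unif_rand() < p) ? 1 : 0;
      }
    }
  }

  NumericVector S(n), Slz(n), Slz2(n);
  NumericMatrix Sp(n, n);
  double llr_active = 0.0;
  for (int t = 0; t < T; ++t) {
    const int *et = &eT(0, t);
    for (int i = 0; i < n; ++i) {
      if (!et[i]) continue;
      const double ly = lyT(i, t);
      S[i] += 1.0;
      Slz[i] += ly;
      Slz2[i] += ly * ly;
      llr_active += llr(i, t);
      for (int j = i + 1; j < n; ++j)
        if (et[j]) { Sp(i, j) += 1.0; Sp(j, i) += 1.0; }
    }
    if (accum) {
      for (int i = 0; i < n; ++i)
        if (et[i]) accET(i, t) += 1.0;
      for (int k = 0; k < P; ++k)
        if (et[pairs0(k, 0)] && et[pairs0(k, 1)]) accPT(k, t) += 1.0;
    }
  }
  return List::create(_["S"] = S, _["S_pair"] = Sp, _["Slz"] = Slz,
                      _["Slz2"] = Slz2, _["llr_active"] = llr_active);
}

// Per-SNP block Gibbs update: redraw each SNP's full indicator vector from
// its exact conditional over all 2^n joint states (states and their MRF
// energies are passed in; the emission term is added per SNP). This kernel
// mixes across strongly coupled configurations that componentwise flips
// traverse slowly. Updates eT IN PLACE.
// Restricting to SNPs t = offset, offset + stride, ... (0-based) lets the
// caller refresh one stratum per sweep at a fixed total budget.
// [[Rcpp::export(name = ".block_sweep_cpp")]]
void block_sweep_cpp(IntegerMatrix eT, NumericMatrix lyT, NumericMatrix hy2T,
                     NumericVector mu, NumericVector sigma2,
                     IntegerMatrix states, NumericVector energy,
                     int offset, int stride) {
  const int n = eT.nrow(), T = eT.ncol(), S = states.nrow();
  std::vector<double> llr_t(n), w(S);
  std::vector<double> c0(n), inv2(n);
  for (int i = 0; i < n; ++i) {
    c0[i] = -0.5 * std::log(sigma2[i]);
    inv2[i] = 0.5 / sigma2[i];
  }
  for (int t = offset; t < T; t += stride) {
    for (int i = 0; i < n; ++i) {
      const double ly = lyT(i, t);
      if (ly == R_NegInf) { llr_t[i] = R_NegInf; continue; }
      const double d = ly - mu[i];
      llr_t[i] = c0[i] - ly - d * d * inv2[i] + hy2T(i, t);
    }
    double mx = R_NegInf;
    for (int s = 0; s < S; ++s) {
      double lw = energy[s];
      for (int i = 0; i < n; ++i)
        if (states(s, i)) {
          if (llr_t[i] == R_NegInf) { lw = R_NegInf; break; }
          lw += llr_t[i];
        }
      w[s] = lw;
      if (lw > mx) mx = lw;
    }
    double tot = 0.0;
    for (int s = 0; s < S; ++s) {
      w[s] = (w[s] == R_NegInf) ? 0.0 : std::exp(w[s] - mx);
      tot += w[s];
    }
    double u = unif_rand() * tot;
    int pick = -1;
    for (int s = 0; s < S; ++s) {
      if (w[s] <= 0.0) continue;
      u -= w[s];
      if (u <= 0.0) { pick = s; break; }
    }
    if (pick < 0)  // guard against accumulated rounding at u ~ tot
      for (int s = S - 1; s >= 0; --s) if (w[s] > 0.0) { pick = s; break; }
    for (int i = 0; i < n; ++i) eT(i, t) = states(pick, i);
  }
}

// Draw a latent field from the bare MRF (no data term) by componentwise
// Gibbs: all-zero start, nsweep systematic scans; SNPs independent.
// Returns the field transposed (n x T).
// [[Rcpp::export(name = ".simulate_field_cpp")]]
IntegerMatrix simulate_field_cpp(int T, NumericVector alpha,
                                 NumericMatrix beta, int nsweep) {
  const int n = alpha.size();
  IntegerMatrix eT(n, T);
  for (int s = 0; s < nsweep; ++s) {
    for (int t = 0; t < T; ++t) {
      int *et = &eT(0, t);
      for (int i = 0; i < n; ++i) {
        double eta = alpha[i];
        for (int j = 0; j < n; ++j)
          if (et[j] && j != i) eta += beta(j, i);
        const double p = 1.0 / (1.0 + std::exp(-eta));
        et[i] = (unif_rand() < p) ? 1 : 0;
      }
    }
  }
  return eT;
}
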