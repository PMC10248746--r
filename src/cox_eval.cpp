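// Partial-likelihood kernels for the time-dependent proportional hazards
// engine.  Counting-process data: a row is at risk on (tstart, tstop], the
// event flag marks a primary event at tstop.  Case weights carry both
// IPTW and Fine-Gray IPCW contributions; ties are handled by the Efron or
// Breslow approximation with weighted death counts (the Efron step count d
// is the unweighted number of tied death rows, as in the survival package).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Evaluate log partial likelihood, score and (optionally) the observed
// information at beta.  Rows need not be sorted.  The linear predictor is
// centred by its weighted mean before exponentiation; all returned
// quantities are invariant to that shift.
// [[Rcpp::export]]
List cox_eval_cpp(NumericVector tstart, NumericVector tstop,
                  IntegerVector event, NumericMatrix X, NumericVector w,
                  NumericVector beta, bool efron, bool need_info) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xt((size_t)n * p);  // row-contiguous copy
  for (int a = 0; a < p; ++a)
    for (int i = 0; i < n; ++i) xt[(size_t)i * p + a] = X(i, a);

  std::vector<double> eta(n), r(n);
  double wsum = 0.0, ebar = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    const double* x = &xt[(size_t)i * p];
    for (int a = 0; a < p; ++a) e += x[a] * beta[a];
    eta[i] = e;
    wsum += w[i];
    ebar += w[i] * e;
  }
  ebar = (wsum > 0.0) ? ebar / wsum : 0.0;
  for (int i = 0; i < n; ++i) r[i] = std::exp(eta[i] - ebar);

  std::vector<int> by_stop(n), by_start(n);
  for (int i = 0; i < n; ++i) by_stop[i] = by_start[i] = i;
  std::sort(by_stop.begin(), by_stop.end(),
            [&](int a, int b) { return tstop[a] > tstop[b]; });
  std::sort(by_start.begin(), by_start.end(),
            [&](int a, int b) { return tstart[a] > tstart[b]; });
  std::vector<int> deaths;
  for (int i : by_stop)
    if (event[i]) deaths.push_back(i);  // descending tstop

  double S0 = 0.0;
  std::vector<double> S1(p, 0.0), S2(need_info ? (size_t)p * p : 0, 0.0);
  auto upd = [&](int i, double sign) {
    const double wr = sign * w[i] * r[i];
    const double* x = &xt[(size_t)i * p];
    S0 += wr;
    for (int a = 0; a < p; ++a) {
      S1[a] += wr * x[a];
      if (need_info)
        for (int b = 0; b <= a; ++b) S2[(size_t)a * p + b] += wr * x[a] * x[b];
    }
  };

  double loglik = 0.0;
  NumericVector score(p);
  NumericMatrix info(p, p);
  std::vector<double> S1d(p), sumwx(p), S2d(need_info ? (size_t)p * p : 0),
      xbark(p);

  size_t ps = 0, pr = 0, pd = 0;
  while (pd < deaths.size()) {
    const double t = tstop[deaths[pd]];
    while (ps < (size_t)n && tstop[by_stop[ps]] >= t) upd(by_stop[ps++], +1.0);
    while (pr < (size_t)n && tstart[by_start[pr]] >= t) upd(by_start[pr++], -1.0);

    double wd = 0.0, S0d = 0.0, etasum = 0.0;
    std::fill(S1d.begin(), S1d.end(), 0.0);
    std::fill(sumwx.begin(), sumwx.end(), 0.0);
    std::fill(S2d.begin(), S2d.end(), 0.0);
    int d = 0;
    while (pd < deaths.size() && tstop[deaths[pd]] == t) {
      const int i = deaths[pd++];
      const double* x = &xt[(size_t)i * p];
      const double wr = w[i] * r[i];
      ++d;
      wd += w[i];
      etasum += w[i] * (eta[i] - ebar);
      S0d += wr;
      for (int a = 0; a < p; ++a) {
        sumwx[a] += w[i] * x[a];
        S1d[a] += wr * x[a];
        if (need_info)
          for (int b = 0; b <= a; ++b)
            S2d[(size_t)a * p + b] += wr * x[a] * x[b];
      }
    }
    loglik += etasum;
    for (int a = 0; a < p; ++a) score[a] += sumwx[a];

    const int ksteps = efron ? d : 1;
    const double wk = wd / ksteps;
    for (int k = 0; k < ksteps; ++k) {
      const double f = efron ? (double)k / d : 0.0;
      const double S0k = S0 - f * S0d;
      loglik -= wk * std::log(S0k);
      for (int a = 0; a < p; ++a) {
        xbark[a] = (S1[a] - f * S1d[a]) / S0k;
        score[a] -= wk * xbark[a];
      }
      if (need_info)
        for (int a = 0; a < p; ++a)
          for (int b = 0; b <= a; ++b) {
            const double S2k = S2[(size_t)a * p + b] - f * S2d[(size_t)a * p + b];
            info(a, b) += wk * (S2k / S0k - xbark[a] * xbark[b]);
          }
    }
  }
  if (need_info)
    for (int a = 0; a < p; ++a)
      for (int b = a + 1; b < p; ++b) info(a, b) = info(b, a);

  return List::create(_["loglik"] = loglik, _["score"] = score,
                      _["info"] = info);
}

// Per-row score residuals at beta; rows sum to the score vector (exactly,
// including under Efron ties with unequal weights).  Used for the
// patient-clustered sandwich variance.
// [[Rcpp::export]]
NumericMatrix cox_score_resid_cpp(NumericVector tstart, NumericVector tstop,
                                  IntegerVector event, NumericMatrix X,
                                  NumericVector w, NumericVector beta,
                                  bool efron) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xt((size_t)n * p);
  for (int a = 0; a < p; ++a)
    for (int i = 0; i < n; ++i) xt[(size_t)i * p + a] = X(i, a);

  std::vector<double> eta(n), r(n);
  double wsum = 0.0, ebar = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    const double* x = &xt[(size_t)i * p];
    for (int a = 0; a < p; ++a) e += x[a] * beta[a];
    eta[i] = e;
    wsum += w[i];
    ebar += w[i] * e;
  }
  ebar = (wsum > 0.0) ? ebar / wsum : 0.0;
  for (int i = 0; i < n; ++i) r[i] = std::exp(eta[i] - ebar);

  std::vector<int> by_stop(n), by_start(n);
  for (int i = 0; i < n; ++i) by_stop[i] = by_start[i] = i;
  std::sort(by_stop.begin(), by_stop.end(),
            [&](int a, int b) { return tstop[a] > tstop[b]; });
  std::sort(by_start.begin(), by_start.end(),
            [&](int a, int b) { return tstart[a] > tstart[b]; });
  std::vector<int> deaths;
  for (int i : by_stop)
    if (event[i]) deaths.push_back(i);

  double S0 = 0.0;
  std::vector<double> S1(p, 0.0);
  auto upd = [&](int i, double sign) {
    const double wr = sign * w[i] * r[i];
    const double* x = &xt[(size_t)i * p];
    S0 += wr;
    for (int a = 0; a < p; ++a) S1[a] += wr * x[a];
  };

  // per unique death time (descending during sweep): hazard increments and
  // k-averaged means needed to reconstruct residuals afterwards
  std::vector<double> ut;              // unique death times (desc for now)
  std::vector<double> dlam, dlam_frac; // sum_k dLam_k, sum_k (k/d) dLam_k
  std::vector<double> xdlam, xdlam_frac, xbar_avg;  // p-vectors, flattened

  size_t ps = 0, pr = 0, pd = 0;
  while (pd < deaths.size()) {
    const double t = tstop[deaths[pd]];
    while (ps < (size_t)n && tstop[by_stop[ps]] >= t) upd(by_stop[ps++], +1.0);
    while (pr < (size_t)n && tstart[by_start[pr]] >= t) upd(by_start[pr++], -1.0);

    double wd = 0.0, S0d = 0.0;
    std::vector<double> S1d(p, 0.0);
    int d = 0;
    while (pd < deaths.size() && tstop[deaths[pd]] == t) {
      const int i = deaths[pd++];
      const double wr = w[i] * r[i];
      ++d;
      wd += w[i];
      S0d += wr;
      for (int a = 0; a < p; ++a) S1d[a] += wr * xt[(size_t)i * p + a];
    }

    const int ksteps = efron ? d : 1;
    const double wk = wd / ksteps;
    double dl = 0.0, dlf = 0.0;
    std::vector<double> xd(p, 0.0), xdf(p, 0.0), xb(p, 0.0);
    for (int k = 0; k < ksteps; ++k) {
      const double f = efron ? (double)k / d : 0.0;
      const double S0k = S0 - f * S0d;
      const double h = wk / S0k;
      dl += h;
      dlf += f * h;
      for (int a = 0; a < p; ++a) {
        const double xbk = (S1[a] - f * S1d[a]) / S0k;
        xd[a] += xbk * h;
        xdf[a] += f * xbk * h;
        xb[a] += xbk / ksteps;
      }
    }
    ut.push_back(t);
    dlam.push_back(dl);
    dlam_frac.push_back(dlf);
    for (int a = 0; a < p; ++a) {
      xdlam.push_back(xd[a]);
      xdlam_frac.push_back(xdf[a]);
      xbar_avg.push_back(xb[a]);
    }
  }

  // reverse to ascending time, build cumulative sums
  const int m = (int)ut.size();
  std::vector<double> at(m), cl(m + 1, 0.0), cx((size_t)(m + 1) * p, 0.0);
  for (int j = 0; j < m; ++j) at[j] = ut[m - 1 - j];
  for (int j = 0; j < m; ++j) {
    const int src = m - 1 - j;
    cl[j + 1] = cl[j] + dlam[src];
    for (int a = 0; a < p; ++a)
      cx[(size_t)(j + 1) * p + a] = cx[(size_t)j * p + a] + xdlam[(size_t)src * p + a];
  }

  NumericMatrix resid(n, p);
  for (int i = 0; i < n; ++i) {
    const double* x = &xt[(size_t)i * p];
    // death times in (tstart_i, tstop_i]
    const int lo = (int)(std::upper_bound(at.begin(), at.end(), tstart[i]) -
                         at.begin());
    const int hi = (int)(std::upper_bound(at.begin(), at.end(), tstop[i]) -
                         at.begin());
    const double wr = w[i] * r[i];
    const double dL = cl[hi] - cl[lo];
    for (int a = 0; a < p; ++a)
      resid(i, a) = -wr * (x[a] * dL -
                           (cx[(size_t)hi * p + a] - cx[(size_t)lo * p + a]));
    if (event[i]) {
      // locate own death time (ascending index hi-1 must match tstop_i)
      const int j = hi - 1;
      const int src = m - 1 - j;
      for (int a = 0; a < p; ++a) {
        resid(i, a) += w[i] * (x[a] - xbar_avg[(size_t)src * p + a]);
        // undo the (k/d) fraction of the own-time risk contribution
        resid(i, a) += wr * (x[a] * dlam_frac[src] -
                             xdlam_frac[(size_t)src * p + a]);
      }
    }
  }
  return resid;
}
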