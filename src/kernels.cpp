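#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sample-entropy template-match counts (Chebyshev distance, self-matches
// excluded). Returns c(B, A): B = pairs of m-length templates within r,
// A = pairs of (m+1)-length templates within r, both over the n-m leading
// template positions so that every counted m-template has an extension.
static void sampen_counts_core(const double *p, int n, int m, double r,
                               double &B, double &A) {
  B = 0.0; A = 0.0;
  if (n <= m + 1 || r < 0) return;
  const int lim = n - m;
  // Enumerate only the pairs already matching on the first coordinate by
  // sweeping a sorted order of template heads: O(n log n + matches * m).
  // Lagged coordinates are re-ordered into contiguous arrays so the sweep
  // stays cache-friendly.
  std::vector<int> ord(lim);
  for (int i = 0; i < lim; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [p](int a, int b) { return p[a] < p[b]; });
  std::vector<double> v0(lim);
  std::vector<double> lag((size_t)lim * m);
  for (int a = 0; a < lim; ++a) {
    v0[a] = p[ord[a]];
    for (int k = 1; k <= m; ++k) lag[(size_t)(k - 1) * lim + a] = p[ord[a] + k];
  }
  if (m == 2) {
    // branchless inner loop over the fixed-length run of first-coordinate
    // matches (run end located by bisection on the sorted heads)
    const double *y1 = &lag[0], *y2 = &lag[lim];
    long Bi = 0, Ai = 0;
    for (int a = 0; a < lim; ++a) {
      const double va = v0[a];
      const int hi = (int)(std::upper_bound(v0.begin() + a + 1, v0.end(),
                                            va + r) - v0.begin());
      const double a1 = y1[a], a2 = y2[a];
      for (int b = a + 1; b < hi; ++b) {
        const int ok1 = std::fabs(a1 - y1[b]) <= r;
        const int ok2 = std::fabs(a2 - y2[b]) <= r;
        Bi += ok1;
        Ai += ok1 & ok2;
      }
    }
    B = (double)Bi; A = (double)Ai;
    return;
  }
  for (int a = 0; a < lim; ++a) {
    const double va = v0[a];
    for (int b = a + 1; b < lim && v0[b] - va <= r; ++b) {
      bool ok = true;
      for (int k = 0; k < m - 1; ++k) {
        const double *lk = &lag[(size_t)k * lim];
        if (std::fabs(lk[a] - lk[b]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      const double *lm = &lag[(size_t)(m - 1) * lim];
      if (std::fabs(lm[a] - lm[b]) <= r) A += 1.0;
    }
  }
}

// Sample-entropy template-match counts (Chebyshev distance, self-matches
// excluded). Returns c(B, A): B = pairs of m-length templates within r,
// A = pairs of (m+1)-length templates within r, both over the n-m leading
// template positions so that every counted m-template has an extension.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  double B, A;
  sampen_counts_core(REAL(x), x.size(), m, r, B, A);
  return NumericVector::create(B, A);
}

// Ordinal-pattern counts for permutation entropy. Patterns are Lehmer-coded
// ranks of (x[i], x[i+delay], ..., x[i+(order-1)delay]); ties broken by
// first occurrence (stable: equal values keep temporal order).
// [[Rcpp::export]]
NumericVector perm_pattern_counts_cpp(NumericVector x, int order, int delay) {
  const int n = x.size();
  int npat = 1;
  for (int i = 2; i <= order; ++i) npat *= i;
  NumericVector counts(npat);
  const int span = (order - 1) * delay;
  if (n <= span) return counts;
  std::vector<int> fact(order, 1);
  for (int i = order - 2; i >= 0; --i) fact[i] = fact[i + 1] * (order - 1 - i);
  // fact[k] = (order-1-k)!
  for (int i = 0; i + span < n; ++i) {
    int code = 0;
    for (int k = 0; k < order - 1; ++k) {
      double xk = x[i + k * delay];
      int smaller = 0;
      for (int l = k + 1; l < order; ++l) {
        if (x[i + l * delay] < xk) ++smaller;  // strict: ties keep order
      }
      code += smaller * fact[k];
    }
    counts[code] += 1.0;
  }
  return counts;
}

static const double DB4_LO[8] = {  // decomposition low-pass (db4)
  -0.010597401785069032,  0.0328830116668852,
   0.030841381835560764, -0.18703481171909309,
  -0.027983769416859854,  0.6308807679298589,
   0.7148465705529157,    0.2303778133088965
};

static void check_dwt_feasible(int n, int levels) {
  int div = 1 << levels;
  if (levels < 1) stop("levels must be >= 1");
  if (n % div != 0 || n < div) {
    int maxlev = 0;
    int m = n;
    while (m % 2 == 0 && m > 1) { ++maxlev; m /= 2; }
    stop("signal length %d does not support %d decomposition levels (max feasible: %d)",
         n, levels, maxlev);
  }
}

// One periodized analysis step; writes cA and cD (each length len/2).
static void dwt_step(const std::vector<double> &a, std::vector<double> &ca,
                     std::vector<double> &cd) {
  double g[8];  // quadrature-mirror high-pass: g[n] = (-1)^n h[7-n]
  for (int n = 0; n < 8; ++n) g[n] = ((n % 2) ? -1.0 : 1.0) * DB4_LO[7 - n];
  const int len = (int)a.size();
  const int half = len / 2;
  ca.resize(half); cd.resize(half);
  for (int k = 0; k < half; ++k) {
    double sa = 0.0, sd = 0.0;
    const int base = 2 * k;
    for (int m2 = 0; m2 < 8; ++m2) {
      int idx = base + m2;
      if (idx >= len) idx -= len;  // circular wrap
      const double v = a[idx];
      sa += DB4_LO[m2] * v;
      sd += g[m2] * v;
    }
    ca[k] = sa;
    cd[k] = sd;
  }
}

// Periodized orthonormal discrete wavelet transform with the db4
// (8-tap Daubechies) filter pair. Returns list(cA_L, cD_L, ..., cD_1).
// Circular extension keeps the transform orthonormal, so subband energies
// sum exactly to the signal energy (Parseval).
// [[Rcpp::export]]
List dwt_db4_per_cpp(NumericVector x, int levels) {
  check_dwt_feasible(x.size(), levels);
  List out(levels + 1);
  std::vector<double> a(x.begin(), x.end()), ca, cd;
  for (int lev = 0; lev < levels; ++lev) {
    dwt_step(a, ca, cd);
    out[levels - lev] = NumericVector(cd.begin(), cd.end());
    a.swap(ca);
  }
  out[0] = NumericVector(a.begin(), a.end());
  return out;
}

// --- minimal deterministic RNG for the embedding layout (splitmix64) ---
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double clip4(double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

// Stochastic-gradient layout of a fuzzy neighbor graph in 2-D
// (UMAP-style cross-entropy with negative sampling). `from`/`to` are 0-based
// edge endpoints of the symmetrized graph; epochs_per_sample controls how
// often each edge fires. Deterministic given `seed`.
// [[Rcpp::export]]
NumericMatrix embed_sgd_cpp(NumericMatrix init, IntegerVector from, IntegerVector to,
                            NumericVector epochs_per_sample, double a, double b,
                            int n_epochs, double initial_alpha, int neg_rate,
                            double seed) {
  int n = init.nrow();
  int ne = from.size();
  NumericMatrix emb = clone(init);
  std::vector<double> eons(ne), eos(ne), eonns(ne);
  for (int e = 0; e < ne; ++e) {
    eos[e] = epochs_per_sample[e];
    eons[e] = epochs_per_sample[e];
    eonns[e] = epochs_per_sample[e] / neg_rate;
  }
  std::vector<double> next_sample(eons), next_neg(eonns);
  uint64_t rng = (uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0x853C49E6748FEA9BULL;
  double *E = REAL(emb);
  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    double alpha = initial_alpha * (1.0 - (double)(epoch - 1) / n_epochs);
    for (int e = 0; e < ne; ++e) {
      if (next_sample[e] > epoch) continue;
      int i = from[e], j = to[e];
      double *pi = E + i, *pj = E + j;
      double dx = pi[0] - pj[0], dy = pi[n] - pj[n];
      double d2 = dx * dx + dy * dy;
      if (d2 > 0.0) {
        double pd = a * std::pow(d2, b);
        double gc = (-2.0 * a * b * std::pow(d2, b - 1.0)) / (1.0 + pd);
        double gx = clip4(gc * dx) * alpha, gy = clip4(gc * dy) * alpha;
        pi[0] += gx; pi[n] += gy;
        pj[0] -= gx; pj[n] -= gy;
      }
      next_sample[e] += eos[e];
      int n_neg = (int)((epoch - next_neg[e]) / eonns[e]);
      for (int t = 0; t < n_neg; ++t) {
        int k = (int)(splitmix64(rng) % (uint64_t)n);
        if (k == i) continue;
        double *pk = E + k;
        double rx = pi[0] - pk[0], ry = pi[n] - pk[n];
        double r2 = rx * rx + ry * ry;
        double gc;
        if (r2 > 0.0) {
          gc = (2.0 * b) / ((0.001 + r2) * (1.0 + a * std::pow(r2, b)));
        } else {
          continue;
        }
        pi[0] += clip4(gc * rx) * alpha;
        pi[n] += clip4(gc * ry) * alpha;
      }
      next_neg[e] += n_neg * eonns[e];
    }
  }
  return emb;
}

// --- batched per-segment feature kernel -------------------------------------
// Computes, for each column (channel) of `mat`, the non-spectral features:
// 8 time stats, 3 Hjorth parameters, sample/permutation/histogram entropies,
// and 8 stats for each of the (levels + 1) wavelet coefficient sets.
// Must agree exactly with the single-channel R operations; the test suite
// cross-checks the two paths.

static void moment_stats(const double *v, int n, double out[4]) {
  // mean and population central moments m2, m3, m4
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += v[i];
  mu /= n;
  double m2 = 0, m3 = 0, m4 = 0;
  for (int i = 0; i < n; ++i) {
    const double d = v[i] - mu, d2 = d * d;
    m2 += d2; m3 += d2 * d; m4 += d2 * d2;
  }
  out[0] = mu; out[1] = m2 / n; out[2] = m3 / n; out[3] = m4 / n;
}

// [[Rcpp::export]]
NumericMatrix segment_features_cpp(NumericMatrix mat, int sampen_m,
                                   double sampen_r_factor, int perm_order,
                                   int perm_delay, int hist_bins, int levels) {
  const int n = mat.nrow(), nch = mat.ncol();
  const int nw = levels + 1;
  const int nfeat = 8 + 3 + 3 + 8 * nw;
  check_dwt_feasible(n, levels);
  NumericMatrix out(nfeat, nch);
  double lgfact = 0.0;
  for (int i = 2; i <= perm_order; ++i) lgfact += std::log((double)i);
  for (int ch = 0; ch < nch; ++ch) {
    const double *x = &mat(0, ch);
    double *f = &out(0, ch);
    double m[4];
    moment_stats(x, n, m);
    const double mu = m[0], v0 = m[1];
    f[0] = mu;
    f[1] = v0;
    f[2] = (v0 == 0) ? 0.0 : m[2] / std::pow(v0, 1.5);
    f[3] = (v0 == 0) ? 0.0 : m[3] / (v0 * v0) - 3.0;
    double ss = 0, mn = x[0], mx = x[0], ll = 0;
    int zc = 0;
    for (int i = 0; i < n; ++i) {
      ss += x[i] * x[i];
      if (x[i] < mn) mn = x[i];
      if (x[i] > mx) mx = x[i];
      if (i > 0) {
        ll += std::fabs(x[i] - x[i - 1]);
        const double s1 = (x[i] > 0) - (x[i] < 0);
        const double s0 = (x[i - 1] > 0) - (x[i - 1] < 0);
        if (s1 != s0) ++zc;
      }
    }
    f[4] = std::sqrt(ss / n);
    f[5] = mx - mn;
    f[6] = (double)zc / (n - 1);
    f[7] = ll / (n - 1);
    // Hjorth parameters from the variances of the first two differences
    if (v0 == 0) {
      f[8] = f[9] = f[10] = 0.0;
    } else {
      double s1 = 0, s1sq = 0, s2 = 0, s2sq = 0;
      for (int i = 1; i < n; ++i) {
        const double d = x[i] - x[i - 1];
        s1 += d; s1sq += d * d;
      }
      for (int i = 2; i < n; ++i) {
        const double d = x[i] - 2 * x[i - 1] + x[i - 2];
        s2 += d; s2sq += d * d;
      }
      const double mu1 = s1 / (n - 1), mu2 = s2 / (n - 2);
      const double v1 = s1sq / (n - 1) - mu1 * mu1;
      const double v2 = s2sq / (n - 2) - mu2 * mu2;
      const double mob = std::sqrt(v1 / v0);
      f[8] = v0;
      f[9] = mob;
      f[10] = (v1 == 0) ? 0.0 : std::sqrt(v2 / v1) / mob;
    }
    {
      double B, A;
      sampen_counts_core(x, n, sampen_m, sampen_r_factor * std::sqrt(v0), B, A);
      f[11] = (A == 0 || B == 0) ? 0.0 : -std::log(A / B);
    }
    {
      NumericVector counts = perm_pattern_counts_cpp(
        NumericVector(x, x + n), perm_order, perm_delay);
      double tot = 0, h = 0;
      for (double c : counts) tot += c;
      for (double c : counts) if (c > 0) { const double p = c / tot; h -= p * std::log(p); }
      f[12] = h / lgfact;
    }
    if (mx == mn) {
      f[13] = 0.0;
    } else {
      std::vector<int> cnt(hist_bins, 0);
      for (int i = 0; i < n; ++i) {
        int b = (int)std::floor((x[i] - mn) / (mx - mn) * hist_bins);
        if (b < 0) b = 0;
        if (b >= hist_bins) b = hist_bins - 1;
        ++cnt[b];
      }
      double h = 0;
      for (int c : cnt) if (c > 0) { const double p = (double)c / n; h -= p * std::log(p); }
      f[13] = h / std::log((double)hist_bins);
    }
    {
      std::vector<double> a(x, x + n), ca, cd;
      std::vector< std::vector<double> > sets(nw);
      for (int lev = 0; lev < levels; ++lev) {
        dwt_step(a, ca, cd);
        sets[levels - lev] = cd;
        a.swap(ca);
      }
      sets[0] = a;
      double total_e = 0.0;
      std::vector<double> energies(nw);
      for (int s = 0; s < nw; ++s) {
        double e = 0;
        for (double c : sets[s]) e += c * c;
        energies[s] = e;
        total_e += e;
      }
      for (int s = 0; s < nw; ++s) {
        const std::vector<double> &cc = sets[s];
        const int nc = (int)cc.size();
        double wm[4];
        moment_stats(cc.data(), nc, wm);
        double ma = 0, mxa = 0;
        for (double c : cc) {
          const double ac = std::fabs(c);
          ma += ac;
          if (ac > mxa) mxa = ac;
        }
        double *g = f + 14 + 8 * s;
        g[0] = wm[0];
        g[1] = std::sqrt(wm[1]);
        g[2] = ma / nc;
        g[3] = energies[s];
        g[4] = (total_e == 0) ? 0.0 : energies[s] / total_e;
        g[5] = mxa;
        g[6] = (wm[1] == 0) ? 0.0 : wm[2] / std::pow(wm[1], 1.5);
        g[7] = (wm[1] == 0) ? 0.0 : wm[3] / (wm[1] * wm[1]) - 3.0;
      }
    }
  }
  return out;
}
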