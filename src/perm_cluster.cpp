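#include <Rcpp.h>
using namespace Rcpp;

// Null distribution of the maximum temporal cluster mass for a
// within-subject F map under condition-label permutation.
//
// The effect projection A (symmetric idempotent, rank df1) is supplied as
// an orthonormal contrast matrix Cm (df1 x n_c) with A = Cm' Cm, so only
// df1 projections per (sample, subject) are computed: ||A y||^2 = ||Cm y||^2.
//
// Y:     (n_c x n_t x n_s) data array (condition x sample x subject)
// Cm:    (df1 x n_c) orthonormal rows spanning the effect subspace
// perms: (n_c x n_perm*n_s) 0-based row permutations, subject fastest
// thr:   cluster-forming F threshold
// [[Rcpp::export]]
NumericVector perm_null_max_mass(NumericVector Y, NumericMatrix Cm,
                                 IntegerMatrix perms, int n_perm,
                                 double thr, double df1, double df2) {
  IntegerVector dims = Y.attr("dim");
  const int n_c = dims[0], n_t = dims[1], n_s = dims[2];
  const int q = Cm.nrow();
  NumericVector out(n_perm);
  std::vector<double> cv((size_t)q * n_c), yp(n_c), v(q), f(n_t),
      ss_all(n_t), mbuf((size_t)q * n_t);
  for (int k = 0; k < n_c; ++k)
    for (int j = 0; j < q; ++j) cv[j + (size_t)q * k] = Cm(j, k);
  const double *y = Y.begin();
  const int *pm = perms.begin();
  double *m = mbuf.data();
  for (int b = 0; b < n_perm; ++b) {
    std::fill(mbuf.begin(), mbuf.end(), 0.0);
    std::fill(ss_all.begin(), ss_all.end(), 0.0);
    for (int s = 0; s < n_s; ++s) {
      const int *p = pm + (size_t)n_c * ((size_t)b * n_s + s);
      const double *ys = y + (size_t)s * n_c * n_t;
      for (int t = 0; t < n_t; ++t) {
        const double *yt = ys + (size_t)t * n_c;
        for (int k = 0; k < n_c; ++k) yp[k] = yt[p[k]];
        const double *cm = cv.data();
        double sa = 0.0;
        for (int j = 0; j < q; ++j) v[j] = 0.0;
        for (int k = 0; k < n_c; ++k) {
          const double w = yp[k];
          for (int j = 0; j < q; ++j) v[j] += cm[j + (size_t)q * k] * w;
        }
        double *mt = m + (size_t)t * q;
        for (int j = 0; j < q; ++j) {
          mt[j] += v[j];
          sa += v[j] * v[j];
        }
        ss_all[t] += sa;
      }
    }
    for (int t = 0; t < n_t; ++t) {
      const double *mt = m + (size_t)t * q;
      double se = 0.0;
      for (int j = 0; j < q; ++j) se += mt[j] * mt[j];
      se /= n_s;
      double err = ss_all[t] - se;
      if (err < 0) err = 0;
      f[t] = se == 0 ? 0.0 : (se / df1) / (err / df2);
    }
    double best = 0.0, cur = 0.0;
    for (int t = 0; t < n_t; ++t) {
      if (f[t] > thr) {
        cur += f[t];
        if (cur > best) best = cur;
      } else {
        cur = 0.0;
      }
    }
    out[b] = best;
  }
  return out;
}
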