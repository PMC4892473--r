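// Permutation engine for the supervised-PC set test (no-covariate path).
//
// For every label column the full adaptive procedure is repeated: screen
// CpGs by univariate logistic score statistic, extract PC1 of each
// candidate top-m subset, pick the candidate whose PC1 has the largest
// score statistic, and return the Wald ratio of the PC1 slope in a
// logistic fit. PC1 score vectors are label-free, so they are cached
// across permutations under a subset bitmask (p <= 64; larger sets skip
// the cache).

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Pc1Entry {
  vec s;      // PC1 sample scores (centered scale)
  double ss;  // sum of squares
};

// Newton-Raphson logistic fit of y on (1, s); returns the Wald ratio of
// the slope. Mirrors the R reference implementation (fast_logistic_slope).
double wald_slope(const vec& s, const vec& y) {
  const double ybar = mean(y);
  double b0 = std::log(ybar / (1.0 - ybar)), b1 = 0.0;
  double sw = 0, sws = 0, swss = 0, det = 0;
  for (int it = 0; it < 30; ++it) {
    vec mu = 1.0 / (1.0 + exp(-(b0 + b1 * s)));
    vec w = mu % (1.0 - mu);
    sw = accu(w);
    sws = dot(w, s);
    swss = dot(w, s % s);
    det = sw * swss - sws * sws;
    if (det <= 0) break;
    const vec r = y - mu;
    const double u0 = accu(r), u1 = dot(r, s);
    const double d0 = (swss * u0 - sws * u1) / det;
    const double d1 = (sw * u1 - sws * u0) / det;
    b0 += d0; b1 += d1;
    if (std::abs(d0) + std::abs(d1) <
        1e-8 * (1.0 + std::abs(b0) + std::abs(b1))) break;
  }
  vec mu = 1.0 / (1.0 + exp(-(b0 + b1 * s)));
  vec w = mu % (1.0 - mu);
  sw = accu(w); sws = dot(w, s); swss = dot(w, s % s);
  det = sw * swss - sws * sws;
  if (det <= 0) return 0.0;
  return b1 / std::sqrt(sw / det);
}

}  // namespace

// Gc: centered methylation columns (n x p); Gn: columns scaled to unit
// sum-of-squares; CGG = Gc'Gc; sizes: candidate screening sizes; Y: one
// 0/1 label vector per column (first = observed, rest = permutations).
// [[Rcpp::export]]
Rcpp::NumericVector spca_perm_stats_cpp(const arma::mat& Gc,
                                        const arma::mat& Gn,
                                        const arma::mat& CGG,
                                        const arma::uvec& sizes,
                                        const arma::mat& Y) {
  const uword p = Gc.n_cols, ncol = Y.n_cols;
  const bool use_cache = p <= 64;
  std::unordered_map<unsigned long long, Pc1Entry> cache;
  Rcpp::NumericVector out(ncol);

  for (uword j = 0; j < ncol; ++j) {
    const vec y = Y.col(j);
    const vec u = abs(Gn.t() * y);
    const uvec ord = sort_index(u, "descend");

    double best_val = -1.0;
    vec best_s;   // copy: uncached entries are scratch-local
    Pc1Entry scratch;

    for (uword k = 0; k < sizes.n_elem; ++k) {
      const uvec sel = ord.head(sizes(k));
      const Pc1Entry* ent = nullptr;
      unsigned long long key = 0;
      if (use_cache) {
        for (uword i = 0; i < sel.n_elem; ++i) key |= 1ULL << sel(i);
        auto hit = cache.find(key);
        if (hit != cache.end()) ent = &hit->second;
      }
      if (!ent) {
        Pc1Entry e;
        if (sel.n_elem == 1) {
          e.s = Gc.col(sel(0));
        } else {
          vec eigval;
          mat eigvec;
          eig_sym(eigval, eigvec, CGG.submat(sel, sel));
          e.s = Gc.cols(sel) * eigvec.col(eigvec.n_cols - 1);
        }
        e.ss = dot(e.s, e.s);
        if (use_cache) {
          ent = &(cache[key] = std::move(e));
        } else {
          scratch = std::move(e);
          ent = &scratch;
        }
      }
      const double d = dot(ent->s, y);
      const double val = d * d / ent->ss;   // score statistic up to a
                                            // label-invariant factor
      if (val > best_val) {
        best_val = val;
        best_s = ent->s;
      }
    }
    out[j] = wald_slope(best_s, y);
  }
  return out;
}
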