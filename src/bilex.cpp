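#include <Rcpp.h>
using namespace Rcpp;

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

// Best-matching unit: argmin over nodes (rows of W) of Euclidean distance
// to x.  Strict '<' keeps the lowest row-major index on ties.
// [[Rcpp::export]]
int cpp_bmu(const NumericMatrix& W, const NumericVector& x) {
  const int n = W.nrow(), d = W.ncol();
  std::vector<double> acc(n, 0.0);
  for (int j = 0; j < d; ++j) {
    const double xj = x[j];
    const double* col = &W(0, j);
    for (int i = 0; i < n; ++i) {
      const double diff = col[i] - xj;
      acc[i] += diff * diff;
    }
  }
  int best = 0;
  double bestv = acc[0];
  for (int i = 1; i < n; ++i)
    if (acc[i] < bestv) { bestv = acc[i]; best = i; }
  return best;
}

// BMU index (0-based) and input-space distance for every row of X.
// [[Rcpp::export]]
List cpp_bmus(const NumericMatrix& W, const NumericMatrix& X) {
  const int n = W.nrow(), d = W.ncol(), m = X.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  std::vector<double> acc(n);
  for (int r = 0; r < m; ++r) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < d; ++j) {
      const double xj = X(r, j);
      const double* col = &W(0, j);
      for (int i = 0; i < n; ++i) {
        const double diff = col[i] - xj;
        acc[i] += diff * diff;
      }
    }
    int best = 0;
    double bestv = acc[0];
    for (int i = 1; i < n; ++i)
      if (acc[i] < bestv) { bestv = acc[i]; best = i; }
    idx[r] = best;
    dist[r] = std::sqrt(bestv);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// In-place Gaussian-kernel update of the listed nodes (0-based) toward x:
// w <- w + lr * g * (x - w).  The caller owns W exclusively.
// [[Rcpp::export]]
void cpp_som_update(NumericMatrix W, const NumericVector& x,
                    const IntegerVector& nodes, const NumericVector& g,
                    double lr) {
  const int k = nodes.size(), d = W.ncol();
  for (int j = 0; j < d; ++j) {
    const double xj = x[j];
    double* col = &W(0, j);
    for (int t = 0; t < k; ++t) {
      const int i = nodes[t];
      col[i] += lr * g[t] * (xj - col[i]);
    }
  }
}

// As cpp_som_update, but also refreshes w2 (per-node squared weight norm),
// used by the trainer's incremental BMU search.
// [[Rcpp::export]]
void cpp_som_update_tracked(NumericMatrix W, NumericVector w2,
                            const NumericVector& x, const IntegerVector& nodes,
                            const NumericVector& g, double lr) {
  const int k = nodes.size(), d = W.ncol();
  std::vector<double> acc(k, 0.0);
  for (int j = 0; j < d; ++j) {
    const double xj = x[j];
    double* col = &W(0, j);
    for (int t = 0; t < k; ++t) {
      const int i = nodes[t];
      const double v = col[i] + lr * g[t] * (xj - col[i]);
      col[i] = v;
      acc[t] += v * v;
    }
  }
  for (int t = 0; t < k; ++t) w2[nodes[t]] = acc[t];
}

// Hebbian accumulation with lazily-scaled rows.  Effective weight is
// W(i,j) * scale(i); the increment c * as * at is divided by the row scale
// at write time.  rowmax tracks the row's maximum effective weight; when it
// exceeds 1 the row scale is divided by it (multiplicative normalisation of
// the outgoing weight vector) in O(1), which commutes exactly with later
// additions.  src/tgt are 0-based node indices.
// [[Rcpp::export]]
void cpp_hebb(NumericMatrix W, NumericVector scale, NumericVector rowmax,
              const IntegerVector& src, const NumericVector& as,
              const IntegerVector& tgt, const NumericVector& at, double c) {
  const int ns = src.size(), nt = tgt.size();
  std::vector<double> inc(ns), sc(ns), rm(ns, 0.0);
  const int* RESTRICT si = &src[0];
  for (int s = 0; s < ns; ++s) {
    sc[s] = scale[si[s]];
    inc[s] = c * as[s] / sc[s];
  }
  for (int t = 0; t < nt; ++t) {
    const double a = at[t];
    double* RESTRICT col = &W(0, tgt[t]);
    for (int s = 0; s < ns; ++s) {
      const double v = col[si[s]] + a * inc[s];
      col[si[s]] = v;
      const double eff = v * sc[s];
      if (eff > rm[s]) rm[s] = eff;
    }
  }
  for (int s = 0; s < ns; ++s) {
    const int i = si[s];
    if (rm[s] > rowmax[i]) rowmax[i] = rm[s];
    if (rowmax[i] > 1.0) {
      scale[i] /= rowmax[i];
      rowmax[i] = 1.0;
    }
  }
}

// Materialise the effective weights of a lazily-scaled matrix: row i of W
// times scale(i).
// [[Rcpp::export]]
NumericMatrix cpp_effective(const NumericMatrix& W, const NumericVector& scale) {
  const int n = W.nrow(), m = W.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      out(i, j) = W(i, j) * scale[i];
  return out;
}
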