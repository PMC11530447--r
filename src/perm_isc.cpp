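#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Participant ISC of a (possibly circularly shifted) target against a fixed
// partner set: for each partner, the mean windowed Pearson r over all
// defined windows; the participant value is the median over partners.
// Windows where either side has (near-)zero variance are excluded, matching
// the R path in windowed_pairwise_isc().

namespace {

struct PartnerStats {
  std::vector<double> sy, syy;  // per-window sums, length nw
};

inline double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// mean-r of shifted target xs vs one partner (demeaned columns of Y)
double pair_mean_r(const std::vector<double>& xs,
                   const std::vector<double>& sxw,
                   const std::vector<double>& sxxw,
                   const double* y, const PartnerStats& ps,
                   int n, int w, double eps) {
  const int nw = n - w + 1;
  // prefix sums of the cross product
  std::vector<double> cz(n + 1, 0.0);
  for (int t = 0; t < n; ++t) cz[t + 1] = cz[t] + xs[t] * y[t];
  double acc = 0.0;
  int cnt = 0;
  for (int t = 0; t < nw; ++t) {
    double vx = sxxw[t] - sxw[t] * sxw[t] / w;
    double vy = ps.syy[t] - ps.sy[t] * ps.sy[t] / w;
    if (vx <= eps || vy <= eps) continue;
    double sxy = cz[t + w] - cz[t];
    double r = (sxy - sxw[t] * ps.sy[t] / w) / std::sqrt(vx * vy);
    if (r > 1.0) r = 1.0;
    if (r < -1.0) r = -1.0;
    acc += r;
    ++cnt;
  }
  return cnt ? acc / cnt : NA_REAL;
}

void window_stats(const std::vector<double>& x, int n, int w,
                  std::vector<double>& sw, std::vector<double>& sww) {
  std::vector<double> c1(n + 1, 0.0), c2(n + 1, 0.0);
  for (int t = 0; t < n; ++t) {
    c1[t + 1] = c1[t] + x[t];
    c2[t + 1] = c2[t] + x[t] * x[t];
  }
  const int nw = n - w + 1;
  sw.resize(nw);
  sww.resize(nw);
  for (int t = 0; t < nw; ++t) {
    sw[t] = c1[t + w] - c1[t];
    sww[t] = c2[t + w] - c2[t];
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector perm_isc_null_cpp(NumericVector x, NumericMatrix Y,
                                IntegerVector offsets, int window) {
  const int n = x.size();
  const int p = Y.ncol();
  if (Y.nrow() != n) stop("target and partners must share length");
  if (window < 2 || window > n) stop("invalid window");
  const double eps = 1e-12 * window;

  // demean target and partner columns once
  std::vector<double> x0(n);
  double mx = 0.0;
  for (int t = 0; t < n; ++t) mx += x[t];
  mx /= n;
  for (int t = 0; t < n; ++t) x0[t] = x[t] - mx;

  std::vector<std::vector<double> > Yc(p, std::vector<double>(n));
  std::vector<PartnerStats> ps(p);
  for (int j = 0; j < p; ++j) {
    double my = 0.0;
    for (int t = 0; t < n; ++t) my += Y(t, j);
    my /= n;
    for (int t = 0; t < n; ++t) Yc[j][t] = Y(t, j) - my;
    window_stats(Yc[j], n, window, ps[j].sy, ps[j].syy);
  }

  NumericVector out(offsets.size());
  std::vector<double> xs(n), sxw, sxxw, vals;
  for (int it = 0; it < offsets.size(); ++it) {
    int off = offsets[it] % n;
    if (off < 0) off += n;
    // xs[t] = x0[(t - off) mod n]  (forward rotation by off)
    for (int t = 0; t < n; ++t) xs[t] = x0[(t - off % n + n) % n];
    window_stats(xs, n, window, sxw, sxxw);
    vals.clear();
    for (int j = 0; j < p; ++j) {
      double m = pair_mean_r(xs, sxw, sxxw, Yc[j].data(), ps[j], n, window,
                             eps);
      if (!ISNA(m) && !ISNAN(m)) vals.push_back(m);
    }
    out[it] = median_of(vals);
  }
  return out;
}
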