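#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All geometry is done in the (index, value) plane with the candidate treated
// as an infinite line; the vector/cross-product form is used instead of the
// slope/intercept form (identical algebra, stable for steep candidates).

static inline double lg1(double v) {
  // code-length term: log2 clamped below at 1 bit argument, so terms are >= 0
  return v > 1.0 ? std::log2(v) : 0.0;
}

// Greedy character-point scan of one window.
//
// 0-based positions internally, returned 1-based. `limit` > 0 allows an early
// stop once `limit` character points have been found *and* at least one merge
// has occurred among them (output prefix is identical to a full scan because
// the greedy is left-to-right and memoryless between character points).
// `limit` = 0 forces a full scan.
//
// Returns:
//   cp         1-based character-point positions (always starts at 1;
//              includes the last window point when the scan reached the end)
//   evals      number of segment-preference tests performed
//   all_points true when the scan reached the end and every window point is
//              a character point (the "random data, keep everything" case)
// [[Rcpp::export(name = ".greedy_scan_cpp")]]
List greedy_scan_cpp(NumericVector x, NumericVector y,
                     double wp, double wa, int limit) {
  const int n = x.size();
  if (n < 2) stop("window must hold at least 2 points");
  const double *px = REAL(x), *py = REAL(y);

  long evals = 0;
  std::vector<int> cp;
  cp.push_back(0);
  bool all_consec = true;  // cp so far are exactly 0,1,...,len-1

  int start = 0;
  int cur = start + 2;
  double noseg = 0.0;
  bool fresh = true;

  auto line_bits = [&](int k) {
    double dx = px[k + 1] - px[k], dy = py[k + 1] - py[k];
    return lg1(std::sqrt(dx * dx + dy * dy));
  };

  while (cur <= n - 1) {
    if (fresh) {
      noseg = line_bits(start) + line_bits(start + 1);
      fresh = false;
    }
    // MDL_seg(start, cur) with early exit once the cost reaches MDL_noseg
    ++evals;
    const double ax = px[start], ay = py[start];
    const double ex = px[cur] - ax, ey = py[cur] - ay;
    const double L = std::sqrt(ex * ex + ey * ey);
    double cost = lg1(L);
    bool prefer = cost < noseg;
    if (prefer) {
      for (int k = start; k < cur; ++k) {
        double d1 = std::fabs(ex * (py[k] - ay) - ey * (px[k] - ax)) / L;
        double d2 = std::fabs(ex * (py[k + 1] - ay) - ey * (px[k + 1] - ax)) / L;
        double s = d1 + d2;
        double dp = s > 0.0 ? (d1 * d1 + d2 * d2) / s : 0.0;
        double da = std::fabs((px[k + 1] - px[k]) * ey -
                              (py[k + 1] - py[k]) * ex) / L;
        cost += lg1(wp * dp) + lg1(wa * da);
        if (cost >= noseg) { prefer = false; break; }
      }
    }

    if (prefer) {
      ++cur;
      if (cur <= n - 1) noseg += line_bits(cur - 1);
    } else {
      cp.push_back(cur - 1);
      if (cur - 1 != start + 1) all_consec = false;
      start = cur - 1;
      cur = start + 2;
      fresh = true;
      if (limit > 0 && (int)cp.size() >= limit && !all_consec) break;
    }
  }

  bool all_points = false;
  if (cur > n - 1) {                 // scan reached the window end
    if (cp.back() != n - 1) cp.push_back(n - 1);
    all_points = all_consec && (int)cp.size() == n;
  }

  IntegerVector out(cp.size());
  for (size_t i = 0; i < cp.size(); ++i) out[i] = cp[i] + 1;
  return List::create(_["cp"] = out,
                      _["evals"] = (double)evals,
                      _["all_points"] = all_points);
}

// Bounded mean-reverting random walk. Each step moves by
//   delta = sign * (U mod max(1, floor(B))) * sharpness
// where sign is +/- with equal probability, U is a uniform integer and B is
// the distance from the current value to the bound in the direction of
// motion, so fluctuations meet increasing resistance away from the midpoint.
// Uses R's RNG: reproducible under set.seed().
// [[Rcpp::export(name = ".gen_walk_cpp")]]
NumericVector gen_walk_cpp(double n, double lb, double ub, double sharpness) {
  R_xlen_t len = (R_xlen_t)n;
  NumericVector v((R_xlen_t)len);
  double cur = (lb + ub) / 2.0;
  v[0] = cur;
  for (R_xlen_t i = 1; i < len; ++i) {
    double sg = (unif_rand() < 0.5) ? 1.0 : -1.0;
    double B = sg > 0 ? (ub - cur) : (cur - lb);
    double m = std::max(1.0, std::floor(B));
    double step = std::floor(unif_rand() * m);  // uniform integer in 0..m-1
    cur += sg * step * sharpness;
    if (cur < lb) cur = lb; else if (cur > ub) cur = ub;
    v[i] = cur;
  }
  return v;
}
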