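#include "hull.h"
#include <cmath>
#include <cfloat>
#include <algorithm>
#include <R.h>
#include <Rmath.h>

namespace ars {

static const double SLOPE_TOL = 1e-7;   // tolerated non-monotonicity in dh
static const double TINY_SLOPE = 1e-10; // Taylor fallback threshold

// log of int_A^B exp(hh + s*(x - xx)) dx, A < B, one edge may be infinite
static double seg_mass_log(double xx, double hh, double s, double A, double B) {
  if (A == R_NegInf) {
    if (s <= 0.0) return R_PosInf;  // infinite mass: invalid
    return hh + s * (B - xx) - std::log(s);
  }
  if (B == R_PosInf) {
    if (s >= 0.0) return R_PosInf;
    return hh + s * (A - xx) - std::log(-s);
  }
  double d = B - A;
  if (std::fabs(s) < TINY_SLOPE)
    return hh + s * (A - xx) + std::log(d) + std::log1p(s * d / 2.0);
  double sd = s * d;
  if (sd > 700.0)  // evaluate from the B end
    return hh + s * (B - xx) - std::log(s) + std::log1p(-std::exp(-sd));
  double em = std::expm1(sd);  // sign of em matches sign of s
  return hh + s * (A - xx) + std::log(em / s);
}

double Hull::intersect(int j) const {
  double den = dh[j] - dh[j + 1];
  if (den < 1e-14) {
    // numerically parallel tangents: split midway between the points
    return 0.5 * (x[j] + x[j + 1]);
  }
  return (h[j + 1] - h[j] - x[j + 1] * dh[j + 1] + x[j] * dh[j]) / den;
}

double Hull::seg_logJ(int i) const {
  return seg_mass_log(x[i], h[i], dh[i], z[i], z[i + 1]);
}

void Hull::recompute_all() {
  int kk = k();
  z.assign(kk + 1, 0.0);
  z[0] = lo; z[kk] = hi;
  for (int j = 0; j + 1 < kk; ++j) z[j + 1] = intersect(j);
  // clamp against domain (inserts near the edges can push z outside)
  for (int j = 1; j < kk; ++j) z[j] = std::min(std::max(z[j], lo), hi);
  logJ.assign(kk, 0.0);
  for (int i = 0; i < kk; ++i) logJ[i] = seg_logJ(i);
  refresh_cum();
}

void Hull::refresh_cum() {
  int kk = k();
  double mx = R_NegInf;
  for (int i = 0; i < kk; ++i) mx = std::max(mx, logJ[i]);
  if (!R_finite(mx)) throw InitError("hull envelope has non-finite mass");
  cumJ.assign(kk, 0.0);
  double acc = 0.0;
  for (int i = 0; i < kk; ++i) { acc += std::exp(logJ[i] - mx); cumJ[i] = acc; }
  for (int i = 0; i < kk; ++i) cumJ[i] /= acc;
}

double Hull::total_logJ() const {
  double mx = R_NegInf;
  for (size_t i = 0; i < logJ.size(); ++i) mx = std::max(mx, logJ[i]);
  double acc = 0.0;
  for (size_t i = 0; i < logJ.size(); ++i) acc += std::exp(logJ[i] - mx);
  return mx + std::log(acc);
}

void Hull::build(const std::vector<double> &xs, const std::vector<double> &hs,
                 const std::vector<double> &dhs, double lo_, double hi_) {
  if (xs.size() < 2) throw InitError("hull needs at least 2 support points");
  x = xs; h = hs; dh = dhs; lo = lo_; hi = hi_;
  for (size_t i = 1; i < x.size(); ++i) {
    if (!(x[i] > x[i - 1])) throw InitError("support points must be sorted");
    if (dh[i] > dh[i - 1] + SLOPE_TOL * (1.0 + std::fabs(dh[i - 1])))
      throw LogConcavityError();
  }
  if (lo == R_NegInf && dh.front() <= 0.0)
    throw InitError("leftmost slope must be positive on an unbounded domain");
  if (hi == R_PosInf && dh.back() >= 0.0)
    throw InitError("rightmost slope must be negative on an unbounded domain");
  recompute_all();
}

void Hull::init(Target &target, double lo_, double hi_, double start, int k0) {
  lo = lo_; hi = hi_;
  if (k0 < 2) k0 = 2;
  double s = start;
  double hs, ds;
  target.eval(s, hs, ds);
  // find a finite starting point if the density underflows at `start`
  if (!R_finite(hs)) {
    bool found = false;
    for (int m = 0; m < 60 && !found; ++m) {
      double step = 0.25 * std::pow(1.5, m);
      double cand[2] = { start + step, start - step };
      for (int i = 0; i < 2; ++i) {
        double c = cand[i];
        if (c <= lo || c >= hi) continue;
        target.eval(c, hs, ds);
        if (R_finite(hs)) { s = c; found = true; break; }
      }
    }
    if (!found) throw InitError("could not locate region of positive density");
  }

  // expand left until slope > 0 (needed when lo = -Inf), right until < 0
  double xl = s, hl = hs, dl = ds;
  if (lo == R_NegInf) {
    double step = 0.5; int m = 0;
    while (dl <= 0.0) {
      double c = xl - step;
      double hc, dc;
      target.eval(c, hc, dc);
      if (R_finite(hc)) { xl = c; hl = hc; dl = dc; step *= 2.0; }
      else step *= 0.5;  // stepped past the support; approach more slowly
      if (++m > 200) throw InitError("no point with positive slope found left of start");
    }
  } else {
    if (xl - lo < 1e-12) xl = lo + 1e-6 * (hi - lo);
  }
  double xr = s, hr = hs, dr = ds;
  if (hi == R_PosInf) {
    double step = 0.5; int m = 0;
    while (dr >= 0.0) {
      double c = xr + step;
      double hc, dc;
      target.eval(c, hc, dc);
      if (R_finite(hc)) { xr = c; hr = hc; dr = dc; step *= 2.0; }
      else step *= 0.5;
      if (++m > 200) throw InitError("no point with negative slope found right of start");
    }
  } else {
    if (hi - xr < 1e-12) xr = hi - 1e-6 * (hi - lo);
    if (xr <= xl) {
      // start was at the right edge; pull a right point inside the domain
      double c = (R_finite(hi)) ? (xl + 0.75 * (hi - xl)) : xl + 1.0;
      double hc, dc; target.eval(c, hc, dc);
      if (R_finite(hc)) { xr = c; hr = hc; dr = dc; }
    }
  }

  std::vector<double> xs, hs2, ds2;
  xs.push_back(xl); hs2.push_back(hl); ds2.push_back(dl);
  if (k0 >= 3 && xr > xl) {
    double xm = 0.5 * (xl + xr);
    if (xm > xl + 1e-12 && xm < xr - 1e-12) {
      double hm, dm;
      target.eval(xm, hm, dm);
      if (R_finite(hm)) { xs.push_back(xm); hs2.push_back(hm); ds2.push_back(dm); }
    }
  }
  if (xr > xs.back()) { xs.push_back(xr); hs2.push_back(hr); ds2.push_back(dr); }
  if (xs.size() < 2) throw InitError("could not assemble an initial hull");
  // enforce monotone slopes at machine tolerance (ties collapse)
  for (size_t i = 1; i < xs.size(); ++i) {
    if (ds2[i] > ds2[i - 1] + SLOPE_TOL * (1.0 + std::fabs(ds2[i - 1])))
      throw LogConcavityError();
  }
  build(xs, hs2, ds2, lo, hi);
}

bool Hull::insert(double xn, double hn, double dhn) {
  int kk = k();
  if (kk >= max_points) return false;
  if (!R_finite(hn) || !R_finite(dhn)) return false;
  if (xn <= lo || xn >= hi) return false;
  // locate insertion position
  int pos = (int)(std::lower_bound(x.begin(), x.end(), xn) - x.begin());
  if (pos < kk && std::fabs(x[pos] - xn) < 1e-12) return true;      // duplicate
  if (pos > 0 && std::fabs(x[pos - 1] - xn) < 1e-12) return true;   // duplicate
  // log-concavity check against neighbours
  if (pos > 0 && dhn > dh[pos - 1] + SLOPE_TOL * (1.0 + std::fabs(dh[pos - 1])))
    throw LogConcavityError();
  if (pos < kk && dh[pos] > dhn + SLOPE_TOL * (1.0 + std::fabs(dhn)))
    throw LogConcavityError();
  x.insert(x.begin() + pos, xn);
  h.insert(h.begin() + pos, hn);
  dh.insert(dh.begin() + pos, dhn);
  kk = k();
  // local update: z gains one knot; only z[pos], z[pos+1] change,
  // and segments pos-1, pos, pos+1 need new masses
  z.insert(z.begin() + pos + 1, 0.0);
  z[0] = lo; z[kk] = hi;  // re-anchor the domain edges
  if (pos > 0) z[pos] = std::min(std::max(intersect(pos - 1), lo), hi);
  if (pos + 1 < kk) z[pos + 1] = std::min(std::max(intersect(pos), lo), hi);
  logJ.insert(logJ.begin() + pos, 0.0);
  for (int i = std::max(0, pos - 1); i <= std::min(kk - 1, pos + 1); ++i)
    logJ[i] = seg_logJ(i);
  refresh_cum();
  return true;
}

double Hull::upper_at(double xx) const {
  int kk = k();
  // segment index: first i with z[i+1] >= xx
  int i = (int)(std::upper_bound(z.begin() + 1, z.end(), xx) - (z.begin() + 1));
  if (i >= kk) i = kk - 1;
  return h[i] + dh[i] * (xx - x[i]);
}

double Hull::lower_at(double xx) const {
  int kk = k();
  if (xx < x.front() || xx > x.back()) return R_NegInf;
  int j = (int)(std::upper_bound(x.begin(), x.end(), xx) - x.begin()) - 1;
  if (j >= kk - 1) j = kk - 2;
  if (j < 0) j = 0;
  double t = (xx - x[j]) / (x[j + 1] - x[j]);
  return h[j] + t * (h[j + 1] - h[j]);
}

double Hull::sample(double uprop) const {
  int kk = k();
  // half-open convention: ties on a cumulative boundary go right
  int i = (int)(std::upper_bound(cumJ.begin(), cumJ.end(), uprop) - cumJ.begin());
  if (i >= kk) i = kk - 1;
  double prev = (i == 0) ? 0.0 : cumJ[i - 1];
  double wseg = cumJ[i] - prev;
  double us = (wseg > 0.0) ? (uprop - prev) / wseg : 0.5;
  if (us < 0.0) us = 0.0;
  if (us >= 1.0) us = 1.0 - DBL_EPSILON;
  double A = z[i], B = z[i + 1], s = dh[i];
  if (A == R_NegInf) {           // s > 0
    if (us <= 0.0) return B - 745.0 / s;
    return B + std::log(us) / s;
  }
  if (B == R_PosInf) {           // s < 0
    return A + std::log1p(-us) / s;
  }
  double d = B - A;
  if (std::fabs(s) < TINY_SLOPE)  // second-order Taylor of the exact inverse
    return A + us * d + 0.5 * s * d * d * us * (1.0 - us);
  double sd = s * d;
  if (sd > 700.0) return A + d + std::log(us) / s;
  return A + std::log1p(us * std::expm1(sd)) / s;
}

void ars_sample_loop(Target &target, Hull &hull, int n, bool keep_hull,
                     double lo, double hi, double start,
                     std::vector<double> &out, ArsDiag &diag,
                     std::vector<int> *squeeze_flag) {
  out.clear(); out.reserve(n);
  if (squeeze_flag) { squeeze_flag->clear(); squeeze_flag->reserve(n); }
  if (hull.k() < 2) {
    hull.init(target, lo, hi, start);
    diag.target_evals += hull.k();
  }
  Hull fresh = hull;  // for the pseudo-adaptive reset
  for (int i = 0; i < n; ++i) {
    long guard = 0;
    for (;;) {
      if (++guard > 1000000L)
        throw InitError("rejection guard exceeded (10^6 proposals for one draw)");
      double uprop = unif_rand();
      double xs = hull.sample(uprop);
      double lu = std::log(unif_rand());
      double uk = hull.upper_at(xs);
      double lk = hull.lower_at(xs);
      ++diag.proposals;
      if (lu <= lk - uk) {  // squeeze accept: no target evaluation
        ++diag.squeeze_accepts;
        out.push_back(xs);
        if (squeeze_flag) squeeze_flag->push_back(1);
        break;
      }
      double hx, dhx;
      target.eval(xs, hx, dhx);
      ++diag.target_evals;
      if (R_finite(hx)) hull.insert(xs, hx, dhx);
      if (R_finite(hx) && lu <= hx - uk) {
        ++diag.full_accepts;
        out.push_back(xs);
        if (squeeze_flag) squeeze_flag->push_back(0);
        break;
      }
      ++diag.rejects;
    }
    if (!keep_hull) hull = fresh;
  }
}

} // namespace ars
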