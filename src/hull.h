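#ifndef DIFFSAMP_HULL_H
#define DIFFSAMP_HULL_H

#include <vector>
#include <stdexcept>

// Piecewise-linear upper/lower hull state for adaptive rejection sampling of
// a log-concave target h on (lo, hi) (edges may be infinite).  Segment i
// (0-based, i = 0..k-1) is the tangent at support point i, valid on
// [z[i], z[i+1]]; z has length k+1 with z[0] = lo, z[k] = hi.

namespace ars {

struct Target {
  virtual void eval(double x, double &h, double &dh) = 0;
  virtual ~Target() {}
};

struct LogConcavityError : std::runtime_error {
  LogConcavityError() : std::runtime_error(
      "log-concavity violation detected in hull update (increasing slopes)") {}
};
struct InitError : std::runtime_error {
  explicit InitError(const char *msg) : std::runtime_error(msg) {}
};

class Hull {
public:
  std::vector<double> x, h, dh, z, logJ;
  double lo, hi;
  int max_points;

  Hull() : lo(0), hi(0), max_points(200) {}

  // build from explicit support points (sorted by x); recomputes z and logJ
  void build(const std::vector<double> &xs, const std::vector<double> &hs,
             const std::vector<double> &dhs, double lo_, double hi_);

  // initial hull: bracket the mode from `start` so the envelope has finite
  // mass; k0 >= 2 support points (default 3)
  void init(Target &target, double lo_, double hi_, double start, int k0 = 3);

  // insert a support point (idempotent for duplicates); local z/J update
  // returns false if skipped (duplicate / cap reached)
  bool insert(double xn, double hn, double dhn);

  int k() const { return (int)x.size(); }
  double total_logJ() const;

  double upper_at(double xx) const;
  double lower_at(double xx) const;  // -Inf outside [x_1, x_k]

  // envelope inversion: uprop in [0,1) -> abscissa
  double sample(double uprop) const;

private:
  std::vector<double> cumJ;  // normalized cumulative segment masses
  void recompute_all();
  void refresh_cum();
  double seg_logJ(int i) const;
  double intersect(int j) const;  // z between support points j and j+1
};

// full ARS/P-ARS sampling loop over a target
struct ArsDiag {
  long proposals = 0, squeeze_accepts = 0, full_accepts = 0, rejects = 0,
       target_evals = 0;
};

void ars_sample_loop(Target &target, Hull &hull, int n, bool keep_hull,
                     double lo, double hi, double start,
                     std::vector<double> &out, ArsDiag &diag,
                     std::vector<int> *squeeze_flag = 0);

} // namespace ars

#endif
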