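#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Advance the two-state walkers n_steps steps, mutating copies of the
// state vectors. Per step, per walker (in index order), the RNG is
// consumed as: one uniform (state switch), then, iff the walker is
// unbound after the switch, two normals (x and y diffusion steps).
// Bound walkers consume no further draws. This fixed draw order is the
// contract that makes the R single-step reference (advance_state) and
// this loop bit-identical under a common seed.
//
// Boundary rules:
//  * unbound overshoot: radial mirror r -> 2 - r along the same ray,
//    re-applied, then clamped to 1;
//  * bound, drift outward past r = 1: clamped at 1 (membrane barrier);
//  * bound, drift inward through the origin: passes through (radius
//    |r'|, direction flipped).
// [[Rcpp::export]]
List cpp_advance_walkers(NumericVector x0, NumericVector y0,
                         LogicalVector bound0, int n_steps,
                         double p_bind, double p_unbind,
                         double step_sd, double drift_step,
                         int record_every) {
  const int n = x0.size();
  NumericVector x = clone(x0), y = clone(y0);
  LogicalVector bound = clone(bound0);
  std::vector<double> rec_mean;
  std::vector<int> rec_step;
  RNGScope scope;

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      if (bound[i]) {
        if (u < p_unbind) bound[i] = FALSE;
      } else {
        if (u < p_bind) bound[i] = TRUE;
      }
      if (!bound[i]) {
        double xx = x[i] + step_sd * norm_rand();
        double yy = y[i] + step_sd * norm_rand();
        double r = std::sqrt(xx * xx + yy * yy);
        if (r > 1.0) {
          double rr = r;
          for (int g = 0; g < 8 && rr > 1.0; ++g) rr = std::fabs(2.0 - rr);
          if (rr > 1.0) rr = 1.0;
          xx *= rr / r;
          yy *= rr / r;
          double r2 = xx * xx + yy * yy;   // guard roundoff overshoot
          if (r2 > 1.0) {
            double inv = 1.0 / std::sqrt(r2);
            xx *= inv;
            yy *= inv;
          }
        }
        x[i] = xx;
        y[i] = yy;
      } else {
        double r = std::sqrt(x[i] * x[i] + y[i] * y[i]);
        double rn = r + drift_step;
        if (rn > 1.0) rn = 1.0;
        if (r > 0.0) {
          double f = rn / r;          // negative rn flips through the origin
          x[i] *= f;
          y[i] *= f;
          double r2 = x[i] * x[i] + y[i] * y[i];
          if (r2 > 1.0) {
            double inv = 1.0 / std::sqrt(r2);
            x[i] *= inv;
            y[i] *= inv;
          }
        } else {
          x[i] = std::fabs(rn);       // direction undefined at the origin
          y[i] = 0.0;
        }
      }
    }
    if (record_every > 0 && s % record_every == 0) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += std::sqrt(x[i] * x[i] + y[i] * y[i]);
      rec_mean.push_back(m / n);
      rec_step.push_back(s);
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["bound"] = bound,
                      _["rec_step"] = wrap(rec_step),
                      _["rec_mean"] = wrap(rec_mean));
}
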