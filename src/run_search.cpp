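#include <Rcpp.h>
using namespace Rcpp;

// Core search loop. One encounter = one restart position followed by
// signed steps until the path crosses a detection threshold; the crossing
// step is truncated at the threshold and only the travelled part counts.
// Detection thresholds sit at rv and lam - rv (targets at 0 and lam).
//
// step_type: 1 = Levy truncated power law (p1 = mu, p2 = ell0)
//            2 = fixed length          (p1 = ell)
//            3 = shifted exponential   (p1 = rate, p2 = ell0)
//
// Uses R's RNG stream (seed with set.seed() before calling).
// [[Rcpp::export]]
List cpp_run_search(double lam, double rv, int step_type, double p1, double p2,
                    NumericVector starts, double max_steps_per_encounter,
                    bool per_encounter) {
  const int n_targets = starts.size();
  const double left = rv, right = lam - rv;
  const double inv_exp = (step_type == 1) ? -1.0 / (p1 - 1.0) : 0.0;

  double total_distance = 0.0, total_steps = 0.0, total_trunc = 0.0;
  NumericVector enc_dist, enc_steps;
  if (per_encounter) {
    enc_dist = NumericVector(n_targets);
    enc_steps = NumericVector(n_targets);
  }

  RNGScope scope;
  for (int k = 0; k < n_targets; ++k) {
    double x = starts[k];
    if (x < left || x > lam - left)
      stop("restart position outside the live interval");
    double dist = 0.0, steps = 0.0;
    for (;;) {
      if (steps >= max_steps_per_encounter)
        stop("encounter %d exceeded the step cap (%.0f steps)", k + 1,
             max_steps_per_encounter);
      double m;
      switch (step_type) {
      case 1: m = p2 * std::pow(unif_rand(), inv_exp); break;
      case 2: m = p1; break;
      default: m = p2 + exp_rand() / p1; break;
      }
      bool go_left = unif_rand() < 0.5;
      double dthr = go_left ? (x - left) : (right - x);
      steps += 1.0;
      if (m >= dthr) {           // crosses the threshold: truncated step
        dist += dthr;
        total_trunc += 1.0;
        break;
      }
      x += go_left ? -m : m;
      dist += m;
    }
    total_distance += dist;
    total_steps += steps;
    if (per_encounter) {
      enc_dist[k] = dist;
      enc_steps[k] = steps;
    }
  }

  List out = List::create(_["total_distance"] = total_distance,
                          _["n_steps"] = total_steps,
                          _["n_truncated"] = total_trunc);
  if (per_encounter) {
    out["encounter_distance"] = enc_dist;
    out["encounter_steps"] = enc_steps;
  }
  return out;
}
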