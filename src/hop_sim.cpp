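#include <Rcpp.h>
using namespace Rcpp;

// Picket-fence random walk on a square compartment lattice of edge L.
// A substep that would cross a compartment boundary succeeds with
// probability hop_p, otherwise the remainder of the step is reflected at
// the boundary.  Axes are independent (square lattice).  Uses R's RNG so
// set.seed() in R governs reproducibility.

static inline double step_axis(double pos, double dx, double L,
                               double hop_p) {
  double target = pos + dx;
  double eps = 1e-9 * L;
  for (int guard = 0; guard < 64; ++guard) {
    long cur = (long)std::floor(pos / L);
    long tgt = (long)std::floor(target / L);
    if (tgt == cur) return target;
    // first boundary on the way to target
    double b = (target > pos) ? (cur + 1) * L : cur * L;
    if (unif_rand() < hop_p) {
      pos = (target > pos) ? b + eps : b - eps;   // cross, keep going
    } else {
      target = 2.0 * b - target;                  // reflect remainder
    }
  }
  return pos;  // pathological many-crossing step: stay put
}

// [[Rcpp::export]]
List hop_sim_cpp(int n_frames, int substeps, double L, double sigma_step,
                 double hop_p, double x0, double y0) {
  RNGScope scope;
  NumericVector xf(n_frames), yf(n_frames);
  std::vector<double> dwells;
  double x = x0, y = y0;
  long cx = (long)std::floor(x / L), cy = (long)std::floor(y / L);
  long run = 0;           // substeps spent in current compartment
  bool first = true;      // first dwell is censored (unknown entry time)
  double cens_first = 0.0;
  for (int f = 0; f < n_frames; ++f) {
    for (int s = 0; s < substeps; ++s) {
      x = step_axis(x, norm_rand() * sigma_step, L, hop_p);
      y = step_axis(y, norm_rand() * sigma_step, L, hop_p);
      long ncx = (long)std::floor(x / L), ncy = (long)std::floor(y / L);
      if (ncx != cx || ncy != cy) {
        if (!first) dwells.push_back((double)run);
        else cens_first = (double)run;
        first = false;
        cx = ncx; cy = ncy; run = 0;
      }
      run++;
    }
    xf[f] = x; yf[f] = y;
  }
  // first and last runs are censored (entry/exit not observed)
  NumericVector cens = NumericVector::create(cens_first, (double)run);
  return List::create(_["x"] = xf, _["y"] = yf,
                      _["dwell_substeps"] = wrap(dwells),
                      _["censored_substeps"] = cens);
}
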