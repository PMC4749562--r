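// Exact Gillespie simulation of the reporter network with piecewise-constant
// transcription rate beta(t).  Time-varying input handled by restarting the
// clock at switch times: propensities are constant between reactions within a
// segment, so the algorithm remains exact.  Uses R's RNG so runs are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List ssa_reporter_cpp(const arma::vec& grid, const arma::vec& s,
                      const arma::vec& beta, double dm, double dp,
                      double alpha, int m0, int p0) {
  const int n = grid.n_elem;
  IntegerVector mRNA(n), protein(n);
  RNGScope scope;

  double t = grid(0), t_end = grid(n - 1);
  long m = m0, p = p0;
  int gi = 0;

  // boundaries: switch times strictly inside (grid0, gridEnd)
  std::vector<double> bounds;
  for (arma::uword j = 0; j < s.n_elem; ++j)
    if (s(j) > t + 1e-12 && s(j) < t_end - 1e-12) bounds.push_back(s(j));
  bounds.push_back(t_end);
  size_t bi = 0;

  int seg = 0;
  for (arma::uword j = 0; j < s.n_elem; ++j) if (s(j) <= t + 1e-12) ++seg;

  while (t < t_end) {
    double seg_end = bounds[bi];
    double b = beta(seg);
    double a_total = b + dm * m + alpha * m + dp * p;
    double t_new;
    bool event = false;
    if (a_total <= 0.0) {
      t_new = seg_end;
    } else {
      double tau = ::exp_rand() / a_total;
      if (t + tau >= seg_end) {
        t_new = seg_end;
      } else {
        t_new = t + tau;
        event = true;
      }
    }
    // record grid points passed with the pre-event state
    while (gi < n && grid(gi) < t_new - 1e-12) {
      mRNA[gi] = (int)m; protein[gi] = (int)p; ++gi;
    }
    if (event) {
      double u = ::unif_rand() * a_total;
      if (u < b)                       ++m;
      else if (u < b + dm * m)         --m;
      else if (u < b + dm * m + alpha * m) ++p;
      else                             --p;
    } else if (t_new >= seg_end - 1e-15 && bi + 1 < bounds.size()) {
      ++bi; ++seg;
    }
    t = t_new;
  }
  while (gi < n) { mRNA[gi] = (int)m; protein[gi] = (int)p; ++gi; }

  return List::create(_["mRNA"] = mRNA, _["protein"] = protein);
}
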