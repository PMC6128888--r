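// Fused synthesis kernel for the night simulator: copies the stationary
// background slice for each epoch of a chunk and adds the scheduled
// sound events (template segment x raised-cosine envelope, normalized to
// the event's target RMS) in a single pass per event.

#include <Rcpp.h>
#include <cstring>
#include <cmath>
using namespace Rcpp;

static inline double ramp_env(int i, int m, int nr) {
  // matches the R prototype: start ramp set first, end ramp overrides
  double env = 1.0;
  if (i < nr) env = 0.5 - 0.5 * std::cos(M_PI * (double)(i + 1) / nr);
  if (i >= m - nr) env = 0.5 - 0.5 * std::cos(M_PI * (double)(m - i) / nr);
  return env;
}

// [[Rcpp::export]]
NumericMatrix synth_chunk_cpp(NumericVector bg, IntegerVector sh,
                              int frame_len, int frames_per_epoch,
                              List tpls, IntegerVector ev_epoch,
                              IntegerVector tpl_id, IntegerVector tpl_off,
                              IntegerVector n_ev, IntegerVector s_ev,
                              IntegerVector ramp_n, NumericVector amp) {
  const int K = sh.size();
  const R_xlen_t n = (R_xlen_t)frame_len * frames_per_epoch;
  // background overwrites every sample, so skip zero-initialization
  NumericVector flat(no_init(n * K));
  flat.attr("dim") = IntegerVector::create(frame_len, frames_per_epoch * K);
  NumericMatrix out(flat);
  double* op = REAL(out);
  for (int k = 0; k < K; ++k) {
    std::memcpy(op + (size_t)k * n, REAL(bg) + (sh[k] - 1),
                n * sizeof(double));
  }
  const int n_events = tpl_id.size();
  for (int e = 0; e < n_events; ++e) {
    double* xp = op + (size_t)(ev_epoch[e] - 1) * n;
    NumericVector tpl = tpls[tpl_id[e] - 1];
    const double* tp = REAL(tpl) + tpl_off[e];
    const int m = n_ev[e];
    const int nr = ramp_n[e];
    double ss = 0.0;
    for (int i = 0; i < m; ++i) {
      const double v = tp[i] * ramp_env(i, m, nr);
      ss += v * v;
    }
    if (ss <= 0.0) continue;
    const double scale = amp[e] / std::sqrt(ss / m);
    const int lo = s_ev[e] < 0 ? -s_ev[e] : 0;
    const int hi = std::min((R_xlen_t)m, n - s_ev[e]);
    for (int i = lo; i < hi; ++i) {
      xp[s_ev[e] + i] += tp[i] * ramp_env(i, m, nr) * scale;
    }
  }
  return out;
}
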