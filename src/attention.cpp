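// Cached-attention kernel for batched autoregressive sampling.
//
// The R sampler keeps per-layer key/value caches as d x (B*Tcap) matrices,
// one d-vector per column, sequence-major: column b*Tcap + j holds position
// j+1 of sequence b+1, so each sequence's cache is contiguous and the
// per-step scan streams sequentially through memory. The kernel computes
// one decoding step of multi-head causal attention for the whole batch
// without allocating intermediates.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Write x (d x B) into each sequence's cache slot for position `pos`
// (1-based); Tcap is the per-sequence capacity.
// [[Rcpp::export(name = ".cache_write")]]
void cache_write(NumericMatrix buf, NumericMatrix x, int pos, int Tcap) {
  const int d = x.nrow(), B = x.ncol();
  if (pos < 1 || pos > Tcap) stop("cache position out of range");
  double* out = buf.begin();
  const double* in = x.begin();
  for (int b = 0; b < B; ++b) {
    std::copy(in + (R_xlen_t)b * d, in + (R_xlen_t)(b + 1) * d,
              out + ((R_xlen_t)b * Tcap + (pos - 1)) * d);
  }
}

// One attention step over cached positions 1..pos for all batch rows and
// heads. q is d x B (already rotary-embedded, as are the cached keys).
// Returns o, d x B.
// [[Rcpp::export(name = ".attn_step")]]
NumericMatrix attn_step(NumericMatrix Kbuf, NumericMatrix Vbuf,
                        NumericMatrix q, int pos, int nh, int Tcap) {
  const int d = q.nrow(), B = q.ncol();
  const int hd = d / nh;
  const double inv = 1.0 / std::sqrt((double)hd);
  NumericMatrix o(d, B);
  std::vector<double> s((R_xlen_t)pos * nh);
  const double* K = Kbuf.begin();
  const double* V = Vbuf.begin();
  for (int b = 0; b < B; ++b) {
    const double* qb = &q(0, b);
    double* ob = &o(0, b);
    const double* Kb = K + (R_xlen_t)b * Tcap * d;
    const double* Vb = V + (R_xlen_t)b * Tcap * d;
    // scores, all heads in one streaming pass over this sequence's keys
    for (int j = 0; j < pos; ++j) {
      const double* kj = Kb + (R_xlen_t)j * d;
      for (int h = 0; h < nh; ++h) {
        const int c0 = h * hd;
        double acc = 0.0;
        for (int c = 0; c < hd; ++c) acc += kj[c0 + c] * qb[c0 + c];
        s[(R_xlen_t)h * pos + j] = acc * inv;
      }
    }
    for (int h = 0; h < nh; ++h) {
      double* sh = &s[(R_xlen_t)h * pos];
      double mx = R_NegInf;
      for (int j = 0; j < pos; ++j) if (sh[j] > mx) mx = sh[j];
      double z = 0.0;
      for (int j = 0; j < pos; ++j) {
        sh[j] = std::exp(sh[j] - mx);
        z += sh[j];
      }
      const double zinv = 1.0 / z;
      for (int j = 0; j < pos; ++j) sh[j] *= zinv;
    }
    // weighted value sum, again one streaming pass
    for (int j = 0; j < pos; ++j) {
      const double* vj = Vb + (R_xlen_t)j * d;
      for (int h = 0; h < nh; ++h) {
        const int c0 = h * hd;
        const double w = s[(R_xlen_t)h * pos + j];
        for (int c = 0; c < hd; ++c) ob[c0 + c] += w * vj[c0 + c];
      }
    }
  }
  return o;
}
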