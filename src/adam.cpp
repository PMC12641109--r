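#include <Rcpp.h>
using namespace Rcpp;

// One Adam update over a flat named parameter list. First/second-moment
// buffers are updated in place (they are owned solely by the optimizer
// state); parameter vectors are freshly allocated so snapshots of earlier
// parameters (best-epoch weights) are never aliased.
//
// shrink[j]: parameter j receives decoupled L2/L1 shrinkage
// att[j]:    parameter j belongs to the attention group (lr multiplier)
// Parameter vectors are mutated IN PLACE for speed; the R caller owns
// them exclusively inside the training loop and takes explicit deep
// copies (see snapshot_params) whenever a checkpoint is retained.
//
// [[Rcpp::export]]
void adam_step_cpp(List params, List grads, List m, List v, int t,
                   double lr, double att_mult, LogicalVector shrink,
                   LogicalVector att, double weight_decay, double l1,
                   double beta1, double beta2, double eps) {
  const int J = params.size();
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (int j = 0; j < J; ++j) {
    NumericVector p = params[j], g = grads[j], mj = m[j], vj = v[j];
    const R_xlen_t n = p.size();
    const double lrk = att[j] ? lr * att_mult : lr;
    const bool sh = shrink[j];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double gi = g[i];
      const double mi = beta1 * mj[i] + (1.0 - beta1) * gi;
      const double vi = beta2 * vj[i] + (1.0 - beta2) * gi * gi;
      mj[i] = mi;
      vj[i] = vi;
      double step = lrk * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
      if (sh) {
        const double pi = p[i];
        if (weight_decay > 0) step += lr * weight_decay * pi;
        if (l1 > 0) step += lr * l1 * ((pi > 0) - (pi < 0));
      }
      p[i] -= step;
    }
  }
}
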