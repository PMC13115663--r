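#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update over the flattened parameter vector. The state
// vectors are owned exclusively by the optimizer state list, so mutating
// them in place is safe; gradients arrive already scattered into `g`.
// [[Rcpp::export]]
void adam_update_cpp(NumericVector pvec, NumericVector m, NumericVector v,
                     NumericVector g, NumericVector decay_mask,
                     double lr, double weight_decay, int t,
                     double beta1, double beta2, double eps) {
  const R_xlen_t n = pvec.size();
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  const double scale = lr * std::sqrt(bc2) / bc1;
  const double eps2 = eps * std::sqrt(bc2);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] + weight_decay * decay_mask[i] * pvec[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    pvec[i] -= scale * m[i] / (std::sqrt(v[i]) + eps2);
  }
}

// Copy each gradient array into its slice of the flat gradient vector.
// Slices not covered by `grads` keep their previous content, so the
// caller zeroes `g` when the gradient set can change.
// [[Rcpp::export]]
void scatter_grads_cpp(NumericVector g, List grads, IntegerVector starts) {
  for (int k = 0; k < grads.size(); ++k) {
    NumericVector gk(grads[k]);
    std::copy(gk.begin(), gk.end(), g.begin() + starts[k]);
  }
}

// Refresh the parameter arrays (in place) from the flat parameter vector.
// [[Rcpp::export]]
void gather_params_cpp(List params, NumericVector pvec,
                       IntegerVector starts, IntegerVector which) {
  for (int k = 0; k < which.size(); ++k) {
    NumericVector pk(params[which[k]]);
    std::copy(pvec.begin() + starts[which[k]],
              pvec.begin() + starts[which[k]] + pk.size(), pk.begin());
  }
}
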