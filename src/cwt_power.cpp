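// Batched continuous-wavelet periodogram power.
//
// Given the FFT spectra of B padded hourly series (columns of F) and the
// real, analytic wavelet kernels for T scales (columns of W, zero on
// negative frequencies), computes for every (scale, series) the
// time-averaged periodogram power sqrt(mean |S|), the temporal mean taken
// over samples [lo_t, hi_t] (0-based, inclusive) outside the cone of
// influence. Scales with lo_t > hi_t yield NaN.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export]]
arma::mat cwt_power_impl(const arma::cx_mat& F, const arma::mat& W,
                         const arma::ivec& lo, const arma::ivec& hi) {
  const arma::uword Npad = F.n_rows, B = F.n_cols, T = W.n_cols;
  arma::mat out(T, B);
  arma::cx_mat Y(Npad, B);
  for (arma::uword t = 0; t < T; ++t) {
    if (lo[t] > hi[t]) {
      out.row(t).fill(arma::datum::nan);
      continue;
    }
    Y = F.each_col() % arma::cx_vec(W.col(t), arma::zeros(Npad));
    arma::cx_mat S = arma::ifft(Y);
    out.row(t) = arma::sqrt(
      arma::mean(arma::abs(S.rows((arma::uword)lo[t], (arma::uword)hi[t])), 0));
  }
  return out;
}
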