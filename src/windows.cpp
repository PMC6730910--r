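// Sliding-window extraction: every window is a contiguous copy of 150
// samples per channel. The output array (win_len x n_ch x n_win) is
// allocated directly as an R object and filled in place, so no second
// buffer of the (potentially gigabyte-sized) window stack exists.

#include <Rcpp.h>

// [[Rcpp::export]]
Rcpp::NumericVector extract_windows_cpp(const Rcpp::NumericMatrix& rec_t,
                                        int win_len) {
  const int n_samples = rec_t.nrow();
  const int n_ch = rec_t.ncol();
  const int n_win = n_samples - win_len + 1;
  Rcpp::NumericVector out(Rcpp::Dimension(win_len, n_ch, n_win));
  double* po = out.begin();
  const double* pr = rec_t.begin();
  for (int w = 0; w < n_win; ++w) {
    for (int c = 0; c < n_ch; ++c) {
      std::memcpy(po + (static_cast<size_t>(w) * n_ch + c) * win_len,
                  pr + static_cast<size_t>(c) * n_samples + w,
                  sizeof(double) * win_len);
    }
  }
  return out;
}
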