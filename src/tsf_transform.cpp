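#include <Rcpp.h>
using namespace Rcpp;

// Interval transform of the time series forest: for every (interval,
// channel) pair, the mean, sample standard deviation and least-squares slope
// (per sample index) of the window segment. X is the stacked instance
// matrix, one row per instance, channel-major blocks of width w. Column
// layout of the result matches cbind over intervals of per-interval
// (channel-major, then mean/sd/slope) blocks.

// [[Rcpp::export(name = ".tsf_transform")]]
NumericMatrix tsf_transform(NumericMatrix X, int w, int n_channels,
                            IntegerVector starts, IntegerVector ends) {
  int n = X.nrow();
  int n_int = starts.size();
  NumericMatrix out(n, n_int * n_channels * 3);

  for (int k = 0; k < n_int; ++k) {
    int s = starts[k] - 1, e = ends[k] - 1;
    int len = e - s + 1;
    double tbar = (len - 1) / 2.0;
    double stt = 0.0;
    for (int t = 0; t < len; ++t) stt += (t - tbar) * (t - tbar);
    for (int ch = 0; ch < n_channels; ++ch) {
      int col0 = k * n_channels * 3 + ch * 3;
      int off = ch * w + s;
      for (int i = 0; i < n; ++i) {
        double sum = 0.0, sumsq = 0.0, wsum = 0.0;
        for (int t = 0; t < len; ++t) {
          double v = X(i, off + t);
          sum += v;
          sumsq += v * v;
          wsum += (t - tbar) * v;
        }
        double m = sum / len;
        double ss = sumsq - len * m * m;
        if (ss < 0) ss = 0;
        out(i, col0) = m;
        out(i, col0 + 1) = len > 1 ? std::sqrt(ss / (len - 1)) : 0.0;
        out(i, col0 + 2) = stt > 0 ? wsum / stt : 0.0;
      }
    }
  }
  return out;
}
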