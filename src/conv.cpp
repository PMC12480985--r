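#include <Rcpp.h>
using namespace Rcpp;

// 1-D convolution along columns with replicate edge padding.
// k must have odd length; result has the same dimensions as x.
static void conv_cols_inplace(const NumericMatrix& x, const NumericVector& k,
                              NumericMatrix& out) {
  const int n = x.nrow(), m = x.ncol(), kl = k.size();
  const int h = (kl - 1) / 2;
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int t = 0; t < kl; ++t) {
        int ii = i + t - h;
        if (ii < 0) ii = 0;
        else if (ii >= n) ii = n - 1;
        acc += k[kl - 1 - t] * x(ii, j);
      }
      out(i, j) = acc;
    }
  }
}

// [[Rcpp::export(name = ".sep_conv2")]]
NumericMatrix sep_conv2(NumericMatrix x, NumericVector krow, NumericVector kcol) {
  if (krow.size() % 2 == 0 || kcol.size() % 2 == 0)
    stop("kernels must have odd length");
  NumericMatrix tmp(x.nrow(), x.ncol());
  conv_cols_inplace(x, krow, tmp);
  NumericMatrix tmpt = transpose(tmp);
  NumericMatrix outt(tmpt.nrow(), tmpt.ncol());
  conv_cols_inplace(tmpt, kcol, outt);
  return transpose(outt);
}

// Local maxima of x in a (2r+1)^2 square window, value strictly above thr.
// Plateaus: a pixel qualifies if no neighbour in the window is larger and it
// is the first (column-major) pixel of the plateau. Border of width r is
// excluded. Returns a two-column matrix of 1-based (row, col) indices.
// [[Rcpp::export(name = ".local_maxima")]]
IntegerMatrix local_maxima(NumericMatrix x, int r, double thr) {
  const int n = x.nrow(), m = x.ncol();
  std::vector<int> ri, ci;
  for (int j = r; j < m - r; ++j) {
    for (int i = r; i < n - r; ++i) {
      double v = x(i, j);
      if (!(v > thr)) continue;
      bool ok = true;
      for (int dj = -r; dj <= r && ok; ++dj) {
        for (int di = -r; di <= r; ++di) {
          if (di == 0 && dj == 0) continue;
          double w = x(i + di, j + dj);
          if (w > v || (w == v && (dj < 0 || (dj == 0 && di < 0)))) {
            ok = false;
            break;
          }
        }
      }
      if (ok) { ri.push_back(i + 1); ci.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t t = 0; t < ri.size(); ++t) { out(t, 0) = ri[t]; out(t, 1) = ci[t]; }
  return out;
}

// Column-wise median for a channels x samples matrix, taken across rows
// at each column (i.e. the across-channel median at every sample).
// [[Rcpp::export(name = ".col_median")]]
NumericVector col_median(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(m);
  std::vector<double> buf(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    std::sort(buf.begin(), buf.end());
    out[j] = (n % 2 == 1) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
  }
  return out;
}
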