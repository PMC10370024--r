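#include <Rcpp.h>
using namespace Rcpp;

// Smoothed local autocorrelation of the binomial reduced interference
// distribution. For lag tau = 0..L computes
//   K(n, tau) = sum_{m=-tau}^{tau} w_tau(m) x(n+m+tau) x(n+m-tau)
// with w_tau the binomial weights C(2*tau, tau+m) / 4^tau (sum 1) and x
// treated as zero outside its support. Returned as an N x (L+1) matrix;
// the tau = 0 column is exactly x(n)^2, which anchors the energy contract.
// [[Rcpp::export]]
NumericMatrix rid_lag_matrix(NumericVector x, int max_lag) {
  const int n = x.size();
  const int L = max_lag;
  NumericMatrix K(n, L + 1);

  // binomial weights per lag, built by Pascal recursion on normalized rows
  std::vector< std::vector<double> > w(L + 1);
  w[0] = std::vector<double>(1, 1.0);
  for (int tau = 1; tau <= L; ++tau) {
    // row of order 2*tau from row of order 2*(tau-1): two convolutions
    // with {1/2, 1/2}
    std::vector<double> prev = w[tau - 1];
    for (int rep = 0; rep < 2; ++rep) {
      std::vector<double> cur(prev.size() + 1, 0.0);
      for (size_t i = 0; i < prev.size(); ++i) {
        cur[i] += 0.5 * prev[i];
        cur[i + 1] += 0.5 * prev[i];
      }
      prev = cur;
    }
    w[tau] = prev; // length 2*tau + 1, indices m = -tau..tau
  }

  for (int tau = 0; tau <= L; ++tau) {
    const std::vector<double>& wt = w[tau];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      int mlo = -tau, mhi = tau;
      for (int m = mlo; m <= mhi; ++m) {
        int ia = i + m + tau, ib = i + m - tau;
        if (ia < 0 || ia >= n || ib < 0 || ib >= n) continue;
        acc += wt[m + tau] * x[ia] * x[ib];
      }
      K(i, tau) = acc;
    }
  }
  return K;
}
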