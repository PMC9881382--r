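#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mean out-of-bag accuracy of the univariate median-threshold classifier,
// for every label column (observed + permuted outcomes) and every protein.
//
// values : n_cases x n_proteins abundance (any monotone scale; only order
//          relative to the in-bag median matters)
// labels : n_cases x n_labelsets integer 0/1 (1 = progressor)
// boot   : n_resamples x n_cases 1-based in-bag indices, drawn once and
//          shared across label sets (the reuse contract)
// direction_mode : 0 = pick the direction with the higher in-bag accuracy
//                  (tie -> above-median predicts progressor);
//                  1 = fixed per protein by fc_dir (+1: above-median predicts
//                  progressor, -1: below-median does)
//
// Values equal to the in-bag median count as "at/below". Resamples with an
// empty out-of-bag set are skipped; the return is the mean accuracy over
// retained resamples (NaN if none were retained).
// [[Rcpp::export]]
NumericMatrix bag_accuracy_kernel(const NumericMatrix& values,
                                  const IntegerMatrix& labels,
                                  const IntegerMatrix& boot,
                                  const int direction_mode,
                                  const IntegerVector& fc_dir) {
  const int n = values.nrow(), P = values.ncol();
  const int K = labels.ncol(), B = boot.nrow();
  if (labels.nrow() != n || boot.ncol() != n)
    stop("values, labels and boot must agree on the number of cases");
  if (direction_mode == 1 && fc_dir.size() != P)
    stop("fc_dir must have one entry per protein");

  NumericMatrix out(K, P);
  std::vector< std::vector<int> > oob(B);
  std::vector<char> inbag(n);
  NumericMatrix med(B, P);
  std::vector<double> buf(n);

  for (int b = 0; b < B; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) inbag[boot(b, i) - 1] = 1;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob[b].push_back(i);
    for (int p = 0; p < P; ++p) {
      for (int i = 0; i < n; ++i) buf[i] = values(boot(b, i) - 1, p);
      std::sort(buf.begin(), buf.end());
      med(b, p) = (n % 2) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }

  for (int k = 0; k < K; ++k) {
    for (int p = 0; p < P; ++p) {
      double acc_sum = 0.0;
      int used = 0;
      for (int b = 0; b < B; ++b) {
        const int n_oob = (int)oob[b].size();
        if (n_oob == 0) continue;
        const double m = med(b, p);
        int dir;
        if (direction_mode == 1) {
          dir = fc_dir[p];
        } else {
          // in-bag accuracy of "above-median predicts progressor", counted
          // over the bootstrap multiset; the opposite direction scores 1 -
          // this, so the comparison reduces to a majority check
          int agree = 0;
          for (int i = 0; i < n; ++i) {
            const int idx = boot(b, i) - 1;
            agree += ((values(idx, p) > m) == (labels(idx, k) == 1));
          }
          dir = (2 * agree >= n) ? 1 : -1;
        }
        int corr = 0;
        for (int j = 0; j < n_oob; ++j) {
          const int idx = oob[b][j];
          const bool above = values(idx, p) > m;
          const bool pred = (dir == 1) ? above : !above;
          corr += (pred == (labels(idx, k) == 1));
        }
        acc_sum += (double)corr / n_oob;
        ++used;
      }
      out(k, p) = used ? acc_sum / used : NA_REAL;
    }
  }
  return out;
}
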