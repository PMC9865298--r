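#include <Rcpp.h>
using namespace Rcpp;

// Distance-weighted k-NN vote over one chunk of query rows.
//
// cross: -2 * X %*% t(Q) for the chunk (n x m, training rows down the
// columns so the scan is cache-contiguous); qsq, trsq: squared row norms
// of Q and X, so dist^2(r, j) = qsq[r] + trsq[j] + cross(j, r).
// y: 1-based class index per training row.  Votes are weighted by inverse
// distance; queries coinciding with training points (dist <= 1e-8) are
// decided by those exact matches alone.  Ties go to the lower class index.
// [[Rcpp::export]]
IntegerVector knn_vote(NumericMatrix cross, NumericVector qsq,
                       NumericVector trsq, IntegerVector y,
                       int n_classes, int k) {
  const int n = cross.nrow(), m = cross.ncol();
  IntegerVector out(m);
  std::vector<double> best_d(k);
  std::vector<int> best_i(k);
  for (int r = 0; r < m; ++r) {
    const double *col = &cross(0, r);
    int filled = 0;
    for (int j = 0; j < n; ++j) {
      double d2 = qsq[r] + trsq[j] + col[j];
      if (d2 < 0) d2 = 0;
      if (filled < k) {
        int pos = filled++;
        while (pos > 0 && best_d[pos - 1] > d2) {
          best_d[pos] = best_d[pos - 1];
          best_i[pos] = best_i[pos - 1];
          --pos;
        }
        best_d[pos] = d2;
        best_i[pos] = j;
      } else if (d2 < best_d[k - 1]) {
        int pos = k - 1;
        while (pos > 0 && best_d[pos - 1] > d2) {
          best_d[pos] = best_d[pos - 1];
          best_i[pos] = best_i[pos - 1];
          --pos;
        }
        best_d[pos] = d2;
        best_i[pos] = j;
      }
    }
    std::vector<double> votes(n_classes, 0.0);
    bool exact = best_d[0] <= 1e-16;
    for (int s = 0; s < filled; ++s) {
      int cls = y[best_i[s]] - 1;
      if (exact) {
        if (best_d[s] <= 1e-16) votes[cls] += 1.0;
      } else {
        votes[cls] += 1.0 / std::sqrt(best_d[s]);
      }
    }
    int win = 0;
    for (int c = 1; c < n_classes; ++c) {
      if (votes[c] > votes[win]) win = c;
    }
    out[r] = win + 1;
  }
  return out;
}
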