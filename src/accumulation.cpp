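#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo engine for allele accumulation curves.
//
// One uniform permutation of the cohort yields the whole curve at once: an
// allele is captured by the first n individuals iff the smallest permutation
// rank among its carriers is <= n.  Per replicate we histogram those
// first-capture ranks by allele class and accumulate, for every n, the
// per-class captured counts and their squares (for Monte-Carlo standard
// errors).  Uses R's RNG, so results are reproducible under set.seed().
//
// carriers: list of 1-based integer vectors, the individuals carrying each
//           catalog allele (each must be non-empty)
// class_id: 1-based class index per allele, length = length(carriers)
// n_classes, n_ind, reps: counts
//
// Returns sum and sumsq matrices of dimension (n_classes + 1) x n_ind; row 1
// is the "all" aggregate, rows 2.. follow class_id numbering.
// [[Rcpp::export]]
List accum_kernel(List carriers, IntegerVector class_id, int n_classes,
                  int n_ind, int reps) {
  const int A = carriers.size();
  if (class_id.size() != A) stop("class_id length mismatch");
  std::vector<std::vector<int>> carr(A);
  for (int a = 0; a < A; ++a) {
    IntegerVector v = carriers[a];
    if (v.size() == 0) stop("allele with no carriers in cohort");
    carr[a].assign(v.begin(), v.end());
    for (int ix : carr[a])
      if (ix < 1 || ix > n_ind) stop("carrier index out of range");
  }
  const int K = n_classes + 1;  // row 0 = "all"
  NumericMatrix sum(K, n_ind), sumsq(K, n_ind);
  std::vector<int> rank(n_ind);
  std::vector<int> hist(K * n_ind);

  for (int rep = 0; rep < reps; ++rep) {
    IntegerVector perm = sample(n_ind, n_ind, false);  // R RNG
    for (int k = 0; k < n_ind; ++k) rank[perm[k] - 1] = k;  // 0-based rank
    std::fill(hist.begin(), hist.end(), 0);
    for (int a = 0; a < A; ++a) {
      int first = n_ind;
      for (int ix : carr[a]) {
        int r = rank[ix - 1];
        if (r < first) first = r;
      }
      int cls = class_id[a];  // 1..n_classes
      ++hist[0 * n_ind + first];
      ++hist[cls * n_ind + first];
    }
    for (int c = 0; c < K; ++c) {
      long cum = 0;
      for (int n = 0; n < n_ind; ++n) {
        cum += hist[c * n_ind + n];
        sum(c, n) += cum;
        sumsq(c, n) += (double)cum * (double)cum;
      }
    }
    if (rep % 256 == 0) checkUserInterrupt();
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq);
}
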