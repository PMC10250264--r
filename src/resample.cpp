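#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stratified resampling engine shared by the split-half and length-curve
// code. Trials are laid out contiguously by group (participant x stratum);
// per replication and group it draws, using R's RNG stream:
//   method 0: a subsample of k_sub trials without replacement (half A only);
//   method 1: a permutated split -- subsample k_sub (or all) trials, then
//             partition them into two disjoint halves whose sizes differ by
//             at most one (the odd trial lands in a half at random);
//   method 2: a Monte Carlo split -- subsample k_sub (or all) trials, then
//             draw each half independently with replacement from them
//             (ceil(s/2) draws, or s when mc_full_size).
// Each trial carries a validity weight w (0/1): sums accumulate w*x and
// counts accumulate w, so flagged trials inside a draw simply do not
// contribute to the half mean.
// [[Rcpp::export]]
List resample_halves_cpp(NumericVector x, NumericVector w,
                         IntegerVector grp_start, IntegerVector grp_size,
                         IntegerVector k_sub, int n_reps, int method,
                         bool mc_full_size) {
  const int G = grp_start.size();
  NumericMatrix sum_a(G, n_reps), cnt_a(G, n_reps);
  const bool two_halves = method != 0;
  NumericMatrix sum_b(two_halves ? G : 1, two_halves ? n_reps : 1);
  NumericMatrix cnt_b(two_halves ? G : 1, two_halves ? n_reps : 1);

  int maxm = 0;
  for (int g = 0; g < G; ++g) maxm = std::max(maxm, grp_size[g]);
  std::vector<int> idx(maxm);

  for (int g = 0; g < G; ++g) {
    const int st = grp_start[g], m = grp_size[g];
    const int s = (k_sub[g] > 0) ? k_sub[g] : m;
    if (s > m) stop("subsample size exceeds stratum size");
    for (int j = 0; j < m; ++j) idx[j] = st + j;
    const bool need_shuffle = (s < m) || method == 1;

    for (int rep = 0; rep < n_reps; ++rep) {
      if (need_shuffle) {
        for (int j = 0; j < s; ++j) {
          int r = j + (int)(unif_rand() * (m - j));
          if (r >= m) r = m - 1;
          std::swap(idx[j], idx[r]);
        }
      }
      if (method == 0) {
        double sa = 0.0, ca = 0.0;
        for (int j = 0; j < s; ++j) {
          sa += w[idx[j]] * x[idx[j]];
          ca += w[idx[j]];
        }
        sum_a(g, rep) = sa; cnt_a(g, rep) = ca;
      } else if (method == 1) {
        int ka = s / 2;
        if (s % 2 == 1 && unif_rand() < 0.5) ++ka;
        double sa = 0.0, ca = 0.0, sb = 0.0, cb = 0.0;
        for (int j = 0; j < ka; ++j) {
          sa += w[idx[j]] * x[idx[j]]; ca += w[idx[j]];
        }
        for (int j = ka; j < s; ++j) {
          sb += w[idx[j]] * x[idx[j]]; cb += w[idx[j]];
        }
        sum_a(g, rep) = sa; cnt_a(g, rep) = ca;
        sum_b(g, rep) = sb; cnt_b(g, rep) = cb;
      } else {
        const int h = mc_full_size ? s : (s + 1) / 2;
        double sa = 0.0, ca = 0.0, sb = 0.0, cb = 0.0;
        for (int j = 0; j < h; ++j) {
          int r = (int)(unif_rand() * s); if (r >= s) r = s - 1;
          sa += w[idx[r]] * x[idx[r]]; ca += w[idx[r]];
        }
        for (int j = 0; j < h; ++j) {
          int r = (int)(unif_rand() * s); if (r >= s) r = s - 1;
          sb += w[idx[r]] * x[idx[r]]; cb += w[idx[r]];
        }
        sum_a(g, rep) = sa; cnt_a(g, rep) = ca;
        sum_b(g, rep) = sb; cnt_b(g, rep) = cb;
      }
    }
  }
  if (two_halves) {
    return List::create(_["sum_a"] = sum_a, _["cnt_a"] = cnt_a,
                        _["sum_b"] = sum_b, _["cnt_b"] = cnt_b);
  }
  return List::create(_["sum_a"] = sum_a, _["cnt_a"] = cnt_a);
}
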