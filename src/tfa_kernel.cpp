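#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// The TFA statistic scans every pair of rank thresholds (r_s over the SAM
// ordering, r_t over the target-propensity ordering) on a grid, forms the
// 2x2 table of the two top-lists against the rest of the gene universe, and
// keeps the maximum Yates-corrected chi-square among tables whose expected
// overlap exceeds min_expected and whose observed overlap exceeds expected.
//
// With a = |top-r_s ∩ top-r_t|, b = r_s - a, c = r_t - a, d = N - r_s - r_t + a:
//   ad - bc = a*N - r_s*r_t
//   chi2    = N * (max(0, |ad-bc| - N/2))^2 / (r_s (N-r_s) r_t (N-r_t))
// Maintaining binned prefix counts of the top-r_s genes' propensity ranks
// makes each table O(1) after the O(N) binning pass.
//
// Besides the overlap constraints, tables must satisfy the classic
// chi-square validity rule: the expected count of every cell must reach
// min_cell (default 5). Without it, near-degenerate corner tables (a
// complement margin of a handful of genes) dominate the null maximum with
// Poisson-regime spikes and destroy the linear -log p / statistic
// relationship the extrapolation relies on.

struct ScanResult {
  double chi2;
  int rs, rt;
  bool admissible;   // at least one table passed both constraints
};

// tp_of_sam: 1-based propensity rank of the gene at SAM rank i+1 (0-based i).
static ScanResult scan_grid(const std::vector<int>& tp_of_sam, int grid_step,
                            double min_expected, double min_cell) {
  const int N = (int)tp_of_sam.size();
  ScanResult best{0.0, 0, 0, false};
  if (N < 2) return best;
  const int G = N / grid_step;                 // grid: g, 2g, ..., G*g
  if (G < 1) return best;
  std::vector<long long> cnt((size_t)G + 1, 0);
  const double half = N / 2.0;
  int i = 0;
  for (int gi = 1; gi <= G; ++gi) {
    const int rs = gi * grid_step;
    for (; i < rs; ++i) {
      // bin by propensity rank; ranks beyond the last grid point never fall
      // inside any scanned top-r_t list
      const int b = (tp_of_sam[i] + grid_step - 1) / grid_step;
      if (b <= G) cnt[b]++;
    }
    if (rs >= N) break;                        // zero margin at r_s = N
    const double Ds = (double)rs * (double)(N - rs);
    // admissible r_t window for this r_s (computed once, no per-cell division):
    //   E_a = rs rt / N         > min_expected   (overlap cell, strict)
    //   E_b = rs (N - rt) / N  >= min_cell
    //   E_c = (N - rs) rt / N  >= min_cell
    //   E_d = (N-rs)(N-rt) / N >= min_cell
    double rt_lo = min_expected * (double)N / (double)rs;          // exclusive
    const double rt_lo2 = min_cell * (double)N / (double)(N - rs); // inclusive
    double rt_hi = (double)N - min_cell * (double)N / (double)rs;
    const double rt_hi2 = (double)N -
      min_cell * (double)N / (double)(N - rs);
    if (rt_hi2 < rt_hi) rt_hi = rt_hi2;
    long long a = 0;
    for (int gj = 1; gj <= G; ++gj) {
      a += cnt[gj];
      const int rt = gj * grid_step;
      if (rt >= N) break;
      if ((double)rt <= rt_lo || (double)rt < rt_lo2 ||
          (double)rt > rt_hi) continue;
      const double t = (double)a * N - (double)rs * (double)rt;  // ad - bc
      if (t <= 0) continue;                    // observed <= expected
      best.admissible = true;
      const double u = t - half;               // Yates continuity correction
      if (u <= 0) continue;
      const double chi2 = (double)N * u * u /
        (Ds * (double)rt * (double)(N - rt));
      if (chi2 > best.chi2) {
        best.chi2 = chi2; best.rs = rs; best.rt = rt;
      }
    }
  }
  return best;
}

struct RemovalResult {
  double chi2; int rs, rt, k;
  double base_chi2; int base_rs, base_rt;
  bool admissible;
};

// Re-runs the grid scan after deleting the top-k SAM-ranked genes (k = 0,
// step, 2*step, ... <= max_depth); the final statistic is the max over depths.
// max_depth < 0 requests the default cap: the base maximizer's r_s.
static RemovalResult removal_stat(const std::vector<int>& tp_of_sam,
                                  int grid_step, double min_expected,
                                  double min_cell, int removal_step,
                                  int max_depth) {
  const int N = (int)tp_of_sam.size();
  ScanResult base = scan_grid(tp_of_sam, grid_step, min_expected, min_cell);
  RemovalResult out{base.chi2, base.rs, base.rt, 0,
                    base.chi2, base.rs, base.rt, base.admissible};
  int cap = (max_depth < 0) ? base.rs : max_depth;
  const int cap_lim = N - (int)(4.0 * min_expected);
  if (cap > cap_lim) cap = std::max(0, cap_lim);
  if (cap <= 0) return out;
  int step = removal_step;
  if (step <= 0) step = std::max(1, (cap + 2) / 3);   // default: <= 3 extra depths
  std::vector<int> cum((size_t)N + 1, 0);
  std::vector<int> reduced;
  reduced.reserve((size_t)N);
  for (int k = step; k <= cap; k += step) {
    // cum[t] = number of removed genes with propensity rank <= t
    std::fill(cum.begin(), cum.end(), 0);
    for (int j = 0; j < k; ++j) cum[tp_of_sam[j]] = 1;
    for (int t = 1; t <= N; ++t) cum[t] += cum[t - 1];
    reduced.clear();
    for (int j = k; j < N; ++j)
      reduced.push_back(tp_of_sam[j] - cum[tp_of_sam[j]]);
    ScanResult s = scan_grid(reduced, grid_step, min_expected, min_cell);
    if (s.admissible) out.admissible = true;
    if (s.chi2 > out.chi2) {
      out.chi2 = s.chi2; out.rs = s.rs; out.rt = s.rt; out.k = k;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_max_chisq(IntegerVector tp_of_sam, int grid_step,
                   double min_expected, double min_cell) {
  std::vector<int> v(tp_of_sam.begin(), tp_of_sam.end());
  ScanResult s = scan_grid(v, grid_step, min_expected, min_cell);
  return List::create(_["chi2"] = s.chi2, _["r_s"] = s.rs, _["r_t"] = s.rt,
                      _["admissible"] = s.admissible);
}

// [[Rcpp::export]]
List cpp_removal_stat(IntegerVector tp_of_sam, int grid_step,
                      double min_expected, double min_cell,
                      int removal_step, int max_depth) {
  std::vector<int> v(tp_of_sam.begin(), tp_of_sam.end());
  RemovalResult r = removal_stat(v, grid_step, min_expected, min_cell,
                                 removal_step, max_depth);
  return List::create(_["chi2"] = r.chi2, _["r_s"] = r.rs, _["r_t"] = r.rt,
                      _["removal_depth"] = r.k,
                      _["base_chi2"] = r.base_chi2, _["base_r_s"] = r.base_rs,
                      _["base_r_t"] = r.base_rt, _["admissible"] = r.admissible);
}

// Permutation null of the full statistic: the propensity ordering is permuted
// uniformly relative to the SAM ordering and the identical scan (constraints
// plus removal schedule) is applied, so observed and null statistics are
// exchangeable. RNG is a seeded mt19937, independent of R's RNG state.
// [[Rcpp::export]]
NumericVector cpp_null_stats(int N, int n_perm, int grid_step,
                             double min_expected, double min_cell,
                             int removal_step, int max_depth, int seed,
                             bool use_removal) {
  NumericVector out(n_perm);
  std::mt19937 rng((unsigned int)seed);
  std::vector<int> perm((size_t)N);
  for (int i = 0; i < N; ++i) perm[i] = i + 1;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = N - 1; i > 0; --i) {     // Fisher-Yates
      std::uniform_int_distribution<int> d(0, i);
      std::swap(perm[i], perm[d(rng)]);
    }
    if (use_removal) {
      RemovalResult r = removal_stat(perm, grid_step, min_expected,
                                     min_cell, removal_step, max_depth);
      out[p] = r.chi2;
    } else {
      ScanResult s = scan_grid(perm, grid_step, min_expected, min_cell);
      out[p] = s.chi2;
    }
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
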