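#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// MATCH-style scoring: at each offset the information-weighted score is
//   S = sum_i I(i) * f(i, b_i)
// and the matrix similarity score rescales it between the worst and best
// attainable scores, MSS = (S - Smin) / (Smax - Smin); the core similarity
// score does the same over the 5-position core block. N bases contribute the
// position's minimum weight, so masked sequence degrades scores rather than
// invalidating the window. The minus strand is scanned with the
// reverse-complemented weight matrix so a hit at offset o means the reverse
// complement of seq[o .. o+L-1] matches the motif.
//
// Sequences are encoded 0=A, 1=C, 2=G, 3=T, 4=N. The weight matrix w is
// 4 x L with w(b, i) = I(i) * f(i, b).

struct PwmView {
  std::vector<double> w;      // 5 x L: rows A,C,G,T,N(min)
  std::vector<double> wmin, wmax;
  double smin, smax, cmin, cmax;
  int L, core;
};

static PwmView make_view(const NumericMatrix& w, int core_start) {
  PwmView v;
  v.L = w.ncol();
  v.core = core_start;
  v.w.resize((size_t)5 * v.L);
  v.wmin.resize(v.L);
  v.wmax.resize(v.L);
  for (int i = 0; i < v.L; ++i) {
    double mn = w(0, i), mx = w(0, i);
    for (int b = 0; b < 4; ++b) {
      v.w[(size_t)5 * i + b] = w(b, i);
      mn = std::min(mn, w(b, i));
      mx = std::max(mx, w(b, i));
    }
    v.w[(size_t)5 * i + 4] = mn;            // N base
    v.wmin[i] = mn;
    v.wmax[i] = mx;
  }
  v.smin = v.smax = v.cmin = v.cmax = 0.0;
  for (int i = 0; i < v.L; ++i) {
    v.smin += v.wmin[i]; v.smax += v.wmax[i];
    if (i >= v.core && i < v.core + 5) { v.cmin += v.wmin[i]; v.cmax += v.wmax[i]; }
  }
  return v;
}

static inline double rescale(double s, double lo, double hi) {
  return (hi > lo) ? (s - lo) / (hi - lo) : 1.0;
}

// Reverse-complemented view: w'(b, i) = w(comp(b), L-1-i); core block mirrors.
static PwmView revcomp_view(const NumericMatrix& w, int core_start) {
  const int L = w.ncol();
  NumericMatrix wr(4, L);
  static const int comp[4] = {3, 2, 1, 0};
  for (int i = 0; i < L; ++i)
    for (int b = 0; b < 4; ++b)
      wr(b, i) = w(comp[b], L - 1 - i);
  return make_view(wr, L - 5 - core_start);
}

static void scan_one(const IntegerVector& seq, const PwmView& v, char strand,
                     double mss_cut, double css_cut,
                     std::vector<int>* offs, std::vector<char>* strands,
                     std::vector<double>* mss_out, std::vector<double>* css_out,
                     int* count) {
  const int n = seq.size();
  const int L = v.L;
  for (int o = 0; o + L <= n; ++o) {
    double s = 0.0, cs = 0.0;
    for (int i = 0; i < L; ++i) {
      int b = seq[o + i];
      if (b < 0 || b > 4) b = 4;
      const double wv = v.w[(size_t)5 * i + b];
      s += wv;
      if (i >= v.core && i < v.core + 5) cs += wv;
    }
    const double mss = rescale(s, v.smin, v.smax);
    const double css = rescale(cs, v.cmin, v.cmax);
    if (mss >= mss_cut && css >= css_cut) {
      if (count) (*count)++;
      if (offs) {
        offs->push_back(o);
        strands->push_back(strand);
        mss_out->push_back(mss);
        css_out->push_back(css);
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_pwm_hits(IntegerVector seq, NumericMatrix w, int core_start,
                       double mss_cut, double css_cut, bool both_strands) {
  PwmView fwd = make_view(w, core_start);
  std::vector<int> offs;
  std::vector<char> strands;
  std::vector<double> mss, css;
  scan_one(seq, fwd, '+', mss_cut, css_cut, &offs, &strands, &mss, &css, NULL);
  if (both_strands) {
    PwmView rev = revcomp_view(w, core_start);
    scan_one(seq, rev, '-', mss_cut, css_cut, &offs, &strands, &mss, &css, NULL);
  }
  const int nh = (int)offs.size();
  CharacterVector sv(nh);
  for (int i = 0; i < nh; ++i) sv[i] = (strands[i] == '+') ? "+" : "-";
  return DataFrame::create(_["offset"] = wrap(offs), _["strand"] = sv,
                           _["mss"] = wrap(mss), _["css"] = wrap(css),
                           _["stringsAsFactors"] = false);
}

// Per-promoter hit counts for one matrix over a whole promoter set.
// [[Rcpp::export]]
IntegerVector cpp_pwm_count_many(List seqs, NumericMatrix w, int core_start,
                                 double mss_cut, double css_cut,
                                 bool both_strands) {
  PwmView fwd = make_view(w, core_start);
  PwmView rev = revcomp_view(w, core_start);
  const int n = seqs.size();
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) {
    IntegerVector seq = seqs[j];
    int count = 0;
    scan_one(seq, fwd, '+', mss_cut, css_cut, NULL, NULL, NULL, NULL, &count);
    if (both_strands)
      scan_one(seq, rev, '-', mss_cut, css_cut, NULL, NULL, NULL, NULL, &count);
    out[j] = count;
    if (j % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// MSS/CSS at a single offset on the + strand (used by tests and by the
// rejection sampler that plants detectable sites).
// [[Rcpp::export]]
NumericVector cpp_pwm_score_at(IntegerVector seq, NumericMatrix w,
                               int core_start, int offset) {
  PwmView v = make_view(w, core_start);
  double s = 0.0, cs = 0.0;
  for (int i = 0; i < v.L; ++i) {
    int b = seq[offset + i];
    if (b < 0 || b > 4) b = 4;
    const double wv = v.w[(size_t)5 * i + b];
    s += wv;
    if (i >= v.core && i < v.core + 5) cs += wv;
  }
  return NumericVector::create(_["mss"] = rescale(s, v.smin, v.smax),
                               _["css"] = rescale(cs, v.cmin, v.cmax));
}
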