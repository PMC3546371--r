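// Computational kernel: per-permutation test statistics and the
// raw/step-down extremeness counts of the Westfall-Young maxT procedure.
//
// The expression matrix arrives TRANSPOSED (n samples x m genes) so that
// each gene's values are contiguous in memory.  Missing values are NA.
// All six statistics share one dispatcher so the observed labelling and
// every permuted labelling go through identical code.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

enum TestCode {
  TEST_T = 0,         // Welch two-sample t (unequal variances)
  TEST_T_EQUALVAR = 1,
  TEST_WILCOXON = 2,  // standardized rank sum (rows pre-ranked in R)
  TEST_F = 3,         // one-way ANOVA F
  TEST_PAIRT = 4,
  TEST_BLOCKF = 5     // two-way ANOVA without replication
};

struct Workspace {
  std::vector<double> gsum;   // per-group sums (f)
  std::vector<int>    gcnt;
  std::vector<double> gmean;
  std::vector<double> diffs;  // paired differences
  std::vector<double> tsum;   // per-treatment sums (blockf)
  std::vector<char>   complete; // complete-block flags
};

// Two-sample t; two-pass moments, sample variances with n-1 denominators.
double two_sample_t(const double* x, const int* lab, int n, bool welch) {
  double s0 = 0.0, s1 = 0.0;
  int n0 = 0, n1 = 0;
  for (int j = 0; j < n; ++j) {
    double v = x[j];
    if (ISNAN(v)) continue;
    if (lab[j] == 0) { s0 += v; ++n0; } else { s1 += v; ++n1; }
  }
  if (n0 < 2 || n1 < 2) return NA_REAL;
  double m0 = s0 / n0, m1 = s1 / n1, ss0 = 0.0, ss1 = 0.0;
  for (int j = 0; j < n; ++j) {
    double v = x[j];
    if (ISNAN(v)) continue;
    double d;
    if (lab[j] == 0) { d = v - m0; ss0 += d * d; }
    else             { d = v - m1; ss1 += d * d; }
  }
  double denom;
  if (welch) {
    denom = std::sqrt(ss0 / ((double)(n0 - 1) * n0) +
                      ss1 / ((double)(n1 - 1) * n1));
  } else {
    double sp2 = (ss0 + ss1) / (double)(n0 + n1 - 2);
    denom = std::sqrt(sp2 * (1.0 / n0 + 1.0 / n1));
  }
  if (!(denom > 0.0) || !R_finite(denom)) return NA_REAL;
  return (m0 - m1) / denom;
}

// Standardized Wilcoxon rank sum.  x holds midranks of the gene's
// non-missing values (computed once per gene in R; ranks do not depend
// on the labelling).  No tie correction in the variance term.
double wilcoxon_z(const double* x, const int* lab, int n) {
  double W = 0.0;
  int n0 = 0, n1 = 0;
  for (int j = 0; j < n; ++j) {
    double v = x[j];
    if (ISNAN(v)) continue;
    if (lab[j] == 0) { W += v; ++n0; } else { ++n1; }
  }
  if (n0 == 0 || n1 == 0) return NA_REAL;
  double N = (double)(n0 + n1);
  double E = n0 * (N + 1.0) / 2.0;
  double V = (double)n0 * n1 * (N + 1.0) / 12.0;
  if (!(V > 0.0)) return NA_REAL;
  return (W - E) / std::sqrt(V);
}

// One-way F over the groups actually represented (>=1 non-missing value).
double oneway_f(const double* x, const int* lab, int n, int k, Workspace& w) {
  for (int c = 0; c < k; ++c) { w.gsum[c] = 0.0; w.gcnt[c] = 0; }
  double total = 0.0;
  int N = 0;
  for (int j = 0; j < n; ++j) {
    double v = x[j];
    if (ISNAN(v)) continue;
    w.gsum[lab[j]] += v;
    ++w.gcnt[lab[j]];
    total += v;
    ++N;
  }
  int keff = 0;
  for (int c = 0; c < k; ++c) if (w.gcnt[c] > 0) ++keff;
  if (keff < 2 || N <= keff) return NA_REAL;
  double grand = total / N, ssb = 0.0, ssw = 0.0;
  for (int c = 0; c < k; ++c) {
    if (w.gcnt[c] == 0) { w.gmean[c] = 0.0; continue; }
    w.gmean[c] = w.gsum[c] / w.gcnt[c];
    double d = w.gmean[c] - grand;
    ssb += w.gcnt[c] * d * d;
  }
  for (int j = 0; j < n; ++j) {
    double v = x[j];
    if (ISNAN(v)) continue;
    double d = v - w.gmean[lab[j]];
    ssw += d * d;
  }
  if (!(ssw > 0.0)) return NA_REAL;
  return (ssb / (keff - 1)) / (ssw / (N - keff));
}

// Paired t over complete pairs; pairs are consecutive column pairs, the
// member labelled 1 is the treated one.
double paired_t_stat(const double* x, const int* lab, int n, Workspace& w) {
  int np = n / 2, cnt = 0;
  double sum = 0.0;
  for (int p = 0; p < np; ++p) {
    double a = x[2 * p], b = x[2 * p + 1];
    if (ISNAN(a) || ISNAN(b)) continue;
    double d = (lab[2 * p] == 1) ? (a - b) : (b - a);
    w.diffs[cnt++] = d;
    sum += d;
  }
  if (cnt < 2) return NA_REAL;
  double mean = sum / cnt, ss = 0.0;
  for (int i = 0; i < cnt; ++i) {
    double d = w.diffs[i] - mean;
    ss += d * d;
  }
  double sd = std::sqrt(ss / (cnt - 1));
  if (!(sd > 0.0)) return NA_REAL;
  return mean / (sd / std::sqrt((double)cnt));
}

// Randomized-block F (two-way ANOVA without replication) over complete
// blocks; blocks are consecutive runs of k columns, labels give the
// treatment of each column.
double block_f_stat(const double* x, const int* lab, int n, int k, Workspace& w) {
  int nb = n / k, b = 0;
  double total = 0.0;
  for (int c = 0; c < k; ++c) w.tsum[c] = 0.0;
  for (int j = 0; j < nb; ++j) {
    bool ok = true;
    double bs = 0.0;
    for (int c = 0; c < k; ++c) {
      double v = x[j * k + c];
      if (ISNAN(v)) { ok = false; break; }
      bs += v;
    }
    w.complete[j] = ok;
    if (ok) { ++b; total += bs; }
  }
  if (b < 2) return NA_REAL;
  double N = (double)b * k, grand = total / N;
  double sstot = 0.0, ssblock = 0.0, sstr = 0.0;
  for (int j = 0; j < nb; ++j) {
    if (!w.complete[j]) continue;
    double bs = 0.0;
    for (int c = 0; c < k; ++c) {
      double v = x[j * k + c];
      bs += v;
      double d = v - grand;
      sstot += d * d;
      w.tsum[lab[j * k + c]] += v;
    }
    double d = bs / k - grand;
    ssblock += k * d * d;
  }
  for (int c = 0; c < k; ++c) {
    double d = w.tsum[c] / b - grand;
    sstr += b * d * d;
    w.tsum[c] = 0.0;
  }
  double ssres = sstot - ssblock - sstr;
  if (!(ssres > 0.0)) return NA_REAL;
  return (sstr / (k - 1)) / (ssres / ((double)(k - 1) * (b - 1)));
}

inline double one_stat(const double* x, const int* lab, int n, int test,
                       int k, Workspace& w) {
  switch (test) {
    case TEST_T:          return two_sample_t(x, lab, n, true);
    case TEST_T_EQUALVAR: return two_sample_t(x, lab, n, false);
    case TEST_WILCOXON:   return wilcoxon_z(x, lab, n);
    case TEST_F:          return oneway_f(x, lab, n, k, w);
    case TEST_PAIRT:      return paired_t_stat(x, lab, n, w);
    case TEST_BLOCKF:     return block_f_stat(x, lab, n, k, w);
  }
  return NA_REAL;
}

void init_workspace(Workspace& w, int n, int k) {
  w.gsum.assign(k, 0.0);
  w.gcnt.assign(k, 0);
  w.gmean.assign(k, 0.0);
  w.diffs.assign(n / 2 + 1, 0.0);
  w.tsum.assign(k, 0.0);
  w.complete.assign(k > 0 ? n / k + 1 : 1, 0);
}

// side: 0 = abs, 1 = upper, 2 = lower; undefined -> -Inf (never extreme)
inline double extremeness(double s, int side) {
  if (ISNAN(s)) return NEG_INF;
  switch (side) {
    case 0:  return std::fabs(s);
    case 1:  return s;
    default: return -s;
  }
}

} // namespace

// Signed statistics for one labelling; NA where undefined.
// [[Rcpp::export]]
NumericVector stat_vector_cpp(NumericMatrix Xt, IntegerVector lab,
                              int test, int k) {
  int n = Xt.nrow(), m = Xt.ncol();
  if (lab.size() != n) stop("label vector length does not match sample count");
  NumericVector out(m);
  Workspace w;
  init_workspace(w, n, k);
  const double* xp = REAL(Xt);
  const int* lp = INTEGER(lab);
  for (int g = 0; g < m; ++g)
    out[g] = one_stat(xp + (size_t)g * n, lp, n, test, k, w);
  return out;
}

// Accumulate raw and successive-maxima extremeness counts over a chunk of
// labellings (columns of `labels`).  Counts are exact integers kept in
// doubles; their reduction across chunks is therefore order-independent.
// [[Rcpp::export]]
List maxt_kernel_cpp(NumericMatrix Xt, IntegerMatrix labels, int test, int k,
                     int side, IntegerVector ordering0, int defined_count,
                     NumericVector obs_ext, double eps) {
  int n = Xt.nrow(), m = Xt.ncol(), nperm = labels.ncol();
  if (labels.nrow() != n) stop("labelling matrix row count does not match sample count");
  if (obs_ext.size() != m) stop("observed statistic length does not match gene count");
  NumericVector raw(m), adj(m);
  std::vector<double> ext(m);
  Workspace w;
  init_workspace(w, n, k);
  const double* xp = REAL(Xt);
  const int* lmat = INTEGER(labels);
  const int* ord = INTEGER(ordering0);
  const double* oe = REAL(obs_ext);
  for (int p = 0; p < nperm; ++p) {
    const int* lab = lmat + (size_t)p * n;
    for (int g = 0; g < m; ++g)
      ext[g] = extremeness(one_stat(xp + (size_t)g * n, lab, n, test, k, w),
                           side);
    for (int g = 0; g < m; ++g)
      if (!ISNAN(oe[g]) && ext[g] >= oe[g] - eps) raw[g] += 1.0;
    double run = NEG_INF;
    for (int r = defined_count - 1; r >= 0; --r) {
      int g = ord[r];
      if (ext[g] > run) run = ext[g];
      if (run >= oe[g] - eps) adj[r] += 1.0;
    }
  }
  return List::create(_["raw_counts"] = raw,
                      _["adj_counts"] = adj,
                      _["processed"] = (double)nperm);
}
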