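#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pooled-variance (Student) two-sample t from sufficient statistics,
// signed high minus low. Undefined (NA) when either group has < 2
// members or when the pooled variance is zero with unequal means; equal
// groups with identical values give t = 0.
static double pooled_t(double n1, double s1, double ss1,
                       double n0, double s0, double ss0) {
  if (n1 < 2.0 || n0 < 2.0) return NA_REAL;
  double m1 = s1 / n1, m0 = s0 / n0;
  double sp2 = (ss1 - n1 * m1 * m1 + ss0 - n0 * m0 * m0) / (n1 + n0 - 2.0);
  if (sp2 <= 0.0) {
    if (m1 == m0) return 0.0;
    return NA_REAL;
  }
  return (m1 - m0) / std::sqrt(sp2 * (1.0 / n1 + 1.0 / n0));
}

// Cross-validated QMDR evaluation of SNP pairs.
//
// G: n x m genotype matrix (0/1/2, NA allowed); pairs: P x 2 matrix of
// 0-based column indices; y: trait; fold: 0..K-1 per sample;
// empty_low: 1 = held-out members of training-empty cells join the LOW
// pool at testing time, 0 = they are dropped.
//
// Returns list(train = P x K training t, test = P x K testing t).
// [[Rcpp::export]]
List qmdr_core_cpp(const IntegerMatrix& G, const IntegerMatrix& pairs,
                   const NumericVector& y, const IntegerVector& fold,
                   int K, int empty_low) {
  const int n = G.nrow();
  const int P = pairs.nrow();
  if (y.size() != n || fold.size() != n)
    stop("trait/fold length must match genotype rows");
  NumericMatrix train(P, K), test(P, K);
  std::vector<double> cnt(9 * K), sum(9 * K), ss(9 * K);
  for (int p = 0; p < P; ++p) {
    const int c1 = pairs(p, 0), c2 = pairs(p, 1);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(ss.begin(), ss.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int g1 = G(i, c1), g2 = G(i, c2);
      if (g1 == NA_INTEGER || g2 == NA_INTEGER) continue;
      const int b = 9 * fold[i] + 3 * g1 + g2;
      const double yi = y[i];
      cnt[b] += 1.0; sum[b] += yi; ss[b] += yi * yi;
    }
    double cntC[9], sumC[9], ssC[9];
    for (int c = 0; c < 9; ++c) { cntC[c] = sumC[c] = ssC[c] = 0.0; }
    for (int f = 0; f < K; ++f)
      for (int c = 0; c < 9; ++c) {
        cntC[c] += cnt[9 * f + c];
        sumC[c] += sum[9 * f + c];
        ssC[c] += ss[9 * f + c];
      }
    for (int f = 0; f < K; ++f) {
      double tn = 0.0, tsum = 0.0;
      double tc[9], tsm[9], tss[9];
      for (int c = 0; c < 9; ++c) {
        tc[c] = cntC[c] - cnt[9 * f + c];
        tsm[c] = sumC[c] - sum[9 * f + c];
        tss[c] = ssC[c] - ss[9 * f + c];
        tn += tc[c]; tsum += tsm[c];
      }
      if (tn < 1.0) { train(p, f) = NA_REAL; test(p, f) = NA_REAL; continue; }
      const double grand = tsum / tn;
      bool high[9];
      for (int c = 0; c < 9; ++c)
        high[c] = (tc[c] > 0.0) && (tsm[c] / tc[c] > grand);
      // training statistic: pooled high vs low over non-empty cells
      double n1 = 0, s1 = 0, q1 = 0, n0 = 0, s0 = 0, q0 = 0;
      for (int c = 0; c < 9; ++c) {
        if (tc[c] == 0.0) continue;
        if (high[c]) { n1 += tc[c]; s1 += tsm[c]; q1 += tss[c]; }
        else { n0 += tc[c]; s0 += tsm[c]; q0 += tss[c]; }
      }
      train(p, f) = pooled_t(n1, s1, q1, n0, s0, q0);
      // testing statistic on the held-out fold with training labels
      n1 = s1 = q1 = n0 = s0 = q0 = 0.0;
      for (int c = 0; c < 9; ++c) {
        const int b = 9 * f + c;
        if (cnt[b] == 0.0) continue;
        if (high[c]) { n1 += cnt[b]; s1 += sum[b]; q1 += ss[b]; }
        else if (tc[c] > 0.0 || empty_low) {
          n0 += cnt[b]; s0 += sum[b]; q0 += ss[b];
        }
      }
      test(p, f) = pooled_t(n1, s1, q1, n0, s0, q0);
    }
  }
  return List::create(Named("train") = train, Named("test") = test);
}
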