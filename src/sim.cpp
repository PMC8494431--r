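#include <Rcpp.h>
using namespace Rcpp;

// One-pass genotype generation for the synthetic-cohort module.
//
// q0 / q01 are m x n_subpop matrices of cumulative Hardy-Weinberg
// thresholds per subpopulation: P(x=0) and P(x<=1). p2 holds the
// inside-tract probability of the allele-b homozygote (the allele-b
// frequency). Tracts are given as 1-based row ranges per sample and
// overwrite the HWE draw with a homozygote whose allele is chosen by
// frequency. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".cpp_sim_genotypes")]]
IntegerMatrix cpp_sim_genotypes(NumericMatrix q0, NumericMatrix q01,
                                NumericMatrix p2, IntegerVector subpop,
                                IntegerVector tr_sample, IntegerVector tr_lo,
                                IntegerVector tr_hi) {
  int m = q0.nrow();
  int n = subpop.size();
  IntegerMatrix out(n, m);  // samples x variants
  RNGScope scope;
  int* o = out.begin();

  for (int j = 0; j < m; ++j) {
    double c0a = q0(j, 0), c0b = q0(j, 1);
    double c1a = q01(j, 0), c1b = q01(j, 1);
    int* col = o + static_cast<size_t>(j) * n;
    for (int s = 0; s < n; ++s) {
      double u = unif_rand();
      if (subpop[s] == 1) {
        col[s] = (u > c0a) + (u > c1a);
      } else {
        col[s] = (u > c0b) + (u > c1b);
      }
    }
  }
  for (int t = 0; t < tr_sample.size(); ++t) {
    int s = tr_sample[t] - 1;
    int k = subpop[s] - 1;
    const double* p = &p2(0, k);
    for (int j = tr_lo[t] - 1; j <= tr_hi[t] - 1; ++j) {
      o[static_cast<size_t>(j) * n + s] = (unif_rand() < p[j]) ? 2 : 0;
    }
  }
  return out;
}

// fast validation: every call in {0, 1, 2, NA}
// [[Rcpp::export(name = ".cpp_calls_valid")]]
bool cpp_calls_valid(IntegerMatrix calls) {
  for (int* it = calls.begin(); it != calls.end(); ++it) {
    int x = *it;
    if (x != NA_INTEGER && (x < 0 || x > 2)) return false;
  }
  return true;
}

// Per-sample F3 and missing-call counts in one pass over a
// samples x variants call matrix. `use` marks variants with usable
// frequencies (0 < p < 1); terms follow the correlation-between-uniting-
// gametes estimator.
// [[Rcpp::export(name = ".cpp_f3_profile")]]
List cpp_f3_profile(IntegerMatrix calls, NumericVector p,
                    LogicalVector use) {
  int n = calls.nrow();
  int m = calls.ncol();
  NumericVector sum(n, 0.0);
  IntegerVector cnt(n, 0);
  IntegerVector n_miss(n, 0);

  for (int j = 0; j < m; ++j) {
    const int* col = &calls(0, j);
    bool usable = use[j];
    double pj = p[j], a = 1.0 + 2.0 * pj, b = 2.0 * pj * pj,
           d = 2.0 * pj * (1.0 - pj);
    for (int i = 0; i < n; ++i) {
      int x = col[i];
      if (x == NA_INTEGER) {
        n_miss[i] += 1;
      } else if (usable) {
        double xd = x;
        sum[i] += (xd * xd - a * xd + b) / d;
        cnt[i] += 1;
      }
    }
  }
  NumericVector f3(n);
  for (int i = 0; i < n; ++i) {
    f3[i] = cnt[i] > 0 ? sum[i] / cnt[i] : NA_REAL;
  }
  return List::create(_["f3"] = f3, _["n_used"] = cnt,
                      _["n_missing"] = n_miss);
}
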