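#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Two-step sliding-window ROH detection.
//
// Step 1 (flagging): every contiguous window of `window_snps` SNP indices
// that lies fully inside the chromosome is classified as homozygous iff it
// holds at most `window_max_het` heterozygous and `window_max_missing`
// missing calls. A SNP is flagged when the fraction of homozygous windows
// among the windows covering it reaches `hit_threshold`. Chromosomes shorter
// than the window are handled as a single truncated window so edge SNPs stay
// reachable.
//
// Step 2 (run building): maximal stretches of flagged SNPs are split at
// inter-SNP gaps exceeding `max_gap_bp`, trimmed inward to the nearest
// non-missing homozygous call, and kept only if they satisfy the minimum
// SNP count, minimum span and average SNP density requirements.

static std::vector<char> flag_chromosome(const int* g, int n, int W,
                                         int maxHet, int maxMiss, double thr) {
  std::vector<char> flags(n, 0);
  if (n <= 0) return flags;
  int eff = std::min(W, n);
  int nw = n - eff + 1;

  std::vector<int> het(n + 1, 0), mis(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    het[i + 1] = het[i] + (g[i] != NA_INTEGER && g[i] == 1 ? 1 : 0);
    mis[i + 1] = mis[i] + (g[i] == NA_INTEGER ? 1 : 0);
  }
  std::vector<int> prefHom(nw + 1, 0);
  for (int w = 0; w < nw; ++w) {
    int h = het[w + eff] - het[w];
    int m = mis[w + eff] - mis[w];
    prefHom[w + 1] = prefHom[w] + ((h <= maxHet && m <= maxMiss) ? 1 : 0);
  }
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - eff + 1);
    int hi = std::min(i, nw - 1);
    if (hi < lo) lo = hi;  // defensive; cannot trigger for nw >= 1
    int cov = hi - lo + 1;
    int hom = prefHom[hi + 1] - prefHom[lo];
    if (static_cast<double>(hom) / cov >= thr) flags[i] = 1;
  }
  return flags;
}

struct Run { int start, end; };  // 0-based inclusive indices

static void emit_runs(const int* g, const int* pos, int n,
                      const std::vector<char>& flags,
                      double max_gap_bp, int min_snps, double min_kb,
                      double density_kb_per_snp, std::vector<Run>& out) {
  int i = 0;
  while (i < n) {
    if (!flags[i]) { ++i; continue; }
    int j = i;
    while (j + 1 < n && flags[j + 1]) ++j;
    // split [i, j] at gaps exceeding max_gap_bp
    int s = i;
    for (int k = i; k <= j; ++k) {
      bool last = (k == j);
      bool split = !last &&
        (static_cast<double>(pos[k + 1]) - pos[k]) > max_gap_bp;
      if (last || split) {
        int a = s, b = k;
        // trim ends to non-missing homozygous genotypes
        while (a <= b && !(g[a] != NA_INTEGER && (g[a] == 0 || g[a] == 2))) ++a;
        while (b >= a && !(g[b] != NA_INTEGER && (g[b] == 0 || g[b] == 2))) --b;
        if (a <= b) {
          int nsnp = b - a + 1;
          double len_kb = (static_cast<double>(pos[b]) - pos[a] + 1.0) / 1000.0;
          if (nsnp >= min_snps && len_kb >= min_kb &&
              len_kb / nsnp <= density_kb_per_snp) {
            out.push_back({a, b});
          }
        }
        s = k + 1;
      }
    }
    i = j + 1;
  }
}

// [[Rcpp::export(name = ".cpp_flag_snps")]]
LogicalVector cpp_flag_snps(IntegerVector geno, int window_snps,
                            int window_max_het, int window_max_missing,
                            double hit_threshold) {
  int n = geno.size();
  std::vector<char> f = flag_chromosome(geno.begin(), n, window_snps,
                                        window_max_het, window_max_missing,
                                        hit_threshold);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = f[i] != 0;
  return out;
}

// [[Rcpp::export(name = ".cpp_call_one")]]
IntegerMatrix cpp_call_one(IntegerVector geno, IntegerVector pos,
                           int window_snps, int window_max_het,
                           int window_max_missing, double hit_threshold,
                           int min_snps, double min_kb,
                           double density_kb_per_snp, double max_gap_kb) {
  int n = geno.size();
  std::vector<char> f = flag_chromosome(geno.begin(), n, window_snps,
                                        window_max_het, window_max_missing,
                                        hit_threshold);
  std::vector<Run> runs;
  emit_runs(geno.begin(), pos.begin(), n, f, max_gap_kb * 1000.0, min_snps,
            min_kb, density_kb_per_snp, runs);
  IntegerMatrix out(runs.size(), 3);
  for (size_t r = 0; r < runs.size(); ++r) {
    out(r, 0) = runs[r].start + 1;           // 1-based index
    out(r, 1) = runs[r].end + 1;
    out(r, 2) = runs[r].end - runs[r].start + 1;
  }
  return out;
}

// geno_t: variants x samples (column = one sample, contiguous);
// chrom_offsets: 0-based start offsets of each chromosome block plus a final
// sentinel equal to the number of variants.
// [[Rcpp::export(name = ".cpp_call_matrix")]]
DataFrame cpp_call_matrix(IntegerMatrix geno_t, IntegerVector pos,
                          IntegerVector chrom_offsets, int window_snps,
                          int window_max_het, int window_max_missing,
                          double hit_threshold, int min_snps, double min_kb,
                          double density_kb_per_snp, double max_gap_kb) {
  int n_samples = geno_t.ncol();
  int n_chrom = chrom_offsets.size() - 1;
  double max_gap_bp = max_gap_kb * 1000.0;
  std::vector<int> out_sample, out_start, out_end, out_nsnp;

  for (int s = 0; s < n_samples; ++s) {
    const int* col = &geno_t(0, s);
    for (int c = 0; c < n_chrom; ++c) {
      int off = chrom_offsets[c];
      int n = chrom_offsets[c + 1] - off;
      if (n <= 0) continue;
      std::vector<char> f = flag_chromosome(col + off, n, window_snps,
                                            window_max_het,
                                            window_max_missing,
                                            hit_threshold);
      std::vector<Run> runs;
      emit_runs(col + off, pos.begin() + off, n, f, max_gap_bp, min_snps,
                min_kb, density_kb_per_snp, runs);
      for (size_t r = 0; r < runs.size(); ++r) {
        out_sample.push_back(s + 1);
        out_start.push_back(off + runs[r].start + 1);
        out_end.push_back(off + runs[r].end + 1);
        out_nsnp.push_back(runs[r].end - runs[r].start + 1);
      }
    }
  }
  return DataFrame::create(_["sample"] = out_sample,
                           _["start_idx"] = out_start,
                           _["end_idx"] = out_end,
                           _["n_snps"] = out_nsnp);
}
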