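#' Sliding-window ROH caller parameters
#'
#' Defaults reproduce the `ROH_1.5Mb`-style calling used for megabase-scale
#' autozygosity on SNP arrays: 50-SNP sliding windows allowing 1 heterozygote
#' and 5 missing calls, a 5% homozygous-window hit threshold, and run-level
#' requirements of at least 100 consecutive SNPs spanning at least 1500 kb,
#' with on average one SNP per 50 kb and no inter-SNP gap above 5000 kb.
#'
#' @param window_snps Window size in SNPs.
#' @param window_max_het Maximum heterozygous calls per homozygous window.
#' @param window_max_missing Maximum missing calls per homozygous window.
#' @param hit_threshold Fraction of covering windows that must be homozygous
#'   for a SNP to be flagged.
#' @param min_snps Minimum SNPs per emitted segment.
#' @param min_kb Minimum segment span in kb.
#' @param density_kb_per_snp Maximum average kb per SNP within a segment.
#' @param max_gap_kb Maximum gap between consecutive segment SNPs in kb.
#' @return A named list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, window_max_het = 1,
                       window_max_missing = 5, hit_threshold = 0.05,
                       min_snps = 100, min_kb = 1500,
                       density_kb_per_snp = 50, max_gap_kb = 5000) {
  p <- list(window_snps = window_snps, window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            hit_threshold = hit_threshold, min_snps = min_snps,
            min_kb = min_kb, density_kb_per_snp = density_kb_per_snp,
            max_gap_kb = max_gap_kb)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && length(x) == 1, TRUE)),
            window_snps >= 1, window_max_het >= 0, window_max_missing >= 0,
            hit_threshold > 0, hit_threshold <= 1,
            min_snps >= 1, min_kb > 0, density_kb_per_snp > 0, max_gap_kb > 0)
  structure(p, class = "roh_params")
}

#' Flag SNPs covered by homozygous sliding windows
#'
#' Step one of the two-step caller, for one sample on one chromosome. Every
#' contiguous `window_snps`-SNP index window fully inside the chromosome is
#' classified as homozygous iff it contains at most `window_max_het`
#' heterozygous and `window_max_missing` missing calls; a SNP is flagged when
#' the proportion of homozygous windows among those covering it reaches
#' `hit_threshold`. Near chromosome ends the denominator is the number of
#' existing windows, so edge SNPs remain reachable; a chromosome shorter than
#' one window is evaluated as a single truncated window.
#'
#' @param calls Integer vector of genotypes (0/1/2/`NA`) for one sample on
#'   one chromosome, in map order.
#' @param params A [roh_params()].
#' @return Logical vector of per-SNP flags.
#' @export
flag_homozygous_snps <- function(calls, params = roh_params()) {
  stopifnot(length(calls) >= 1)
  .cpp_flag_snps(as.integer(calls), params$window_snps, params$window_max_het,
                 params$window_max_missing, params$hit_threshold)
}

#' Call ROH segments for one sample on one chromosome
#'
#' Step two of the caller: maximal stretches of flagged SNPs become candidate
#' runs, each run is split wherever the bp gap between adjacent member SNPs
#' exceeds `max_gap_kb`, endpoints are trimmed inward to the nearest
#' non-missing homozygous genotype, and surviving runs must hold at least
#' `min_snps` SNPs, span at least `min_kb` kb (span = last − first SNP
#' position + 1) and average no more than `density_kb_per_snp` kb per SNP.
#'
#' @inheritParams flag_homozygous_snps
#' @param pos_bp Integer vector of 1-based SNP positions, strictly increasing.
#' @param chrom Chromosome number recorded in the output.
#' @param sample_id Sample identifier recorded in the output.
#' @return Tibble with columns `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_kb`; zero rows when no segment qualifies.
#' @export
call_roh_sample <- function(calls, pos_bp, params = roh_params(),
                            chrom = 1L, sample_id = "sample") {
  stopifnot(length(calls) == length(pos_bp), !is.unsorted(pos_bp, strictly = TRUE))
  m <- .cpp_call_one(as.integer(calls), as.integer(pos_bp),
                     params$window_snps, params$window_max_het,
                     params$window_max_missing, params$hit_threshold,
                     params$min_snps, params$min_kb,
                     params$density_kb_per_snp, params$max_gap_kb)
  segment_tibble(sample_id, chrom, pos_bp[m[, 1]], pos_bp[m[, 2]], m[, 3])
}

#' Call ROH segments across a cohort
#'
#' Runs the two-step caller for every sample on every chromosome of a
#' [geno_matrix()] and concatenates the results in stable
#' `(sample, chrom, start_bp)` order. Deterministic: permuting sample order
#' never changes any sample's segments.
#'
#' @param g A [geno_matrix()] (typically after QC).
#' @param params A [roh_params()].
#' @return Tibble of segments as in [call_roh_sample()].
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_params(n_case = 20, n_control = 20,
#'                                      m_snps = 3000,
#'                                      chrom_lengths_bp = 3e7), seed = 1)
#' segs <- call_roh(cohort$genotypes)
#' head(segs)
#' }
#' @export
call_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "geno_matrix"))
  if (n_samples(g) == 0 || n_variants(g) == 0) {
    return(segment_tibble(character(), integer(), integer(), integer(),
                          integer()))
  }
  chroms <- unique(g$variants$chrom)  # already sorted by geno_matrix()
  offsets <- c(0L, cumsum(as.integer(table(factor(g$variants$chrom,
                                                  levels = chroms)))))
  res <- .cpp_call_matrix(t(g$calls), as.integer(g$variants$pos_bp),
                          as.integer(offsets), params$window_snps,
                          params$window_max_het, params$window_max_missing,
                          params$hit_threshold, params$min_snps,
                          params$min_kb, params$density_kb_per_snp,
                          params$max_gap_kb)
  segs <- segment_tibble(
    g$samples$sample_id[res$sample],
    g$variants$chrom[res$start_idx],
    g$variants$pos_bp[res$start_idx],
    g$variants$pos_bp[res$end_idx],
    res$n_snps
  )
  dplyr::arrange(segs, match(.data$sample_id, g$samples$sample_id),
                 .data$chrom, .data$start_bp)
}

segment_tibble <- function(sample_id, chrom, start_bp, end_bp, n_snps) {
  tibble::tibble(
    sample_id = as.character(sample_id),
    chrom = as.integer(chrom),
    start_bp = as.integer(start_bp),
    end_bp = as.integer(end_bp),
    n_snps = as.integer(n_snps),
    length_kb = (as.numeric(end_bp) - as.numeric(start_bp) + 1) / 1000
  )
}

#' Write ROH segments to disk
#'
#' Tab-delimited `(sample_id, chrom, start_bp, end_bp, n_snps, length_kb)`,
#' or BED (0-based half-open, name = sample_id) when `format = "bed"`.
#'
#' @param segments Segment tibble from [call_roh()].
#' @param path Output file.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_segments <- function(segments, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(segments, path)
  } else {
    bed <- tibble::tibble(
      chrom = paste0("chr", segments$chrom),
      start = segments$start_bp - 1L,   # 0-based half-open
      end = segments$end_bp,
      name = segments$sample_id
    )
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}
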