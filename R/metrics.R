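#' Fraction of the autosome in runs of homozygosity (FROH)
#'
#' Sums segment lengths in bp over one sample's segments (optionally skipping
#' excluded chromosomes) and divides by the approximate autosome size of
#' 3e9 bp. The denominator is deliberately left unchanged under chromosome
#' exclusion so effect sizes stay comparable across sensitivity runs; set
#' `renormalize = TRUE` to shrink it by the excluded chromosomes' total
#' segment-bearing span instead (requires `chrom_lengths_bp`).
#'
#' @param segments Segment tibble for a single sample ([call_roh_sample()]
#'   output or rows of [call_roh()] output).
#' @param exclude_chroms Integer vector of chromosomes to exclude.
#' @param renormalize Renormalise the denominator under exclusion?
#' @param chrom_lengths_bp Named numeric vector of chromosome lengths, only
#'   used when `renormalize = TRUE`.
#' @return FROH as a unitless fraction (multiply by 100 to report percent).
#' @examples
#' segs <- tibble::tibble(sample_id = "s", chrom = 1L, start_bp = 1L,
#'                        end_bp = 18593000L, n_snps = 1000L,
#'                        length_kb = 18593)
#' 100 * froh(segs)  # 0.62% of the autosome
#' @export
froh <- function(segments, exclude_chroms = integer(), renormalize = FALSE,
                 chrom_lengths_bp = NULL) {
  stopifnot(length(unique(segments$sample_id)) <= 1,
            all(exclude_chroms %in% 1:22))
  keep <- !(segments$chrom %in% exclude_chroms)
  total_bp <- sum(as.numeric(segments$end_bp[keep]) -
                    segments$start_bp[keep] + 1)
  denom <- AUTOSOME_BP
  if (renormalize) {
    stopifnot(!is.null(chrom_lengths_bp))
    denom <- denom - sum(chrom_lengths_bp[as.character(exclude_chroms)])
  }
  total_bp / denom
}

#' Correlation-between-uniting-gametes inbreeding coefficient (F3)
#'
#' Per-SNP term \eqn{[x^2 - (1+2p)x + 2p^2] / [2p(1-p)]} with genotype
#' \eqn{x \in \{0,1,2\}} counting copies of the frequency-\eqn{p} allele,
#' averaged over included non-missing SNPs. Under Hardy-Weinberg equilibrium
#' the term has expectation zero, so outbred genomes give values near zero
#' (negative for heterozygote excess) and autozygous genomes positive values.
#'
#' @param calls Integer genotype vector (0/1/2/`NA`) for one sample.
#' @param freqs Allele-b frequency per SNP, typically [allele_freqs()] of the
#'   study cohort. SNPs with `p` outside (0, 1) are skipped.
#' @param chrom Optional chromosome per SNP, required when `exclude_chroms`
#'   is non-empty.
#' @param exclude_chroms Chromosomes to exclude.
#' @return F3 estimate (finite; may be negative).
#' @examples
#' f3(c(1L), 0.5)           # single het at p = 0.5: -1
#' f3(c(0L, 2L), c(0.5, 0.5)) # homozygotes: +1
#' @export
f3 <- function(calls, freqs, chrom = NULL, exclude_chroms = integer()) {
  stopifnot(length(calls) == length(freqs))
  use <- !is.na(calls) & !is.na(freqs) & freqs > 0 & freqs < 1
  if (length(exclude_chroms)) {
    stopifnot(!is.null(chrom), length(chrom) == length(calls))
    use <- use & !(chrom %in% exclude_chroms)
  }
  if (!any(use)) stop("no usable SNPs for F3", call. = FALSE)
  x <- as.numeric(calls[use])
  p <- freqs[use]
  mean((x^2 - (1 + 2 * p) * x + 2 * p^2) / (2 * p * (1 - p)))
}

#' Per-sample homozygosity burden profiles
#'
#' One row per sample: segment count, total ROH kb, FROH, F3 and missing-call
#' fraction. F3 allele frequencies are estimated from all non-missing calls
#' in `g` (cases and controls together), mirroring per-study analysis.
#'
#' @param g A [geno_matrix()] after QC.
#' @param segments Segment tibble from [call_roh()] run on `g`.
#' @param exclude_chroms Chromosomes excluded from both FROH and F3
#'   (sensitivity analyses).
#' @return Tibble `(sample_id, n_roh, total_roh_kb, froh, f3,
#'   missing_fraction)` in the sample order of `g`.
#' @export
profile_cohort <- function(g, segments, exclude_chroms = integer()) {
  stopifnot(inherits(g, "geno_matrix"))
  freqs <- allele_freqs(g)
  vkeep <- !(g$variants$chrom %in% exclude_chroms)
  skeep <- !(segments$chrom %in% exclude_chroms)
  segs <- segments[skeep, , drop = FALSE]

  by_sample <- dplyr::group_by(segs, .data$sample_id)
  burden <- dplyr::summarise(
    by_sample,
    n_roh = dplyr::n(),
    total_roh_kb = sum(.data$length_kb),
    total_roh_bp = sum(as.numeric(.data$end_bp) - .data$start_bp + 1),
    .groups = "drop"
  )

  # per-SNP F3 terms and missing counts in one compiled pass; with every
  # chromosome excluded F3 is undefined and reported as NA
  use <- vkeep & !is.na(freqs) & freqs > 0 & freqs < 1
  p <- freqs
  p[!use] <- 0.5  # placeholder; unused columns are skipped
  scan <- .cpp_f3_profile(g$calls, p, use)
  prof <- tibble::tibble(
    sample_id = g$samples$sample_id,
    missing_fraction = scan$n_missing / n_variants(g),
    f3 = ifelse(scan$n_used > 0, scan$f3, NA_real_)
  )
  prof <- dplyr::left_join(prof, burden, by = "sample_id")
  dplyr::transmute(
    prof,
    sample_id = .data$sample_id,
    n_roh = dplyr::coalesce(.data$n_roh, 0L),
    total_roh_kb = dplyr::coalesce(.data$total_roh_kb, 0),
    froh = dplyr::coalesce(.data$total_roh_bp, 0) / AUTOSOME_BP,
    f3 = .data$f3,
    missing_fraction = .data$missing_fraction
  )
}

#' Study-by-status summary of homozygosity profiles
#'
#' Medians and interquartile ranges of total ROH length, segment count, FROH
#' and F3, split by study and case-control status.
#'
#' @param profiles Output of [profile_cohort()].
#' @param samples Sample sheet with `sample_id`, `study` and `status`.
#' @return Tibble, one row per study x status.
#' @export
summarize_profiles <- function(profiles, samples) {
  tbl <- dplyr::inner_join(profiles,
                           samples[, intersect(c("sample_id", "study", "status"),
                                               names(samples))],
                           by = "sample_id")
  grp <- dplyr::group_by(tbl, dplyr::across(dplyr::any_of(c("study", "status"))))
  dplyr::summarise(
    grp,
    n = dplyr::n(),
    median_total_kb = stats::median(.data$total_roh_kb),
    iqr_total_kb_lo = stats::quantile(.data$total_roh_kb, 0.25),
    iqr_total_kb_hi = stats::quantile(.data$total_roh_kb, 0.75),
    median_n_roh = stats::median(.data$n_roh),
    median_froh_pct = 100 * stats::median(.data$froh),
    iqr_froh_pct_lo = 100 * stats::quantile(.data$froh, 0.25),
    iqr_froh_pct_hi = 100 * stats::quantile(.data$froh, 0.75),
    median_f3 = stats::median(.data$f3),
    .groups = "drop"
  )
}
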