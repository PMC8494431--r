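#' Quality-control thresholds
#'
#' Defaults follow standard pre-analysis GWAS filtering: drop variants with
#' minor allele frequency below 0.05, missingness above 3%, or a
#' Hardy-Weinberg exact p-value below 1e-6 among controls, and drop samples
#' with call rate below 97%.
#'
#' @param maf_min Minimum minor allele frequency (strict `<` drops).
#' @param variant_missing_max Maximum per-variant missingness.
#' @param hwe_p_min Minimum Hardy-Weinberg exact p among controls.
#' @param sample_callrate_min Minimum per-sample call rate.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, variant_missing_max = 0.03,
                          hwe_p_min = 1e-6, sample_callrate_min = 0.97) {
  vals <- c(maf_min, variant_missing_max, hwe_p_min, sample_callrate_min)
  stopifnot(all(vals > 0), all(vals < 1))
  structure(
    list(maf_min = maf_min, variant_missing_max = variant_missing_max,
         hwe_p_min = hwe_p_min, sample_callrate_min = sample_callrate_min),
    class = "qc_thresholds"
  )
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test on genotype counts: conditioning on the observed
#' allele totals, sums the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed count (plain exact test,
#' no mid-p). Heterozygote-count probabilities are computed by the standard
#' recurrence to keep the test stable at large totals.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (homozygote a, heterozygote,
#'   homozygote b).
#' @return Exact p-value in (0, 1]. Monomorphic input returns 1 by convention.
#' @examples
#' hwe_exact_test(25, 50, 25) # perfectly HWE: p = 1
#' hwe_exact_test(10, 0, 10)  # no hets at p = 0.5: tiny p
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  stopifnot(n >= 1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)

  rare <- min(n_a, n_b)
  # possible het counts share the parity of the rare-allele total
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start from the modal region by recurrence in both directions
  mid <- rare * (n_a + n_b - rare) / (n_a + n_b)
  mid <- hets[which.min(abs(hets - mid))]
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+2)(h+1)) with counts implied by h
  if (i_mid < length(hets)) {
    for (i in seq(i_mid, length(hets) - 1)) {
      h <- hets[i]
      haa <- (rare - h) / 2
      hbb <- (n_a + n_b - rare - h) / 2
      probs[i + 1] <- probs[i] * 4 * haa * hbb / ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1) {
    for (i in seq(i_mid, 2)) {
      h <- hets[i]
      haa <- (rare - h) / 2
      hbb <- (n_a + n_b - rare - h) / 2
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (haa + 1) * (hbb + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

#' Apply per-variant quality-control filters
#'
#' Filters are applied in a fixed order so drop reports are reproducible:
#' minor allele frequency (over all samples, non-missing calls), then
#' missingness, then Hardy-Weinberg equilibrium among controls.
#'
#' @param g A [geno_matrix()] whose sample sheet has a `status` column.
#' @param thresholds A [qc_thresholds()].
#' @param hwe Apply the control-only HWE filter? Must be set to `FALSE`
#'   explicitly when the data contain no controls.
#' @return A list with elements `genotypes` (filtered [geno_matrix()]) and
#'   `report` (tibble of per-filter drop counts).
#' @export
apply_variant_qc <- function(g, thresholds = qc_thresholds(), hwe = TRUE) {
  t <- thresholds
  controls <- !is.na(g$samples$status) & g$samples$status == "control"
  if (hwe && !any(controls)) {
    stop("no control samples: the HWE filter needs controls; ",
         "pass hwe = FALSE to disable it explicitly", call. = FALSE)
  }

  p <- allele_freqs(g)
  maf <- pmin(p, 1 - p)
  drop_maf <- is.na(maf) | maf < t$maf_min
  g <- subset_geno(g, variant_idx = which(!drop_maf))

  miss <- colMeans(is.na(g$calls))
  drop_miss <- miss > t$variant_missing_max
  g <- subset_geno(g, variant_idx = which(!drop_miss))

  n_hwe <- 0L
  if (hwe) {
    ctl <- g$calls[controls, , drop = FALSE]
    hwe_p <- vapply(seq_len(ncol(ctl)), function(j) {
      x <- ctl[, j]
      hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                     sum(x == 2, na.rm = TRUE))
    }, numeric(1))
    drop_hwe <- hwe_p < t$hwe_p_min
    n_hwe <- sum(drop_hwe)
    g <- subset_geno(g, variant_idx = which(!drop_hwe))
  }

  report <- tibble::tibble(
    filter = c("maf", "missingness", "hwe_controls"),
    n_dropped = c(sum(drop_maf), sum(drop_miss), n_hwe)
  )
  list(genotypes = g, report = report)
}

#' Apply per-sample quality control
#'
#' Drops samples whose call rate over the (post-variant-QC) variants is below
#' the threshold, and records each survivor's fraction of missing calls in
#' the sample sheet as `missing_fraction` (number of missing calls divided by
#' the number of variants).
#'
#' @inheritParams apply_variant_qc
#' @return A list with elements `genotypes` and `report`.
#' @export
apply_sample_qc <- function(g, thresholds = qc_thresholds()) {
  miss <- rowMeans(is.na(g$calls))
  keep <- 1 - miss >= thresholds$sample_callrate_min
  if (!any(keep)) stop("sample QC removed every sample", call. = FALSE)
  g <- subset_geno(g, sample_idx = which(keep))
  g$samples$missing_fraction <- unname(miss[keep])
  report <- tibble::tibble(filter = "sample_callrate",
                           n_dropped = sum(!keep))
  list(genotypes = g, report = report)
}
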