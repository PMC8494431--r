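# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, per-element loops and hand formulas.

# HWE exact test by full enumeration over heterozygote counts with fixed
# allele totals, probabilities via log-factorials
hwe_enum_oracle <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  nb <- 2 * nbb + nab
  if (na == 0 || nb == 0) return(1)
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- (nb - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# F3 by an explicit per-SNP loop
f3_brute <- function(calls, p) {
  total <- 0
  k <- 0
  for (j in seq_along(calls)) {
    x <- calls[j]
    if (is.na(x) || is.na(p[j]) || p[j] <= 0 || p[j] >= 1) next
    total <- total + (x^2 - (1 + 2 * p[j]) * x + 2 * p[j]^2) /
      (2 * p[j] * (1 - p[j]))
    k <- k + 1
  }
  total / k
}

# brute-force evaluation of the sliding-window flag definition
flags_brute <- function(calls, params) {
  n <- length(calls)
  w <- min(params$window_snps, n)
  nw <- n - w + 1
  hom <- vapply(seq_len(nw), function(s) {
    win <- calls[s:(s + w - 1)]
    sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }, TRUE)
  vapply(seq_len(n), function(i) {
    ws <- max(1, i - w + 1):min(i, nw)
    mean(hom[ws]) >= params$hit_threshold
  }, TRUE)
}

# checks every RohSegment invariant for a set of called segments
expect_valid_segments <- function(segments, params = roh_params()) {
  if (nrow(segments) == 0) return(invisible(TRUE))
  expect_true(all(segments$start_bp <= segments$end_bp))
  expect_true(all(segments$n_snps >= params$min_snps))
  expect_true(all(segments$length_kb >= params$min_kb))
  expect_true(all(segments$length_kb / segments$n_snps <=
                    params$density_kb_per_snp))
  expect_equal(segments$length_kb,
               (segments$end_bp - segments$start_bp + 1) / 1000)
  # per sample x chromosome: sorted and non-overlapping
  by_sc <- split(segments,
                 paste(segments$sample_id, segments$chrom))
  for (d in by_sc) {
    if (nrow(d) < 2) next
    d <- d[order(d$start_bp), ]
    expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
  }
  invisible(TRUE)
}

# DerSimonian-Laird / IVW by direct hand evaluation
meta_hand <- function(beta, se, random = TRUE) {
  w <- 1 / se^2
  bfe <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bfe)^2)
  k <- length(beta)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  if (!random) tau2 <- 0
  ws <- 1 / (se^2 + tau2)
  list(beta = sum(ws * beta) / sum(ws), se = sqrt(1 / sum(ws)),
       Q = q, tau2 = tau2)
}
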