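#' Principal components of ancestry
#'
#' Standardises each variant to mean `2p` and standard deviation
#' `sqrt(2p(1-p))` (allele-b frequency `p` estimated from the data), mean
#' -imputes missing calls for this step only, and extracts the leading `k`
#' right-singular components. Scores are scaled to unit variance and each
#' component's sign is fixed by making its loading sum positive (first
#' non-zero loading decides exact ties), so repeated calls are identical.
#'
#' No LD pruning is applied; thin variants beforehand if desired.
#'
#' @param g A [geno_matrix()].
#' @param k Number of components (default 10).
#' @return Tibble `(sample_id, PC1..PCk)`.
#' @export
compute_pcs <- function(g, k = 10) {
  stopifnot(inherits(g, "geno_matrix"), k >= 1)
  n <- n_samples(g)
  if (n < k + 1) stop("need at least k + 1 samples", call. = FALSE)
  p <- allele_freqs(g)
  use <- !is.na(p) & p > 0 & p < 1
  x <- g$calls[, use, drop = FALSE]
  p <- p[use]
  z <- t((t(x) - 2 * p) / sqrt(2 * p * (1 - p)))
  z[is.na(z)] <- 0   # mean imputation after centring

  sv <- svd(z, nu = min(n, ncol(z)), nv = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) {
    stop("k = ", k, " exceeds the rank (", rank, ") of the standardized ",
         "genotype matrix", call. = FALSE)
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    # loading vector for component j (up to scale): z' u_j
    loading <- crossprod(z, sv$u[, j])
    s <- sum(loading)
    if (abs(s) < 1e-12) s <- loading[which(abs(loading) > 1e-12)[1]]
    if (is.na(s)) s <- 1
    if (s < 0) scores[, j] <- -scores[, j]
    scores[, j] <- scores[, j] / stats::sd(scores[, j])
  }
  out <- tibble::as_tibble(as.data.frame(scores))
  names(out) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble::tibble(sample_id = g$samples$sample_id), out)
}
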