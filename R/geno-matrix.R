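#' Genotype matrix container
#'
#' Bundles hard-call genotypes with their variant map and sample sheet. Calls
#' count copies of `allele_b`, so `0` and `2` are the two homozygotes, `1` is
#' the heterozygote and `NA` is a missing call. Only autosomal variants
#' (chromosomes 1-22) are kept: anything else is dropped with a message, and
#' variants are sorted by `(chrom, pos_bp)`.
#'
#' @param calls Integer matrix, samples in rows and variants in columns.
#'   Values must be 0, 1, 2 or `NA`.
#' @param variants Data frame with columns `id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b` (one row per column of `calls`).
#' @param samples Data frame with at least a `sample_id` column (one row per
#'   row of `calls`). Phenotype columns (`status`, `subtype`, `age`, `sex`,
#'   `study`, `PC1`..) ride along untouched.
#'
#' @return An object of class `geno_matrix` with elements `calls`,
#'   `variants` (tibble) and `samples` (tibble).
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0L, 1L, 2L, 0L, NA, 2L), nrow = 2, byrow = TRUE),
#'   variants = data.frame(
#'     id = c("rs1", "rs2", "rs3"), chrom = 1L, pos_bp = c(100L, 200L, 300L),
#'     allele_a = "A", allele_b = "B"
#'   ),
#'   samples = data.frame(sample_id = c("s1", "s2"))
#' )
#' n_variants(g)
#' @export
geno_matrix <- function(calls, variants, samples) {
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    is.matrix(calls),
    all(c("id", "chrom", "pos_bp", "allele_a", "allele_b") %in% names(variants)),
    "sample_id" %in% names(samples)
  )
  if (nrow(samples) != nrow(calls) || nrow(variants) != ncol(calls)) {
    stop("dimension mismatch: calls is ", nrow(calls), "x", ncol(calls),
         " but ", nrow(samples), " samples / ", nrow(variants),
         " variants supplied", call. = FALSE)
  }
  if (is.double(calls) && any(calls != round(calls), na.rm = TRUE)) {
    stop("calls contain values outside {0, 1, 2, NA}", call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  if (!.cpp_calls_valid(calls)) {
    stop("calls contain values outside {0, 1, 2, NA}", call. = FALSE)
  }
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant id: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(calls) <- "integer"

  autosomal <- variants$chrom %in% 1:22
  if (!all(autosomal)) {
    message(sum(!autosomal), " non-autosomal variant(s) dropped")
    variants <- variants[autosomal, , drop = FALSE]
    calls <- calls[, autosomal, drop = FALSE]
  }
  ord <- order(variants$chrom, variants$pos_bp)
  if (is.unsorted(ord)) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  dimnames(calls) <- list(samples$sample_id, variants$id)

  structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " variants on ", length(unique(x$variants$chrom)), " chromosome(s)\n",
      sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname geno_matrix
#' @param g A `geno_matrix`.
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname geno_matrix
#' @export
n_variants <- function(g) ncol(g$calls)

#' Allele-b frequencies from non-missing calls
#'
#' @param g A `geno_matrix`.
#' @return Numeric vector, one frequency per variant (`NaN` when a variant has
#'   no non-missing calls).
#' @export
allele_freqs <- function(g) {
  colMeans(g$calls, na.rm = TRUE) / 2
}

#' Attach or replace phenotype columns on a genotype matrix
#'
#' Joins a phenotype/covariate table onto the sample sheet by `sample_id`.
#' Samples absent from `pheno` keep `NA` phenotype values.
#'
#' @param g A `geno_matrix`.
#' @param pheno Data frame keyed by `sample_id`.
#' @return `g` with an updated `samples` tibble.
#' @export
attach_phenotypes <- function(g, pheno) {
  pheno <- tibble::as_tibble(pheno)
  stopifnot("sample_id" %in% names(pheno))
  keep <- c("sample_id", setdiff(names(g$samples), names(pheno)))
  g$samples <- dplyr::left_join(g$samples[, keep, drop = FALSE], pheno,
                                by = "sample_id")
  g
}

# restrict a geno_matrix to row/column index vectors, keeping metadata in step
subset_geno <- function(g, sample_idx = NULL, variant_idx = NULL) {
  if (!is.null(sample_idx)) {
    g$calls <- g$calls[sample_idx, , drop = FALSE]
    g$samples <- g$samples[sample_idx, , drop = FALSE]
  }
  if (!is.null(variant_idx)) {
    g$calls <- g$calls[, variant_idx, drop = FALSE]
    g$variants <- g$variants[variant_idx, , drop = FALSE]
  }
  g
}
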