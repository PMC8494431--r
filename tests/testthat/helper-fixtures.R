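# programmatic fixtures; nothing is stored on disk

tiny_variants <- function(m, chrom = 1L, start = 1e6, spacing = 10000L) {
  tibble::tibble(
    id = paste0("rs", chrom, "_", seq_len(m)),
    chrom = as.integer(chrom),
    pos_bp = as.integer(start + (seq_len(m) - 1) * spacing),
    allele_a = "A", allele_b = "B"
  )
}

make_geno <- function(calls, variants = NULL, status = NULL, spacing = 10000L) {
  calls <- as.matrix(calls)
  if (is.null(variants)) variants <- tiny_variants(ncol(calls),
                                                   spacing = spacing)
  samples <- tibble::tibble(sample_id = paste0("s", seq_len(nrow(calls))))
  if (!is.null(status)) samples$status <- status
  geno_matrix(calls, variants, samples)
}

# genotype vector with a fully homozygous tract planted between het flanks
planted_tract_calls <- function(n_flank, n_tract, p = 0.3, seed = 1) {
  set.seed(seed)
  flank <- function(k) rbinom(k, 2, p)
  hets <- function(k) rep(1L, k)
  c(hets(n_flank), 2L * rbinom(n_tract, 1, p), hets(n_flank))
}

empty_segments <- function() {
  tibble::tibble(sample_id = character(), chrom = integer(),
                 start_bp = integer(), end_bp = integer(),
                 n_snps = integer(), length_kb = numeric())
}

one_segment <- function(total_kb, sample_id = "s1", chrom = 1L,
                        start_bp = 1L) {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 start_bp = as.integer(start_bp),
                 end_bp = as.integer(start_bp + total_kb * 1000 - 1),
                 n_snps = 1000L, length_kb = total_kb)
}

# fits comfortably in memory/time; mean_segments lowered so tract placement
# always fits the 30-Mb toy genome
small_sim_params <- function(...) {
  defaults <- list(n_case = 60, n_control = 60, m_snps = 4000,
                   chrom_lengths_bp = c(2.5e7, 2.5e7), mean_segments = 3)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}
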