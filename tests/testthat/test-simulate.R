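test_that("simulate_map is sorted, density-aware and reproducible", {
  p <- small_sim_params()
  map <- simulate_map(p, seed = 5)
  expect_equal(nrow(map), p$m_snps)
  for (c in unique(map$chrom)) {
    expect_false(is.unsorted(map$pos_bp[map$chrom == c], strictly = TRUE))
  }
  expect_true(all(map$freq >= p$freq_low & map$freq <= p$freq_high))
  expect_identical(map, simulate_map(p, seed = 5))
  expect_false(identical(map$pos_bp, simulate_map(p, seed = 6)$pos_bp))

  # mean spacing ~ genome / m
  spacing <- mean(diff(map$pos_bp[map$chrom == 1]))
  expect_lt(abs(spacing - p$chrom_lengths_bp[1] / (p$m_snps / 2)), 2000)

  # too sparse to ever call: warn with the expected SNP count
  sparse <- sim_params(m_snps = 500, chrom_lengths_bp = 5e7)
  expect_warning(simulate_map(sparse, seed = 1), "density too low")
})

test_that("genotypes follow HWE outside tracts and are homozygous inside", {
  # no tracts, no error: heterozygosity matches its analytic expectation
  p <- small_sim_params(mean_segments = 0, genotype_error = 0,
                        missing_rate = 0, subpop_divergence = 0)
  map <- simulate_map(p, seed = 7)
  co <- simulate_genotypes(map, p, n_samples = 300, seed = 8)
  expect_equal(nrow(co$truth), 300)
  expect_true(all(co$truth$true_froh == 0))
  het <- mean(co$genotypes$calls == 1)
  het_expected <- mean(2 * map$freq * (1 - map$freq))
  expect_lt(abs(het - het_expected), 0.005)

  # with tracts but no error, inside-tract heterozygosity is exactly zero
  p2 <- small_sim_params(genotype_error = 0, missing_rate = 0)
  map2 <- simulate_map(p2, seed = 9)
  co2 <- simulate_genotypes(map2, p2, n_samples = 100, seed = 10)
  v <- co2$genotypes$variants
  for (i in seq_len(nrow(co2$tracts))) {
    tr <- co2$tracts[i, ]
    idx <- which(v$chrom == tr$chrom & v$pos_bp >= tr$start_bp &
                   v$pos_bp <= tr$end_bp)
    s <- match(tr$sample_id, co2$genotypes$samples$sample_id)
    expect_false(any(co2$genotypes$calls[s, idx] == 1, na.rm = TRUE))
  }

  # true FROH is planted length over the 3e9-bp autosome
  expect_equal(co2$truth$true_froh,
               as.numeric(tapply(
                 as.numeric(co2$tracts$end_bp - co2$tracts$start_bp + 1),
                 factor(co2$tracts$sample_id,
                        levels = co2$truth$sample_id), sum,
                 default = 0)) / 3e9)
  # tracts lie within chromosome bounds and do not overlap within a sample
  expect_true(all(co2$tracts$start_bp >= 1))
  expect_true(all(co2$tracts$end_bp <=
                    p2$chrom_lengths_bp[co2$tracts$chrom]))
  by_sc <- split(co2$tracts, paste(co2$tracts$sample_id, co2$tracts$chrom))
  for (d in by_sc) {
    if (nrow(d) < 2) next
    d <- d[order(d$start_bp), ]
    expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
  }
})

test_that("genotyping error and missingness are injected at the stated rates", {
  p <- small_sim_params(mean_segments = 0, genotype_error = 0.01,
                        missing_rate = 0.01, subpop_divergence = 0)
  map <- simulate_map(p, seed = 11)
  co <- simulate_genotypes(map, p, n_samples = 200, seed = 12)
  expect_lt(abs(mean(is.na(co$genotypes$calls)) - 0.01), 0.002)
})

test_that("phenotype assignment meets quotas, is seeded, and honours single-sex", {
  p <- small_sim_params()
  map <- simulate_map(p, seed = 13)
  pool <- simulate_genotypes(map, p, n_samples = 300, seed = 14)
  co <- simulate_phenotype(pool, p, seed = 15)
  s <- co$genotypes$samples
  expect_equal(sum(s$status == "case"), p$n_case)
  expect_equal(sum(s$status == "control"), p$n_control)
  expect_equal(s$subtype[s$status == "control"],
               rep("none", p$n_control))
  expect_true(all(s$subtype[s$status == "case"] == p$subtype))
  co_again <- simulate_phenotype(pool, p, seed = 15)
  expect_identical(co_again$genotypes$samples, s)
  expect_false(identical(simulate_phenotype(pool, p, seed = 16)$
                           genotypes$samples$status, s$status))

  # truth rows track the selected samples
  expect_equal(co$truth$sample_id, s$sample_id)
  expect_equal(co$truth$status, s$status)

  # single-sex option: all controls female
  p2 <- small_sim_params(single_sex = TRUE, n_case = 40, n_control = 40)
  pool2 <- simulate_genotypes(simulate_map(p2, seed = 17), p2,
                              n_samples = 400, seed = 18)
  co2 <- simulate_phenotype(pool2, p2, seed = 19)
  s2 <- co2$genotypes$samples
  expect_true(all(s2$sex[s2$status == "control"] == "female"))

  # unattainable quota reports the achieved prevalence
  p3 <- small_sim_params(n_case = 290, n_control = 290)
  expect_error(simulate_phenotype(pool, p3, seed = 20),
               "quota unattainable")
})

test_that("a strong burden effect enriches cases for high-FROH genomes", {
  # bimodal truth: samples either carry no tracts or many
  p <- small_sim_params(n_case = 80, n_control = 80, beta_froh = 600,
                        mean_segments = 3)
  map <- simulate_map(p, seed = 23)
  pool <- simulate_genotypes(map, p, n_samples = 500, seed = 24)
  co <- simulate_phenotype(pool, p, seed = 25)
  froh_case <- co$truth$true_froh[co$truth$status == "case"]
  froh_ctrl <- co$truth$true_froh[co$truth$status == "control"]
  expect_gt(mean(froh_case), mean(froh_ctrl))
})

test_that("under the null the case and control FROH distributions coincide", {
  # 20 independent phenotype draws at beta_froh = 0: the KS test should be
  # non-significant at alpha = 0.01 in essentially all of them (binomial
  # wiggle allows one exceedance)
  p <- small_sim_params(n_case = 50, n_control = 50, beta_froh = 0)
  map <- simulate_map(p, seed = 29)
  pool <- simulate_genotypes(map, p, n_samples = 150, seed = 30)
  sig <- 0
  for (i in 1:20) {
    co <- simulate_phenotype(pool, p, seed = 100 + i)
    ks <- suppressWarnings(
      stats::ks.test(co$truth$true_froh[co$truth$status == "case"],
                     co$truth$true_froh[co$truth$status == "control"]))
    sig <- sig + (ks$p.value < 0.01)
  }
  expect_lte(sig, 1)
})

test_that("simulated cohorts write and read back through the PLINK dialects", {
  p <- small_sim_params(n_case = 15, n_control = 15, m_snps = 400)
  co <- suppressWarnings(simulate_cohort(p, seed = 31))  # sparse toy map
  dir <- withr::local_tempdir()
  prefix <- write_cohort(co, dir, name = "toy", dialect = "binary")
  g2 <- read_genotypes(prefix, "binary")
  expect_identical(unname(g2$calls), unname(co$genotypes$calls))
  pheno <- read_phenotypes(paste0(prefix, ".pheno.tsv"))
  expect_equal(pheno$status, co$genotypes$samples$status)
  truth <- readr::read_tsv(paste0(prefix, ".truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(truth$true_froh, co$truth$true_froh)
})
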