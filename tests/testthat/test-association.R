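test_that("fit_logistic matches the closed-form 2x2 odds ratio and Woolf SE", {
  # a = 10 exposed cases, b = 20 exposed controls, c = 30, d = 40
  y <- rep(c(1, 0, 1, 0), c(10, 20, 30, 40))
  x <- rep(c(1, 1, 0, 0), c(10, 20, 30, 40))
  res <- fit_logistic(y, x)
  expect_equal(res$beta, log(10 * 40 / (20 * 30)), tolerance = 1e-6)
  expect_equal(res$se, sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 40),
               tolerance = 1e-6)
  expect_true(res$converged)
  expect_equal(res$n_case, 40)
  expect_equal(res$n_control, 60)
  # broom-style accessors agree with the object
  gl <- glance(res)
  expect_equal(gl$beta, res$beta)
  td <- tidy(res)
  expect_true("exposure" %in% td$term)
  expect_equal(td$estimate[td$term == "exposure"], res$beta)
})

test_that("fit_logistic rejects degenerate inputs and flags separation", {
  y <- rep(c(1, 0), 20)
  expect_error(fit_logistic(y, rep(1, 40)), "zero-variance")
  expect_error(fit_logistic(rep(1, 10), rnorm(10)), "single class")
  # constant covariate dropped with a warning (single-sex study behaviour)
  expect_warning(
    res <- fit_logistic(y, rnorm(40),
                        covariates = data.frame(sex = rep("female", 40))),
    "constant covariate"
  )
  expect_true(res$converged)
  expect_identical(res$dropped_covariates, "sex")
  # perfectly separated exposure is reported, not silently accepted
  y2 <- rep(c(1, 0), each = 20)
  x2 <- c(rnorm(20, 10), rnorm(20, -10))
  res2 <- fit_logistic(y2, x2)
  expect_false(res2$converged)
})

test_that("burden beta is equivariant under exposure rescaling", {
  set.seed(71)
  y <- rbinom(300, 1, 0.5)
  x <- rnorm(300)
  cov <- data.frame(age = rnorm(300, 60, 8))
  base <- fit_logistic(y, x, cov)
  for (c in c(0.001, 10, 1000)) {
    sc <- fit_logistic(y, x * c, cov)
    expect_equal(sc$beta, base$beta / c, tolerance = 1e-8)
    expect_equal(sc$se, base$se / c, tolerance = 1e-8)
    expect_equal(sc$p, base$p, tolerance = 1e-10)
  }
})

test_that("test_burden recovers a planted burden effect and applies filters", {
  p <- small_sim_params(n_case = 150, n_control = 150, beta_froh = 150)
  co <- simulate_cohort(p, seed = 73)
  segs <- call_roh(co$genotypes)
  res <- test_burden(co$genotypes, segs, metric = "froh")
  expect_true(res$converged)
  # strong true effect at this scale: estimate within 2 SE of truth
  expect_lt(abs(res$beta - 150), 2 * res$se)

  # removing all cases is an error (one class)
  all_cases <- co$genotypes$samples$sample_id[
    co$genotypes$samples$status == "case"]
  expect_error(test_burden(co$genotypes, segs,
                           exclude_samples = all_cases),
               "both cases and controls")
  # unknown covariate named clearly
  expect_error(test_burden(co$genotypes, segs, covariates = "bmi"),
               "bmi")
  # exclude_chroms changes the exposure actually fitted
  res2 <- test_burden(co$genotypes, segs, exclude_chroms = 1L)
  expect_false(isTRUE(all.equal(res$beta, res2$beta)))
})

test_that("compute_pcs separates planted subpopulations deterministically", {
  p <- small_sim_params(subpop_divergence = 0.05, mean_segments = 0)
  co <- simulate_cohort(p, seed = 79)
  pcs <- compute_pcs(co$genotypes, k = 4)
  lab <- co$truth$subpop[match(pcs$sample_id, co$truth$sample_id)]
  gap <- abs(mean(pcs$PC1[lab == 1]) - mean(pcs$PC1[lab == 2]))
  wsd <- sqrt(mean(c(var(pcs$PC1[lab == 1]), var(pcs$PC1[lab == 2]))))
  expect_gt(gap, 4 * wsd)
  # unit variance scores, deterministic including the sign convention
  expect_equal(unname(apply(as.matrix(pcs[, -1]), 2, sd)), rep(1, 4))
  expect_identical(pcs, compute_pcs(co$genotypes, k = 4))

  # identical rows for all samples: rank deficient
  flat <- make_geno(matrix(1L, 12, 50))
  expect_error(compute_pcs(flat, k = 2), "rank")
  expect_error(compute_pcs(co$genotypes, k = 5000), "rank|samples")
})

test_that("bin grids tile from position 1 and midpoints land in the stated bin", {
  v <- tibble::tibble(chrom = c(1L, 1L, 2L), pos_bp = c(10L, 1.9e6, 7e5),
                      id = c("a", "b", "c"), allele_a = "A", allele_b = "B")
  grid <- bin_grid(v)
  expect_equal(nrow(grid), 4 + 2)          # chr1 to 2 Mb, chr2 to 1 Mb
  expect_equal(grid$start_bp[grid$bin_id == "1:1"], 1L)
  expect_equal(grid$end_bp[grid$bin_id == "1:1"], 500000L)
  expect_true(all(grid$end_bp - grid$start_bp + 1 == 500000))

  # worked midpoint example: [1,200,000 - 2,700,000] -> 1,950,000 -> bin 4
  seg <- tibble::tibble(sample_id = "s1", chrom = 1L, start_bp = 1200000L,
                        end_bp = 2700000L, n_snps = 200L, length_kb = 1500)
  ex <- assign_bins(seg, grid)
  expect_equal(ex$bin_id, "1:4")
  expect_equal(grid$start_bp[grid$bin_id == "1:4"], 1500001L)
  expect_equal(grid$end_bp[grid$bin_id == "1:4"], 2000000L)

  # exposure is an indicator: two segments in one bin count once
  segs2 <- dplyr::bind_rows(seg, dplyr::mutate(seg, start_bp = 1600000L,
                                               end_bp = 2100000L))
  expect_equal(nrow(assign_bins(segs2, grid)), 1)
  # no segments -> no exposures
  expect_equal(nrow(assign_bins(empty_segments(), grid)), 0)
})

test_that("bin exposures never exceed per-sample segment counts", {
  co <- simulate_cohort(small_sim_params(), seed = 83)
  segs <- call_roh(co$genotypes)
  grid <- bin_grid(co$genotypes)
  ex <- assign_bins(segs, grid)
  per_sample_ex <- table(factor(ex$sample_id,
                                levels = co$genotypes$samples$sample_id))
  per_sample_segs <- table(factor(segs$sample_id,
                                  levels = co$genotypes$samples$sample_id))
  expect_true(all(as.integer(per_sample_ex) <=
                    as.integer(per_sample_segs)))
})

test_that("test_bins skips sparse and one-arm bins with reasons", {
  set.seed(89)
  n <- 80
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    status = rep(c("case", "control"), n / 2),
    age = rnorm(n, 60, 8)
  )
  grid <- bin_grid(tibble::tibble(chrom = 1L, pos_bp = 2e6, id = "v",
                                  allele_a = "A", allele_b = "B"))
  # bin 1: balanced exposure; bin 2: cases only; bin 3: 2 exposed; bin 4: none
  ex <- dplyr::bind_rows(
    tibble::tibble(sample_id = samples$sample_id[1:20], bin_id = "1:1"),
    tibble::tibble(sample_id = samples$sample_id[seq(1, 19, 2)],
                   bin_id = "1:2"),
    tibble::tibble(sample_id = samples$sample_id[1:2], bin_id = "1:3")
  )
  res <- test_bins(samples, ex, grid, covariates = "age")
  expect_s3_class(res, "roh_binscan")
  expect_equal(res$status[res$bin_id == "1:1"], "tested")
  expect_equal(res$reason[res$bin_id == "1:2"], "one-arm exposure")
  expect_equal(res$reason[res$bin_id == "1:3"], "fewer than min_exposed")
  expect_equal(res$reason[res$bin_id == "1:4"], "unexposed")
  # all bins unexposed: everything skipped
  res0 <- test_bins(samples, ex[0, ], grid, covariates = "age")
  expect_true(all(res0$status == "skipped"))
})

test_that("a planted exposure effect at one bin is recovered within 2 SE", {
  set.seed(97)
  n <- 4000
  exposed <- rbinom(n, 1, 0.125)
  lp <- -0.1 + log(3) * exposed
  y <- rbinom(n, 1, plogis(lp))
  samples <- tibble::tibble(sample_id = paste0("s", 1:n), status =
                              ifelse(y == 1, "case", "control"),
                            age = rnorm(n, 60, 8))
  grid <- bin_grid(tibble::tibble(chrom = 1L, pos_bp = 9e5, id = "v",
                                  allele_a = "A", allele_b = "B"))
  ex <- tibble::tibble(sample_id = samples$sample_id[exposed == 1],
                       bin_id = "1:1")
  res <- test_bins(samples, ex, grid, covariates = "age")
  row <- res[res$bin_id == "1:1", ]
  expect_equal(row$status, "tested")
  expect_lt(abs(row$beta - log(3)), 2 * row$se)
})
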