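test_that("geno_matrix validates inputs, sorts the map and drops non-autosomes", {
  v <- tibble::tibble(id = c("a", "b", "c"), chrom = c(2L, 1L, 23L),
                      pos_bp = c(100L, 200L, 300L),
                      allele_a = "A", allele_b = "B")
  calls <- matrix(c(0L, 1L, 2L, 2L, NA, 0L), nrow = 2, byrow = TRUE)
  expect_message(g <- geno_matrix(calls, v,
                                  tibble::tibble(sample_id = c("s1", "s2"))),
                 "non-autosomal")
  expect_equal(n_variants(g), 2)
  expect_equal(g$variants$id, c("b", "a"))          # sorted by (chrom, pos)
  expect_equal(unname(g$calls[1, ]), c(1L, 0L))     # columns follow the sort

  expect_error(geno_matrix(calls, v, tibble::tibble(sample_id = "s1")),
               "dimension mismatch")
  expect_error(geno_matrix(matrix(3L, 1, 3), v,
                           tibble::tibble(sample_id = "s1")),
               "outside")
  v2 <- v; v2$id <- c("a", "a", "c")
  expect_error(geno_matrix(calls, v2,
                           tibble::tibble(sample_id = c("s1", "s2"))),
               "duplicate variant id")
})

test_that("text and binary dialects round-trip the calls matrix exactly", {
  set.seed(11)
  m <- 25; n <- 9
  calls <- matrix(sample(c(0L, 1L, 2L, NA), m * n, replace = TRUE,
                         prob = c(.4, .3, .25, .05)), n, m)
  g <- make_geno(calls,
                 status = sample(c("case", "control"), n, replace = TRUE))
  g$samples$sex <- sample(c("male", "female"), n, replace = TRUE)

  for (dialect in c("text", "binary")) {
    prefix <- file.path(withr::local_tempdir(), paste0("rt_", dialect))
    write_genotypes(g, prefix, dialect)
    g2 <- read_genotypes(prefix, dialect)
    expect_identical(unname(g2$calls), unname(g$calls))
    expect_identical(g2$variants$pos_bp, g$variants$pos_bp)
    expect_identical(g2$samples$status, g$samples$status)
    expect_identical(g2$samples$sex, g$samples$sex)
  }
})

test_that("a chrX row in the map is dropped on read", {
  calls <- matrix(c(0L, 1L, 2L, 0L, 2L,
                    1L, 1L, 0L, 2L, 0L,
                    2L, 0L, 1L, 1L, 2L), nrow = 3, byrow = TRUE)
  v <- tiny_variants(5)
  v$chrom[4] <- 23L
  prefix <- file.path(withr::local_tempdir(), "x")
  suppressMessages({
    g <- geno_matrix(calls[, -4], v[-4, ], tibble::tibble(
      sample_id = paste0("s", 1:3)))
  })
  # write the 5-variant map by hand so the fixture really contains chrX
  writeLines(paste(v$chrom, v$id, 0, v$pos_bp, sep = "\t"),
             paste0(prefix, ".map"))
  geno_str <- c("A A", "A B", "B B")
  lines <- vapply(1:3, function(i) {
    paste(c(paste0("s", i), paste0("s", i), 0, 0, 0, 1,
            geno_str[calls[i, ] + 1]), collapse = "\t")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  expect_message(g2 <- read_genotypes(prefix, "text"), "1 non-autosomal")
  expect_equal(dim(g2$calls), c(3, 4))
  expect_identical(unname(g2$calls), unname(g$calls))
})

test_that("malformed PED/MAP lines raise parse errors naming file and line", {
  prefix <- file.path(withr::local_tempdir(), "bad")
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"), paste0(prefix, ".map"))
  writeLines(c("s1\ts1\t0\t0\t1\t1\tA A\tA B",
               "s2\ts2\t0\t0\t1\t1\tA A"), paste0(prefix, ".ped"))
  expect_error(read_genotypes(prefix, "text"), "line 2")
  writeLines("1\trs1\t0", paste0(prefix, ".map"))
  expect_error(read_genotypes(prefix, "text"), "expected 4 fields")
})

test_that("hwe_exact_test matches full enumeration and its conventions", {
  # frozen from the enumeration oracle
  expect_equal(hwe_exact_test(57, 14, 50), 5.562047311095e-19,
               tolerance = 1e-10)
  expect_equal(hwe_exact_test(57, 14, 50), hwe_enum_oracle(57, 14, 50),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(25, 50, 25), 1)   # observed het count is modal
  # no hets at p = 0.5, n = 20: extreme (enumeration gives 1.3403e-6)
  expect_equal(hwe_exact_test(10, 0, 10), hwe_enum_oracle(10, 0, 10),
               tolerance = 1e-12)
  expect_lt(hwe_exact_test(10, 0, 10), 1e-5)
  # monomorphic convention
  expect_equal(hwe_exact_test(30, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 12), 1)
})

test_that("hwe_exact_test equals enumeration for every configuration up to total 50", {
  worst <- 0
  for (n in 1:50) {
    for (naa in 0:n) {
      for (nab in 0:(n - naa)) {
        nbb <- n - naa - nab
        d <- abs(hwe_exact_test(naa, nab, nbb) -
                   hwe_enum_oracle(naa, nab, nbb))
        worst <- max(worst, d)
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("variant QC applies MAF, missingness and control-HWE filters in order", {
  set.seed(21)
  n <- 60
  m <- 20
  p <- runif(m, 0.2, 0.4)
  calls <- sapply(p, function(pp) rbinom(n, 2, pp))
  # planted violations
  calls[, 3] <- rbinom(n, 1, 0.04)              # MAF ~0.02 < 0.05
  calls[sample(n, 4), 7] <- NA                  # 6.7% missing > 3%
  calls[, 12] <- sample(rep(c(0L, 2L), n / 2))  # no hets: extreme HWE
  status <- rep(c("case", "control"), n / 2)
  g <- make_geno(calls, status = status)

  res <- apply_variant_qc(g, qc_thresholds())
  expect_equal(n_variants(res$genotypes), 17)
  expect_equal(res$report$n_dropped, c(1, 1, 1))
  expect_equal(sum(res$report$n_dropped),
               m - n_variants(res$genotypes))

  # boundary behaviour: MAF 0.04 dropped (strict <), 4% missing dropped,
  # MAF 0.20 with 2% missing retained
  calls2 <- cbind(
    c(rep(1L, 4), rep(0L, 46)),                       # MAF 0.04
    c(rep(NA, 2), rbinom(48, 2, 0.3)),                # 4% missing
    c(rep(NA, 1), rbinom(49, 2, 0.25))                # 2% missing, MAF ok
  )
  g2 <- make_geno(calls2, status = rep(c("case", "control"), 25))
  res2 <- apply_variant_qc(g2, qc_thresholds())
  expect_false("rs1_1" %in% res2$genotypes$variants$id)
  expect_false("rs1_2" %in% res2$genotypes$variants$id)
  expect_true("rs1_3" %in% res2$genotypes$variants$id)

  # QC is idempotent
  res3 <- apply_variant_qc(res$genotypes, qc_thresholds())
  expect_equal(sum(res3$report$n_dropped), 0)
  expect_identical(res3$genotypes$calls, res$genotypes$calls)

  # surviving MAF recomputed independently is >= 0.05
  surv <- res$genotypes$calls
  maf <- apply(surv, 2, function(x) {
    f <- mean(x, na.rm = TRUE) / 2
    min(f, 1 - f)
  })
  expect_true(all(maf >= 0.05))
})

test_that("variant QC without controls demands an explicit opt-out", {
  g <- make_geno(matrix(rbinom(100, 2, 0.3), 10, 10),
                 status = rep("case", 10))
  expect_error(apply_variant_qc(g), "hwe = FALSE")
  expect_silent(res <- apply_variant_qc(g, hwe = FALSE))
  expect_equal(res$report$n_dropped[res$report$filter == "hwe_controls"], 0)
})

test_that("sample QC drops low call rates and records missing_fraction", {
  set.seed(5)
  calls <- matrix(rbinom(300, 2, 0.3), 3, 100)
  calls[2, 1:4] <- NA    # call rate 0.96 -> dropped
  calls[3, 1:2] <- NA    # 0.98 -> kept, missing_fraction 0.02
  g <- make_geno(calls, status = c("case", "control", "control"))
  res <- apply_sample_qc(g)
  expect_equal(res$genotypes$samples$sample_id, c("s1", "s3"))
  expect_equal(res$genotypes$samples$missing_fraction, c(0, 0.02))
  expect_equal(res$report$n_dropped, 1)

  calls[] <- NA
  expect_error(apply_sample_qc(make_geno(calls)), "every sample")
})
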