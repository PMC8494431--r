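#' Read genotypes from PLINK-dialect files
#'
#' Reads a case-control genotype dataset from either the text dialect
#' (`.ped` + `.map`) or the binary dialect (`.bed` + `.bim` + `.fam`,
#' SNP-major layout). Calls count copies of `allele_b`; in the binary dialect
#' `allele_a`/`allele_b` are the BIM A1/A2 columns, while in the text dialect
#' the two observed allele labels are assigned alphabetically (`allele_a` <
#' `allele_b`) because PED/MAP files carry no allele columns.
#'
#' Non-autosomal variants are dropped (with a message) and variants are
#' sorted by `(chrom, pos_bp)` on the way in.
#'
#' @param prefix Path prefix; the dialect-specific extensions are appended.
#' @param dialect `"binary"` or `"text"`.
#' @return A [geno_matrix()].
#' @seealso [write_genotypes()], [read_phenotypes()]
#' @export
read_genotypes <- function(prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") read_plink_text(prefix) else read_plink_bed(prefix)
}

#' Write genotypes to PLINK-dialect files
#'
#' @param g A [geno_matrix()].
#' @param prefix Output path prefix.
#' @param dialect `"binary"` (BED/BIM/FAM, SNP-major) or `"text"` (PED/MAP).
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(g, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") write_plink_text(g, prefix) else write_plink_bed(g, prefix)
  invisible(prefix)
}

# ---- text dialect (PED/MAP) -------------------------------------------------

read_map_file <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt != 4)) {
    stop("parse error in ", path, " line ", which(nt != 4)[1],
         ": expected 4 fields, got ", nt[which(nt != 4)[1]], call. = FALSE)
  }
  m <- do.call(rbind, toks)
  tibble::tibble(
    chrom = suppressWarnings(as.integer(m[, 1])),
    id = m[, 2],
    pos_bp = suppressWarnings(as.integer(m[, 4]))
  )
}

read_plink_text <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- read_map_file(map_path)
  m <- nrow(map)

  lines <- readLines(ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  bad <- which(nt != 6 + 2 * m)
  if (length(bad)) {
    stop("parse error in ", ped_path, " line ", bad[1], ": expected ",
         6 + 2 * m, " fields (map has ", m, " variants), got ", nt[bad[1]],
         call. = FALSE)
  }
  tok <- do.call(rbind, toks)
  n <- nrow(tok)
  a1 <- tok[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(m), drop = FALSE]

  allele_a <- allele_b <- character(m)
  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
    if (length(obs) > 2) {
      stop("parse error in ", ped_path, ": variant ", map$id[j],
           " has >2 alleles (", paste(obs, collapse = ","), ")", call. = FALSE)
    }
    allele_a[j] <- if (length(obs) >= 1) obs[1] else "0"
    allele_b[j] <- if (length(obs) == 2) obs[2] else "0"
    miss <- a1[, j] == "0" | a2[, j] == "0"
    calls[, j] <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
    calls[miss, j] <- NA_integer_
  }

  samples <- tibble::tibble(
    sample_id = tok[, 2],
    sex = decode_sex(tok[, 5]),
    status = decode_status(tok[, 6])
  )
  variants <- tibble::tibble(
    id = map$id, chrom = map$chrom, pos_bp = map$pos_bp,
    allele_a = allele_a, allele_b = allele_b
  )
  geno_matrix(calls, variants, samples)
}

write_plink_text <- function(g, prefix) {
  v <- g$variants
  map <- paste(v$chrom, v$id, 0, v$pos_bp, sep = "\t")
  writeLines(map, paste0(prefix, ".map"))

  n <- n_samples(g)
  geno_str <- matrix("0 0", n, n_variants(g))
  for (j in seq_len(ncol(geno_str))) {
    lv <- c(
      paste(v$allele_a[j], v$allele_a[j]),
      paste(v$allele_a[j], v$allele_b[j]),
      paste(v$allele_b[j], v$allele_b[j])
    )
    x <- g$calls[, j]
    geno_str[!is.na(x), j] <- lv[x[!is.na(x)] + 1L]
  }
  s <- g$samples
  lead <- paste(s$sample_id, s$sample_id, 0, 0,
                encode_sex(sample_col(s, "sex")),
                encode_status(sample_col(s, "status")), sep = "\t")
  body <- apply(geno_str, 1, paste, collapse = "\t")
  writeLines(paste(lead, body, sep = "\t"), paste0(prefix, ".ped"))
}

# ---- binary dialect (BED/BIM/FAM, SNP-major) --------------------------------

# 2-bit codes: 00 = hom allele_a (call 0), 01 = missing, 10 = het, 11 = hom allele_b
bed_decode_table <- function() {
  codes <- c(0L, NA_integer_, 1L, 2L)
  vapply(0:255, function(v) {
    codes[bitwAnd(bitwShiftR(v, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  }, integer(4))
}

read_plink_bed <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      stop("missing file: ", paste0(prefix, ext), call. = FALSE)
    }
  }
  bim <- utils::read.table(paste0(prefix, ".bim"), colClasses = "character")
  fam <- utils::read.table(paste0(prefix, ".fam"), colClasses = "character")
  m <- nrow(bim)
  n <- nrow(fam)
  bps <- ceiling(n / 4)

  raw <- readBin(bed_path, "raw", n = 3 + m * bps + 1)
  if (length(raw) != 3 + m * bps) {
    stop("parse error in ", bed_path, ": expected ", 3 + m * bps,
         " bytes for ", n, " samples x ", m, " variants, found ", length(raw),
         call. = FALSE)
  }
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("parse error in ", bed_path,
         ": bad magic number or not SNP-major", call. = FALSE)
  }
  lut <- bed_decode_table()
  codes <- lut[, as.integer(raw[-(1:3)]) + 1L]   # 4 x (bps*m)
  calls <- matrix(as.vector(codes), nrow = 4 * bps)[seq_len(n), , drop = FALSE]

  variants <- tibble::tibble(
    id = bim[, 2],
    chrom = suppressWarnings(as.integer(bim[, 1])),
    pos_bp = suppressWarnings(as.integer(bim[, 4])),
    allele_a = bim[, 5], allele_b = bim[, 6]
  )
  samples <- tibble::tibble(
    sample_id = fam[, 2],
    sex = decode_sex(fam[, 5]),
    status = decode_status(fam[, 6])
  )
  geno_matrix(calls, variants, samples)
}

write_plink_bed <- function(g, prefix) {
  v <- g$variants
  s <- g$samples
  writeLines(paste(v$chrom, v$id, 0, v$pos_bp, v$allele_a, v$allele_b,
                   sep = "\t"),
             paste0(prefix, ".bim"))
  writeLines(paste(s$sample_id, s$sample_id, 0, 0,
                   encode_sex(sample_col(s, "sex")),
                   encode_status(sample_col(s, "status")), sep = "\t"),
             paste0(prefix, ".fam"))

  n <- n_samples(g)
  m <- n_variants(g)
  bps <- ceiling(n / 4)
  code <- matrix(1L, 4 * bps, m)                 # pad bits: 01 (missing)
  x <- g$calls
  bit2 <- matrix(c(0L, 2L, 3L)[x + 1L], n, m)    # 0->00, 1->10, 2->11
  bit2[is.na(x)] <- 1L
  code[seq_len(n), ] <- bit2
  dim(code) <- c(4L, bps * m)
  bytes <- as.raw(colSums(code * c(1L, 4L, 16L, 64L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
}

# ---- phenotype/covariate tables ---------------------------------------------

#' Read or write a phenotype/covariate table
#'
#' Tab-delimited with a header; expected columns are `sample_id`, `status`
#' (`case`/`control`), `age`, `sex`, `study` and any further covariates
#' (`PC1`..`PC10`, `missing_fraction`, ...).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_phenotypes
#' @param pheno Data frame to write.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path)
  invisible(path)
}

sample_col <- function(s, col) {
  if (col %in% names(s)) s[[col]] else rep(NA_character_, nrow(s))
}
decode_sex <- function(x) c("male", "female")[match(x, c("1", "2"))]
encode_sex <- function(x) {
  out <- match(x, c("male", "female"))
  out[is.na(out)] <- 0L
  out
}
decode_status <- function(x) c("control", "case")[match(x, c("1", "2"))]
encode_status <- function(x) {
  out <- match(x, c("control", "case"))
  out[is.na(out)] <- -9L
  out
}
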