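#' Fixed-width genomic bin grid
#'
#' Tiles each autosome with half-open bins of `width_bp` starting at
#' position 1 (1-based: bin `k` covers `[(k-1)*width + 1, k*width]`), out to
#' the last mapped SNP of that chromosome.
#'
#' @param variants Variant tibble (`chrom`, `pos_bp`) or a [geno_matrix()].
#' @param width_bp Bin width in bp (default 500 kb).
#' @return Tibble `(bin_id, chrom, start_bp, end_bp)`.
#' @export
bin_grid <- function(variants, width_bp = 500000) {
  if (inherits(variants, "geno_matrix")) variants <- variants$variants
  stopifnot(width_bp >= 1)
  last <- dplyr::summarise(dplyr::group_by(variants, .data$chrom),
                           last_bp = max(.data$pos_bp), .groups = "drop")
  grid <- tidyr::unnest(
    dplyr::mutate(last, k = purrr::map(.data$last_bp,
                                       ~seq_len(ceiling(.x / width_bp)))),
    "k"
  )
  dplyr::transmute(
    grid,
    bin_id = paste0(.data$chrom, ":", .data$k),
    chrom = .data$chrom,
    start_bp = as.integer((.data$k - 1) * width_bp + 1),
    end_bp = as.integer(.data$k * width_bp)
  )
}

#' Assign ROH segments to bins by midpoint
#'
#' Each segment's midpoint `floor((start_bp + end_bp) / 2)` places it in
#' exactly one bin; a sample is exposed at a bin iff at least one of its
#' segments' midpoints falls there (indicator, not a count). Samples without
#' segments simply contribute no rows.
#'
#' @param segments Segment tibble from [call_roh()].
#' @param grid A [bin_grid()] covering every segment chromosome.
#' @return Tibble of distinct `(sample_id, bin_id)` exposures.
#' @export
assign_bins <- function(segments, grid) {
  width_bp <- grid$end_bp[1] - grid$start_bp[1] + 1L
  mid <- floor((as.numeric(segments$start_bp) + segments$end_bp) / 2)
  exposure <- tibble::tibble(
    sample_id = segments$sample_id,
    bin_id = paste0(segments$chrom, ":", ceiling(mid / width_bp))
  )
  missing_bins <- setdiff(unique(exposure$bin_id), grid$bin_id)
  if (length(missing_bins)) {
    stop("grid does not cover bin(s): ",
         paste(utils::head(missing_bins, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(exposure)
}

#' Per-bin ROH association scan within one study
#'
#' Tests each bin's exposure indicator against case-control status with the
#' same covariate-adjusted logistic model as the burden tests. Bins with
#' fewer than `min_exposed` exposed samples overall, or with all exposure in
#' one arm (separation), are reported as skipped with a reason rather than
#' fitted.
#'
#' @param samples Sample sheet with `sample_id`, `status` and the covariate
#'   columns (every sample in the study, exposed or not).
#' @param exposures Output of [assign_bins()].
#' @param grid The [bin_grid()] used.
#' @param covariates Covariate columns, as in [test_burden()].
#' @param min_exposed Minimum exposed samples for a bin to be testable.
#' @return Tibble of class `roh_binscan`: one row per bin with `(bin_id,
#'   chrom, start_bp, end_bp, n_exposed, beta, se, p, status, reason)`;
#'   `status` is `"tested"` or `"skipped"`.
#' @export
test_bins <- function(samples, exposures, grid,
                      covariates = c("age", "sex", "missing_fraction"),
                      min_exposed = 5) {
  stopifnot(all(c("sample_id", "status") %in% names(samples)))
  y <- encode_binary(samples$status)
  cov <- if (length(covariates)) {
    samples[, intersect(covariates, names(samples)), drop = FALSE]
  } else NULL

  one_bin <- function(bin_id) {
    exposed <- samples$sample_id %in%
      exposures$sample_id[exposures$bin_id == bin_id]
    n_exposed <- sum(exposed)
    if (n_exposed == 0) {
      return(tibble::tibble(n_exposed = 0L, beta = NA_real_, se = NA_real_,
                            p = NA_real_, status = "skipped",
                            reason = "unexposed"))
    }
    if (n_exposed < min_exposed) {
      return(tibble::tibble(n_exposed = n_exposed, beta = NA_real_,
                            se = NA_real_, p = NA_real_, status = "skipped",
                            reason = "fewer than min_exposed"))
    }
    if (sum(exposed & y == 1) == 0 || sum(exposed & y == 0) == 0) {
      return(tibble::tibble(n_exposed = n_exposed, beta = NA_real_,
                            se = NA_real_, p = NA_real_, status = "skipped",
                            reason = "one-arm exposure"))
    }
    res <- fit_logistic(y, as.numeric(exposed), covariates = cov,
                        exposure_name = bin_id)
    tibble::tibble(n_exposed = n_exposed, beta = res$beta, se = res$se,
                   p = res$p,
                   status = if (res$converged) "tested" else "not_converged",
                   reason = NA_character_)
  }

  out <- dplyr::bind_cols(
    grid,
    dplyr::bind_rows(lapply(grid$bin_id, one_bin))
  )
  class(out) <- c("roh_binscan", class(out))
  out
}
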