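#' Combine per-study estimates by meta-analysis
#'
#' `dl_random_effects()` implements DerSimonian-Laird random effects:
#' fixed-effect weights \eqn{w_i = 1/se_i^2} give the Cochran statistic
#' \eqn{Q = \sum w_i (\beta_i - \beta_{FE})^2}; the between-study variance is
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))}; the
#' combined estimate re-weights with \eqn{w_i^* = 1/(se_i^2 + \tau^2)}.
#' `ivw_fixed_effects()` is the inverse-variance fixed-effect combination
#' (the scheme used by effect-size meta-analysis of genome-wide scans); it
#' reports the same heterogeneity statistics. In both,
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \cdot 100} and the heterogeneity p-value
#' comes from the upper tail of \eqn{\chi^2_{k-1}} at Q. Whenever
#' \eqn{Q \le k-1} the random-effects result reduces exactly to the
#' fixed-effect one.
#'
#' @param estimates Data frame with columns `study`, `beta`, `se` (one row
#'   per study, `se > 0`), e.g. built from [glance()] of per-study fits.
#' @return Object of class `roh_meta` with `beta`, `se`, `p` (two-sided
#'   normal), `k`, `Q`, `tau2`, `i2` (percent), `p_het`, `method` and the
#'   input `studies`. [tidy()] returns per-study rows with weights,
#'   [glance()] the one-row combined summary.
#' @examples
#' est <- tibble::tibble(study = c("A", "B"), beta = c(1, 3), se = c(1, 1))
#' glance(dl_random_effects(est))  # beta 2, tau2 1, I2 50%
#' glance(ivw_fixed_effects(est))  # beta 2, se 1/sqrt(2)
#' @export
dl_random_effects <- function(estimates) {
  e <- check_estimates(estimates)
  het <- heterogeneity(e$beta, e$se)
  w_star <- 1 / (e$se^2 + het$tau2)
  beta <- sum(w_star * e$beta) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  new_meta("dl", beta, se, e, het, w_star)
}

#' @rdname dl_random_effects
#' @export
ivw_fixed_effects <- function(estimates) {
  e <- check_estimates(estimates)
  het <- heterogeneity(e$beta, e$se)
  w <- 1 / e$se^2
  beta <- sum(w * e$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  new_meta("ivw", beta, se, e, het, w)
}

check_estimates <- function(estimates) {
  e <- tibble::as_tibble(estimates)
  stopifnot(all(c("beta", "se") %in% names(e)))
  if (!"study" %in% names(e)) e$study <- as.character(seq_len(nrow(e)))
  if (nrow(e) == 0) stop("no study estimates to combine", call. = FALSE)
  stopifnot(all(is.finite(e$beta)), all(is.finite(e$se)), all(e$se > 0))
  e
}

heterogeneity <- function(beta, se) {
  k <- length(beta)
  w <- 1 / se^2
  beta_fe <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - beta_fe)^2)
  df <- k - 1
  tau2 <- if (df == 0) 0 else {
    c_w <- sum(w) - sum(w^2) / sum(w)
    max(0, (q - df) / c_w)
  }
  i2 <- if (q > df && q > 0) max(0, (q - df) / q) * 100 else 0
  p_het <- if (df >= 1) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_
  list(k = k, Q = q, tau2 = tau2, i2 = i2, p_het = p_het)
}

new_meta <- function(method, beta, se, e, het, weights) {
  structure(
    list(
      method = method, beta = beta, se = se,
      p = 2 * stats::pnorm(-abs(beta / se)),
      k = het$k, Q = het$Q, tau2 = het$tau2, i2 = het$i2, p_het = het$p_het,
      studies = dplyr::mutate(e, weight = weights / sum(weights))
    ),
    class = "roh_meta"
  )
}

#' @export
print.roh_meta <- function(x, ...) {
  cat("<roh_meta> ", if (x$method == "dl") "DerSimonian-Laird random effects"
      else "inverse-variance fixed effects",
      ", k = ", x$k, "\n", sep = "")
  cat(sprintf("  beta = %.4g (se %.4g), p = %.3g\n", x$beta, x$se, x$p))
  cat(sprintf("  Q = %.4g, tau2 = %.4g, I2 = %.1f%%, p_het = %.3g\n",
              x$Q, x$tau2, x$i2, x$p_het))
  invisible(x)
}

#' @rdname dl_random_effects
#' @param x A `roh_meta` object.
#' @param ... Unused.
#' @export
tidy.roh_meta <- function(x, ...) {
  x$studies
}

#' @rdname dl_random_effects
#' @export
glance.roh_meta <- function(x, ...) {
  tibble::tibble(method = x$method, beta = x$beta, se = x$se, p = x$p,
                 k = x$k, Q = x$Q, tau2 = x$tau2, i2 = x$i2, p_het = x$p_het)
}

#' Leave-one-out meta-analysis
#'
#' Repeats the meta-analysis omitting each study in turn; useful for tracing
#' between-study heterogeneity to a single outlying study.
#'
#' @inheritParams dl_random_effects
#' @param method `"dl"` or `"ivw"`.
#' @return Tibble with one [glance()] row per omitted study, keyed by
#'   `omitted`.
#' @export
leave_one_out <- function(estimates, method = c("dl", "ivw")) {
  method <- match.arg(method)
  e <- check_estimates(estimates)
  if (nrow(e) < 2) stop("leave-one-out needs at least 2 studies", call. = FALSE)
  fun <- if (method == "dl") dl_random_effects else ivw_fixed_effects
  purrr::map_dfr(seq_len(nrow(e)), function(i) {
    dplyr::bind_cols(tibble::tibble(omitted = e$study[i]),
                     glance(fun(e[-i, , drop = FALSE])))
  })
}

#' Bonferroni multiple-testing control
#'
#' @param p_values Numeric vector of p-values.
#' @param n_tests Number of tests the family comprises (defaults to
#'   `length(p_values)`).
#' @param alpha Family-wise error rate.
#' @return List with `alpha_adjusted = alpha / n_tests` and a logical
#'   `significant` flag per p-value (strict `<`).
#' @export
bonferroni <- function(p_values, n_tests = length(p_values), alpha = 0.05) {
  stopifnot(n_tests >= 1)
  list(alpha_adjusted = alpha / n_tests,
       significant = p_values < alpha / n_tests)
}

#' Combine a per-study bin scan across studies
#'
#' Meta-analyses each bin's per-study estimates (default inverse-variance
#' fixed effects) over the bins tested in at least one study, and flags
#' Bonferroni significance over the number of combined bins.
#'
#' @param scans Named list of `roh_binscan` tibbles, one per study.
#' @param method `"ivw"` or `"dl"`.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return Tibble of class `roh_binscan_meta`: one row per combinable bin
#'   with `(bin_id, chrom, start_bp, end_bp, k, beta, se, p, i2, p_het,
#'   bonferroni_significant)`, ordered by `p`.
#' @export
combine_bin_scans <- function(scans, method = c("ivw", "dl"), alpha = 0.05) {
  method <- match.arg(method)
  fun <- if (method == "ivw") ivw_fixed_effects else dl_random_effects
  stopifnot(length(scans) >= 1)
  if (is.null(names(scans))) names(scans) <- paste0("study", seq_along(scans))
  all_rows <- dplyr::bind_rows(scans, .id = "study")
  tested <- dplyr::filter(all_rows, .data$status == "tested")
  if (nrow(tested) == 0) {
    out <- tibble::tibble(bin_id = character(), chrom = integer(),
                          start_bp = integer(), end_bp = integer(),
                          k = integer(), beta = numeric(), se = numeric(),
                          p = numeric(), i2 = numeric(), p_het = numeric(),
                          bonferroni_significant = logical())
    class(out) <- c("roh_binscan_meta", class(out))
    return(out)
  }
  combined <- dplyr::group_modify(
    dplyr::group_by(tested, .data$bin_id, .data$chrom, .data$start_bp,
                    .data$end_bp),
    function(d, key) {
      g <- glance(fun(d[, c("study", "beta", "se")]))
      g[, c("k", "beta", "se", "p", "i2", "p_het")]
    }
  )
  combined <- dplyr::ungroup(combined)
  bf <- bonferroni(combined$p, n_tests = nrow(combined), alpha = alpha)
  combined$bonferroni_significant <- bf$significant
  out <- dplyr::arrange(combined, .data$p)
  class(out) <- c("roh_binscan_meta", class(out))
  out
}
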