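#' Covariate-adjusted logistic association
#'
#' Fits `status ~ exposure + covariates` by maximum likelihood (iteratively
#' reweighted least squares, log-likelihood tolerance 1e-8, at most 50
#' iterations) and reports the Wald estimate, standard error and two-sided
#' p-value for the exposure. Constant covariate columns are dropped with a
#' warning (this is what handles a single-sex study, where the sex column
#' carries no information). Non-convergence or detected separation is
#' reported via `converged = FALSE` rather than an error.
#'
#' @param y Binary outcome: logical, 0/1, or `"case"`/`"control"`.
#' @param exposure Numeric exposure vector (e.g. per-sample FROH).
#' @param covariates Optional numeric matrix or data frame of adjustment
#'   covariates.
#' @param exposure_name Label recorded in the result.
#' @return Object of class `roh_assoc` with elements `exposure_name`, `beta`,
#'   `se`, `p`, `n_case`, `n_control`, `converged`, `dropped_covariates` and
#'   the underlying `fit`. [tidy()] gives the full coefficient table,
#'   [glance()] the one-row summary.
#' @examples
#' # 2x2 table: 10 exposed cases, 20 exposed controls, 30/40 unexposed
#' y <- rep(c(1, 0, 1, 0), c(10, 20, 30, 40))
#' x <- rep(c(1, 1, 0, 0), c(10, 20, 30, 40))
#' glance(fit_logistic(y, x))  # beta = log(10*40/(20*30))
#' @export
fit_logistic <- function(y, exposure, covariates = NULL,
                         exposure_name = "exposure") {
  y <- encode_binary(y)
  stopifnot(length(y) == length(exposure))
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; cannot fit", call. = FALSE)
  }
  if (!all(is.finite(exposure))) stop("non-finite exposure", call. = FALSE)
  if (stats::var(exposure) == 0) {
    stop("zero-variance exposure", call. = FALSE)
  }

  df <- data.frame(.y = y, .exposure = exposure)
  dropped <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    for (nm in names(covariates)) {
      col <- covariates[[nm]]
      if (!is.numeric(col)) col <- as.numeric(as.factor(col))
      if (length(unique(col[!is.na(col)])) < 2) {
        dropped <- c(dropped, nm)
      } else {
        df[[nm]] <- col
      }
    }
    if (length(dropped)) {
      warning("dropping constant covariate(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
  }

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- stats::coef(fit)[".exposure"]
  se <- sqrt(diag(stats::vcov(fit))[".exposure"])
  converged <- isTRUE(fit$converged) && !separation && is.finite(se)
  structure(
    list(
      exposure_name = exposure_name,
      beta = unname(est),
      se = unname(se),
      p = unname(2 * stats::pnorm(-abs(est / se))),
      n_case = sum(y == 1), n_control = sum(y == 0),
      converged = converged,
      separation = separation,
      dropped_covariates = dropped,
      fit = fit
    ),
    class = "roh_assoc"
  )
}

encode_binary <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    stopifnot(all(y %in% c("case", "control")))
    as.integer(y == "case")
  } else {
    stopifnot(all(y %in% c(0, 1, FALSE, TRUE)))
    as.integer(y)
  }
}

#' @export
print.roh_assoc <- function(x, ...) {
  cat("<roh_assoc> ", x$exposure_name,
      sprintf(": beta = %.4g, se = %.4g, p = %.3g", x$beta, x$se, x$p),
      "\n  ", x$n_case, " cases / ", x$n_control, " controls",
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `roh_assoc` object.
#' @param ... Unused.
#' @export
tidy.roh_assoc <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = sub("^\\.exposure$", x$exposure_name, rownames(sm)),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
}

#' @rdname fit_logistic
#' @export
glance.roh_assoc <- function(x, ...) {
  tibble::tibble(
    exposure_name = x$exposure_name, beta = x$beta, se = x$se, p = x$p,
    n_case = x$n_case, n_control = x$n_control, converged = x$converged
  )
}

#' Burden association within one study
#'
#' Computes homozygosity profiles under the requested filters and regresses
#' case-control status on the chosen burden metric with the standard
#' covariate set. The coefficient is the log-odds per unit of the metric, so
#' for FROH `exp(0.001 * beta) - 1` is the relative risk increase per 0.1%
#' of the autosome in ROH.
#'
#' @param g A [geno_matrix()] after QC, with phenotypes attached (`status`
#'   plus the covariate columns).
#' @param segments Segments from [call_roh()] on `g` (only needed for
#'   `metric = "froh"`, but harmlessly required for both).
#' @param metric `"froh"` or `"f3"`.
#' @param covariates Character vector of sample-sheet columns to adjust for;
#'   names absent from the sheet are an error, constant columns are dropped
#'   with a warning by [fit_logistic()].
#' @param pcs Optional PC score tibble from [compute_pcs()]; joined by
#'   `sample_id` and added to the covariates.
#' @param exclude_chroms Chromosomes excluded from the metric.
#' @param exclude_samples Sample ids removed before fitting (e.g. known
#'   somatic-deletion carriers).
#' @param subset_studies Optional study labels; only samples from these
#'   studies are kept (e.g. prospective-only sensitivity runs).
#' @return A `roh_assoc` object.
#' @export
test_burden <- function(g, segments, metric = c("froh", "f3"),
                        covariates = c("age", "sex", "missing_fraction"),
                        pcs = NULL, exclude_chroms = integer(),
                        exclude_samples = character(),
                        subset_studies = NULL) {
  metric <- match.arg(metric)
  keep <- !(g$samples$sample_id %in% exclude_samples)
  if (!is.null(subset_studies)) {
    stopifnot("study" %in% names(g$samples))
    keep <- keep & g$samples$study %in% subset_studies
  }
  g <- subset_geno(g, sample_idx = which(keep))
  segments <- segments[segments$sample_id %in% g$samples$sample_id, ,
                       drop = FALSE]
  if (!any(g$samples$status == "case", na.rm = TRUE) ||
      !any(g$samples$status == "control", na.rm = TRUE)) {
    stop("need both cases and controls after filtering", call. = FALSE)
  }

  prof <- profile_cohort(g, segments, exclude_chroms = exclude_chroms)
  tbl <- dplyr::left_join(g$samples, prof, by = "sample_id",
                          suffix = c(".sheet", ""))
  if (!is.null(pcs)) {
    tbl <- dplyr::left_join(tbl, pcs, by = "sample_id")
    covariates <- c(covariates, setdiff(names(pcs), "sample_id"))
  }
  missing_cov <- setdiff(covariates, names(tbl))
  if (length(missing_cov)) {
    stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  fit_logistic(tbl$status, tbl[[metric]],
               covariates = tbl[, covariates, drop = FALSE],
               exposure_name = metric)
}
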