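#' Forest plot of a meta-analysis
#'
#' Per-study estimates with 95% Wald intervals and the combined estimate.
#'
#' @param object A `roh_meta` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roh_meta <- function(object, ...) {
  st <- object$studies
  df <- dplyr::bind_rows(
    tibble::tibble(study = st$study, beta = st$beta, se = st$se,
                   combined = FALSE),
    tibble::tibble(study = "combined", beta = object$beta, se = object$se,
                   combined = TRUE)
  )
  df$study <- factor(df$study, levels = rev(df$study))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$study,
                                   colour = .data$combined)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                                          xmax = .data$beta + 1.96 * .data$se),
                             show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey30",
                                            "TRUE" = "firebrick")) +
    ggplot2::labs(x = "log-odds (95% CI)", y = NULL,
                  title = sprintf("%s meta-analysis: I² = %.1f%%",
                                  toupper(object$method), object$i2)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a combined bin scan
#'
#' @param object A `roh_binscan_meta` tibble from [combine_bin_scans()] or
#'   [run_bin_scan()].
#' @param alpha Family-wise error rate for the Bonferroni line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roh_binscan_meta <- function(object, alpha = 0.05, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$chrom,
                       .data$start_bp)
  df$x <- seq_len(nrow(df))
  thr <- -log10(alpha / nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -log10(.data$p),
                                   colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(show.legend = FALSE, size = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_colour_manual(values = c("0" = "grey40", "1" = "grey70")) +
    ggplot2::labs(x = "bin (genome order)",
                  y = expression(-log[10](italic(p))),
                  title = "ROH bin scan") +
    ggplot2::theme_minimal()
}

#' Distribution of FROH by case-control status
#'
#' @param profiles Output of [profile_cohort()].
#' @param samples Sample sheet with `sample_id` and `status`.
#' @return A ggplot.
#' @export
plot_froh <- function(profiles, samples) {
  df <- dplyr::inner_join(profiles, samples[, c("sample_id", "status")],
                          by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$froh,
                                   fill = .data$status)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "FROH (% of autosome)", y = "density") +
    ggplot2::theme_minimal()
}
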