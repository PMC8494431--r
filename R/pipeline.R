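#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file holding one) with:
#' \describe{
#'   \item{studies}{List of study entries: `name`, `prefix` (PLINK path
#'     prefix), `dialect` (`"binary"`/`"text"`), optional `pheno` (phenotype
#'     table path), `single_sex`, `subtype`.}
#'   \item{analyses}{Subset of `"burden_froh"`, `"burden_f3"`, `"bin_scan"`.}
#'   \item{qc, roh}{Optional overrides for [qc_thresholds()] /
#'     [roh_params()].}
#'   \item{covariates}{Covariate columns for the logistic models.}
#'   \item{n_pcs}{Number of ancestry PCs to compute and adjust for (0 =
#'     none).}
#'   \item{sensitivity}{Optional `exclude_chroms`, `exclude_samples_file`
#'     (one id per line), `subset_studies`.}
#'   \item{bin_width_bp, min_exposed}{Bin-scan settings.}
#'   \item{meta_method}{`burden` (`"dl"`) and `bins` (`"ivw"`) overrides.}
#'   \item{outdir}{Output directory.}
#'   \item{seed}{Integer seed recorded in the log.}
#' }
#' Validation happens before any compute; missing files are an error here.
#'
#' @param config Named list or path to a YAML file.
#' @return The normalised configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$studies) || length(config$studies) < 1) {
    stop("config needs at least one study entry", call. = FALSE)
  }
  for (st in config$studies) {
    if (is.null(st$name) || is.null(st$prefix)) {
      stop("each study entry needs `name` and `prefix`", call. = FALSE)
    }
    dialect <- st$dialect %||% "binary"
    exts <- if (dialect == "binary") c(".bed", ".bim", ".fam")
            else c(".ped", ".map")
    for (ext in exts) {
      if (!file.exists(paste0(st$prefix, ext))) {
        stop("study ", st$name, ": missing file ", paste0(st$prefix, ext),
             call. = FALSE)
      }
    }
    if (!is.null(st$pheno) && !file.exists(st$pheno)) {
      stop("study ", st$name, ": missing phenotype file ", st$pheno,
           call. = FALSE)
    }
  }
  config$analyses <- config$analyses %||%
    c("burden_froh", "burden_f3", "bin_scan")
  bad <- setdiff(config$analyses,
                 c("burden_froh", "burden_f3", "bin_scan"))
  if (length(bad)) stop("unknown analysis: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  config$covariates <- config$covariates %||%
    c("age", "sex", "missing_fraction")
  config$n_pcs <- config$n_pcs %||% 0
  config$bin_width_bp <- config$bin_width_bp %||% 500000
  config$min_exposed <- config$min_exposed %||% 5
  config$meta_method <- utils::modifyList(list(burden = "dl", bins = "ivw"),
                                          config$meta_method %||% list())
  config$sensitivity <- config$sensitivity %||% list()
  config$outdir <- config$outdir %||% "rohburden_out"
  config$seed <- config$seed %||% 1L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipe_log <- function(state, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  message(msg)
  cat(msg, "\n", file = state$logfile, append = TRUE)
}

# load one study, run QC and the (cached) ROH caller
prepare_study <- function(st, config, state) {
  qc <- do.call(qc_thresholds, config$qc %||% list())
  rp <- do.call(roh_params, config$roh %||% list())

  g <- read_genotypes(st$prefix, st$dialect %||% "binary")
  if (!is.null(st$pheno)) g <- attach_phenotypes(g, read_phenotypes(st$pheno))
  pipe_log(state, "[", st$name, "] loaded ", n_samples(g), " samples x ",
           n_variants(g), " variants")

  vqc <- apply_variant_qc(g, qc)
  sqc <- apply_sample_qc(vqc$genotypes, qc)
  g <- sqc$genotypes
  qc_report <- dplyr::bind_rows(vqc$report, sqc$report)
  pipe_log(state, "[", st$name, "] QC dropped ",
           sum(vqc$report$n_dropped), " variants, ",
           sum(sqc$report$n_dropped), " samples; ", n_samples(g),
           " samples x ", n_variants(g), " variants remain")

  cache_dir <- file.path(config$outdir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- rlang::hash(list(st$prefix, qc, rp))
  cache_file <- file.path(cache_dir,
                          paste0(st$name, "_segments_", key, ".tsv"))
  if (file.exists(cache_file)) {
    segments <- readr::read_tsv(cache_file, show_col_types = FALSE)
    segments$sample_id <- as.character(segments$sample_id)
    pipe_log(state, "[", st$name, "] reused cached segments (",
             nrow(segments), ")")
  } else {
    segments <- call_roh(g, rp)
    readr::write_tsv(segments, cache_file)
    pipe_log(state, "[", st$name, "] called ", nrow(segments),
             " ROH segments")
  }

  pcs <- NULL
  if (config$n_pcs > 0) {
    pcs <- compute_pcs(g, k = config$n_pcs)
    pipe_log(state, "[", st$name, "] computed ", config$n_pcs, " PCs")
  }
  list(name = st$name, genotypes = g, segments = segments, pcs = pcs,
       qc_report = qc_report, single_sex = isTRUE(st$single_sex))
}

read_exclude_samples <- function(sens) {
  if (is.null(sens$exclude_samples_file)) return(character())
  readLines(sens$exclude_samples_file)
}

#' Run the burden analyses end to end
#'
#' Per study: load, QC, call ROH, profile, and fit the covariate-adjusted
#' burden model for each requested metric; then combine across studies with
#' random-effects meta-analysis. Writes per-study association tables, the
#' combined meta table, a study-by-status profile summary and a structured
#' log under `config$outdir`.
#'
#' @param config See [validate_config()].
#' @return Invisibly, a list with `per_study` (tibble of study-level
#'   estimates), `meta` (named list of `roh_meta` objects per metric),
#'   `summary` (profile summary tibble) and `qc_reports`.
#' @export
run_burden <- function(config) {
  config <- validate_config(config)
  metrics <- intersect(c("froh", "f3"),
                       sub("burden_", "",
                           grep("^burden_", config$analyses, value = TRUE)))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- list(logfile = file.path(config$outdir, "run.log"))
  if (length(metrics) == 0) {
    pipe_log(state, "no burden analyses requested; nothing to do")
    return(invisible(NULL))
  }
  sens <- config$sensitivity
  exclude_chroms <- as.integer(sens$exclude_chroms %||% integer())
  exclude_samples <- read_exclude_samples(sens)

  studies <- lapply(config$studies, prepare_study, config = config,
                    state = state)

  per_study <- list()
  summaries <- list()
  for (stu in studies) {
    prof <- profile_cohort(stu$genotypes, stu$segments,
                           exclude_chroms = exclude_chroms)
    summaries[[stu$name]] <- dplyr::mutate(
      summarize_profiles(prof, stu$genotypes$samples), study = stu$name,
      .before = 1
    )
    for (metric in metrics) {
      res <- test_burden(
        stu$genotypes, stu$segments, metric = metric,
        covariates = config$covariates, pcs = stu$pcs,
        exclude_chroms = exclude_chroms,
        exclude_samples = exclude_samples,
        subset_studies = sens$subset_studies
      )
      per_study[[paste(stu$name, metric)]] <- dplyr::mutate(
        glance(res), study = stu$name, metric = metric, .before = 1
      )
      pipe_log(state, "[", stu$name, "] ", metric,
               sprintf(": beta %.4g (se %.4g), p %.3g", res$beta, res$se,
                       res$p))
    }
  }
  per_study <- dplyr::bind_rows(per_study)
  summary_tbl <- dplyr::bind_rows(summaries)

  meta <- list()
  fun <- if (config$meta_method$burden == "dl") dl_random_effects
         else ivw_fixed_effects
  for (metric in metrics) {
    est <- dplyr::filter(per_study, .data$metric == !!metric)
    meta[[metric]] <- fun(est[, c("study", "beta", "se")])
    pipe_log(state, "meta [", metric, "]",
             sprintf(": beta %.4g (se %.4g), p %.3g, I2 %.1f%%",
                     meta[[metric]]$beta, meta[[metric]]$se,
                     meta[[metric]]$p, meta[[metric]]$i2))
  }

  readr::write_tsv(per_study,
                   file.path(config$outdir, "burden_per_study.tsv"))
  readr::write_tsv(dplyr::bind_rows(lapply(meta, glance), .id = "metric"),
                   file.path(config$outdir, "burden_meta.tsv"))
  readr::write_tsv(summary_tbl,
                   file.path(config$outdir, "profile_summary.tsv"))
  invisible(list(per_study = per_study, meta = meta, summary = summary_tbl,
                 qc_reports = lapply(studies, `[[`, "qc_report")))
}

#' Run the regional 500-kb bin scan end to end
#'
#' Per study: load, QC, call ROH, assign segment midpoints to the bin grid
#' and test each bin; then combine bins across studies (inverse-variance
#' fixed effects by default) with a Bonferroni flag over the combined bins.
#' Writes the combined per-bin table and a rank-ordered top-bins listing.
#'
#' @param config See [validate_config()].
#' @param top_n Rows in the top-bins listing.
#' @return Invisibly, a list with `combined` (per-bin meta table of class
#'   `roh_binscan_meta`), `per_study` (list of `roh_binscan` tibbles) and
#'   `alpha_adjusted`.
#' @export
run_bin_scan <- function(config, top_n = 10) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- list(logfile = file.path(config$outdir, "run.log"))
  if (!"bin_scan" %in% config$analyses) {
    pipe_log(state, "bin_scan not in the analysis list; nothing to do")
    return(invisible(NULL))
  }
  studies <- lapply(config$studies, prepare_study, config = config,
                    state = state)

  # one grid spanning all studies so bin ids line up
  all_variants <- dplyr::bind_rows(
    lapply(studies, function(s) s$genotypes$variants[, c("chrom", "pos_bp")])
  )
  grid <- bin_grid(all_variants, width_bp = config$bin_width_bp)

  scans <- list()
  for (stu in studies) {
    prof <- profile_cohort(stu$genotypes, stu$segments)
    sheet <- dplyr::left_join(stu$genotypes$samples,
                              prof[, c("sample_id", "missing_fraction")],
                              by = "sample_id", suffix = c(".sheet", ""))
    if (!is.null(stu$pcs)) {
      sheet <- dplyr::left_join(sheet, stu$pcs, by = "sample_id")
    }
    covs <- c(config$covariates,
              if (!is.null(stu$pcs)) setdiff(names(stu$pcs), "sample_id"))
    exposures <- assign_bins(stu$segments, grid)
    scans[[stu$name]] <- suppressWarnings(
      test_bins(sheet, exposures, grid, covariates = covs,
                min_exposed = config$min_exposed)
    )
    pipe_log(state, "[", stu$name, "] bin scan: ",
             sum(scans[[stu$name]]$status == "tested"), " of ", nrow(grid),
             " bins testable")
  }

  combined <- combine_bin_scans(scans, method = config$meta_method$bins)
  alpha_adj <- if (nrow(combined)) 0.05 / nrow(combined) else NA_real_
  pipe_log(state, "combined ", nrow(combined), " bins; Bonferroni alpha ",
           signif(alpha_adj, 3), "; ",
           sum(combined$bonferroni_significant), " significant")

  readr::write_tsv(combined, file.path(config$outdir, "bin_scan_meta.tsv"))
  readr::write_tsv(utils::head(combined, top_n),
                   file.path(config$outdir, "bin_scan_top.tsv"))
  invisible(list(combined = combined, per_study = scans,
                 alpha_adjusted = alpha_adj))
}
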