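# Orchestration: a single entry point that runs the tabular stages
# (summaries, per-biomarker OLS with leave-one-out validation, survival
# index, diagnostic test, partial-correlation network, predictive curve)
# over a synthetic or user-supplied cohort, and readers for the published
# supplementary-table layouts.

#' Read a long-format timecourse CSV
#'
#' Expected columns (after mapping): `animal_id`, `age_days`, `biomarker`,
#' `value`.  The published raw-timecourse table can be read by supplying a
#' schema mapping its column names onto these.
#'
#' @param path CSV file; lines starting with `#` are treated as comments.
#' @param schema named character vector mapping target names to the file's
#'   column names, e.g. `c(animal_id = "worm", age_days = "age", ...)`.
#' @return data.frame `(animal_id, age_days, biomarker, value)`.
#' @export
read_timecourse_csv <- function(path, schema = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  want <- c("animal_id", "age_days", "biomarker", "value")
  if (!is.null(schema)) {
    for (tgt in names(schema)) names(df)[names(df) == schema[[tgt]]] <- tgt
  }
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop("timecourse table lacks column(s): ",
         paste(missing_cols, collapse = ", "),
         " (supply a schema mapping)")
  df[, want]
}

#' Read a per-animal summary CSV
#'
#' Expected columns: `animal_id`, `dataset_id`, `lifespan_days`, then
#' `<biomarker>_mean` / `<biomarker>_slope` summary columns.
#'
#' @inheritParams read_timecourse_csv
#' @return data.frame.
#' @export
read_summary_csv <- function(path, schema = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (tgt in names(schema)) names(df)[names(df) == schema[[tgt]]] <- tgt
  }
  need <- c("animal_id", "lifespan_days")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("summary table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Replicate the published summary-table regressions
#'
#' Given a per-animal summary table (the layout of the published per-animal
#' summary data), runs the standard models: each biomarker's day-window
#' mean/slope OLS against lifespan with leave-one-out validation, and the
#' seven-predictor survival prediction index where all its columns are
#' present.
#'
#' @param summaries data.frame from [read_summary_csv()].
#' @param models named list of predictor-column character vectors; default:
#'   every `<biomarker>_mean`/`_slope` pair plus singleton slopes.
#' @return named list of [ols_predict()] results (plus
#'   `survival_index` when computable) and `mean_lifespan`.
#' @export
replicate_published_analysis <- function(summaries, models = NULL) {
  y <- summaries$lifespan_days
  cols <- setdiff(names(summaries),
                  c("animal_id", "dataset_id", "lifespan_days"))
  if (is.null(models)) {
    bms <- unique(sub("_(mean|slope)$", "", cols))
    models <- list()
    for (b in bms) {
      pair <- intersect(paste0(b, c("_mean", "_slope")), cols)
      models[[b]] <- pair
    }
  }
  out <- lapply(models, function(pr) {
    keep <- stats::complete.cases(summaries[, pr, drop = FALSE]) & !is.na(y)
    ols_predict(summaries[keep, pr, drop = FALSE], y[keep])
  })
  spi_cols <- c("length_mean", "length_slope", "motion_mean", "motion_slope",
                "texture_mean", "texture_slope", "autofluorescence_slope")
  if (all(spi_cols %in% cols)) {
    keep <- stats::complete.cases(summaries[, spi_cols]) & !is.na(y)
    out$survival_index <-
      survival_prediction_index(summaries[keep, ], y[keep])
  }
  out$mean_lifespan <- mean(y, na.rm = TRUE)
  out
}

#' Pipeline configuration
#'
#' @param cohort optional list with `animals` and `timecourses` (as from
#'   [generate_cohort()] or the readers); if `NULL`, a synthetic cohort is
#'   generated from `cohort_config`.
#' @param cohort_config a [cohort_config()] used when `cohort` is `NULL`.
#' @param window day-summary window.
#' @param alpha network independence threshold.
#' @param lambda_grid ridge penalty grid.
#' @param curve_ages ages for the predictive curve.
#' @param out_dir optional output directory for CSV artifacts.
#' @param seed master seed, propagated to all stochastic stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, cohort_config = NULL,
                            window = c(3, 7), alpha = 0.001,
                            lambda_grid = 10^seq(-4, 4, length.out = 50),
                            curve_ages = 2:7, out_dir = NULL, seed = 1) {
  if (is.null(cohort) && is.null(cohort_config))
    cohort_config <- wormspan::cohort_config(seed = seed)
  structure(list(cohort = cohort, cohort_config = cohort_config,
                 window = window, alpha = alpha, lambda_grid = lambda_grid,
                 curve_ages = curve_ages, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the tabular analysis pipeline
#'
#' Produces per-animal summaries, per-biomarker OLS models with
#' leave-one-out R-squared, a diagnostic dichotomization of the best
#' model, the survival prediction index (when its seven predictors exist),
#' a partial-correlation network over the summary columns plus lifespan,
#' and per-biomarker predictive curves.  When `out_dir` is set, writes
#' `summaries.csv`, `regressions.csv`, `network.csv` and `curve.csv`, each
#' with a header comment carrying the seed and a config hash.
#'
#' @param config a [pipeline_config()].
#' @return a results bundle (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- config$cohort %||% generate_cohort(config$cohort_config)
  animals <- cohort$animals
  tc <- cohort$timecourses
  summaries <- summarize_cohort(tc, config$window)
  m <- match(summaries$animal_id, animals$animal_id)
  y <- animals$lifespan_days[m]

  bms <- sort(unique(tc$biomarker))
  regressions <- list()
  for (b in bms) {
    prs <- intersect(paste0(b, c("_mean", "_slope")), names(summaries))
    feats <- summaries[, prs, drop = FALSE]
    ok <- stats::complete.cases(feats) & !is.na(y)
    regressions[[b]] <- ols_predict(feats[ok, , drop = FALSE], y[ok])
  }
  best <- names(regressions)[which.max(vapply(regressions, `[[`,
                                              numeric(1), "r2"))]
  diag_test <- dichotomize_test(regressions[[best]]$predictions,
                                regressions[[best]]$lifespans)

  spi_cols <- c("length_mean", "length_slope", "motion_mean", "motion_slope",
                "texture_mean", "texture_slope", "autofluorescence_slope")
  spi <- if (all(spi_cols %in% names(summaries))) {
    ok <- stats::complete.cases(summaries[, spi_cols]) & !is.na(y)
    survival_prediction_index(summaries[ok, ], y[ok])
  }

  net_cols <- setdiff(names(summaries), "animal_id")
  net_data <- cbind(summaries[net_cols], lifespan = y)
  network <- pc_skeleton(net_data, alpha = config$alpha)

  lif <- stats::setNames(animals$lifespan_days, animals$animal_id)
  curves <- lapply(bms, function(b)
    predictive_curve(tc, lif, ages = config$curve_ages,
                     biomarker = b, lambda_grid = config$lambda_grid))
  names(curves) <- bms

  kde <- lifespan_kde(animals$lifespan_days)

  bundle <- list(animals = animals, summaries = summaries,
                 regressions = regressions, best_model = best,
                 diagnostic = diag_test, survival_index = spi,
                 network = network, curves = curves, kde = kde,
                 seed = config$seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_hash <- sum(utils::head(utf8ToInt(paste(
      format(config$window), format(config$alpha),
      format(config$seed), collapse = "")), 64) * 7L) %% 100000L
    hdr <- sprintf("# wormspan pipeline; seed=%d; config=%05d",
                   config$seed, cfg_hash)
    wr <- function(df, file) {
      path <- file.path(config$out_dir, file)
      writeLines(hdr, path)
      suppressWarnings(utils::write.table(df, path, sep = ",",
                                          row.names = FALSE, append = TRUE,
                                          quote = FALSE))
      path
    }
    wr(summaries, "summaries.csv")
    reg_df <- do.call(rbind, lapply(names(regressions), function(b) {
      r <- regressions[[b]]
      data.frame(model = b, r2 = r$r2, loo_r2 = r$loo_r2,
                 f = r$f_statistic, p = r$p_value, n = r$n)
    }))
    wr(reg_df, "regressions.csv")
    net_path <- file.path(config$out_dir, "network.csv")
    writeLines(hdr, net_path)
    ncsv <- tempfile(); write_network_csv(network, ncsv)
    file.append(net_path, ncsv); unlink(ncsv)
    curve_df <- do.call(rbind, lapply(names(curves), function(b)
      cbind(biomarker = b, as.data.frame(curves[[b]]))))
    wr(curve_df, "curve.csv")
  }
  bundle
}
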