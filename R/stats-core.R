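# Tabular statistics: interval-midpoint lifespan estimation, day-window
# summaries, OLS with the F-test computed directly from R-squared,
# leave-one-out R-squared, the standardized-weight survival prediction
# index, above/below-average diagnostic tests, Gaussian KDE with Scott's
# rule, and two-sample Kolmogorov-Smirnov comparisons.

#' Interval-midpoint lifespan estimate
#'
#' Under a uniform prior on the time of death within the sampling interval,
#' the expected time of death is halfway between the last observation alive
#' and the first observation dead.
#'
#' @param ages observation ages (days), increasing.
#' @param alive logical: was the animal alive at each observation?
#' @return lifespan in days, or `NA` with attribute `censored = TRUE` when
#'   the animal was never observed dead (right-censored; excluded from
#'   regressions, retained in records).
#' @export
estimate_lifespan <- function(ages, alive) {
  stopifnot(length(ages) == length(alive))
  o <- order(ages)
  ages <- ages[o]; alive <- alive[o]
  if (!alive[1L]) stop("animal dead at first observation: no bracket")
  first_dead <- which(!alive)[1L]
  if (is.na(first_dead))
    return(structure(NA_real_, censored = TRUE))
  last_alive <- max(which(alive[seq_len(first_dead - 1L)]))
  (ages[last_alive] + ages[first_dead]) / 2
}

#' Day-window summary: mean level and least-squares slope
#'
#' @param ages,values the (age, value) series for one biomarker of one
#'   animal.
#' @param window closed day interval (default `c(3, 7)`).
#' @return list with `mean`, `slope` (units/day; `NA` when fewer than two
#'   in-window points), `n` (points used), `window`.
#' @export
window_summary <- function(ages, values, window = c(3, 7)) {
  keep <- ages >= window[1L] & ages <= window[2L] & !is.na(values)
  a <- ages[keep]; v <- values[keep]
  if (length(a) == 0L) stop("no in-window points")
  slope <- if (length(a) >= 2L && stats::sd(a) > 0) {
    sum((a - mean(a)) * (v - mean(v))) / sum((a - mean(a))^2)
  } else NA_real_
  list(mean = mean(v), slope = slope, n = length(a), window = window)
}

#' Summarize a long-format timecourse table into per-animal columns
#'
#' @param timecourses data.frame `(animal_id, age_days, biomarker, value)`.
#' @param window closed day interval.
#' @return wide data.frame: `animal_id` plus `<biomarker>_mean` and
#'   `<biomarker>_slope` columns.
#' @export
summarize_cohort <- function(timecourses, window = c(3, 7)) {
  sp <- split(timecourses, list(timecourses$animal_id, timecourses$biomarker),
              drop = TRUE)
  rows <- lapply(sp, function(d) {
    ws <- window_summary(d$age_days, d$value, window)
    data.frame(animal_id = d$animal_id[1L], biomarker = d$biomarker[1L],
               mean = ws$mean, slope = ws$slope, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  ids <- sort(unique(long$animal_id))
  out <- data.frame(animal_id = ids, stringsAsFactors = FALSE)
  for (b in sort(unique(long$biomarker))) {
    sub <- long[long$biomarker == b, ]
    m <- match(ids, sub$animal_id)
    out[[paste0(b, "_mean")]] <- sub$mean[m]
    out[[paste0(b, "_slope")]] <- sub$slope[m]
  }
  out
}

# standardized model matrix with collinearity check
standardize_predictors <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X); sdv <- apply(X, 2L, stats::sd)
  if (any(sdv == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X)[sdv == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  d <- svd(Z, nu = 0, nv = 0)$d
  if (d[length(d)] <= 0 || d[1L] / d[length(d)] > 1e8) {
    cors <- stats::cor(Z)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1L, ]
    stop(sprintf("collinear predictors (condition number > 1e8): %s and %s",
                 colnames(X)[worst[1L]], colnames(X)[worst[2L]]))
  }
  list(Z = Z, mean = mu, sd = sdv)
}

#' Ordinary least-squares lifespan regression
#'
#' Multivariate OLS of lifespan on biomarker summaries.  Coefficients are
#' reported in standardized (unit-free, SD) terms so their magnitudes are
#' directly comparable.  Significance comes from the F statistic computed
#' directly from R-squared, `F = R^2 df_error / ((1 - R^2) df_model)` with
#' `df_model = p` and `df_error = n - p - 1`, referred to the
#' `F(df_model, df_error)` distribution.
#'
#' @param features data.frame or matrix of predictors (rows with missing
#'   values are dropped and counted).
#' @param lifespans numeric response, days.
#' @param loo also compute the leave-one-out R-squared.
#' @return object of class `regression_result`: predictor names,
#'   standardized and raw coefficients, intercept, `r2`, `f_statistic`,
#'   `p_value`, `df_model`, `df_error`, `loo_r2`, `predictions` (raw
#'   scale), `n`, `n_dropped`.
#' @export
ols_predict <- function(features, lifespans, loo = TRUE) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(X) & !is.na(lifespans)
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]; y <- lifespans[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1 observations")
  st <- standardize_predictors(X)
  fit <- stats::lm.fit(cbind(1, st$Z), y)
  yhat <- y - fit$residuals
  r2 <- r_squared(y, yhat)
  dfm <- p; dfe <- n - p - 1L
  f <- r2 * dfe / ((1 - r2) * dfm)
  pval <- stats::pf(f, dfm, dfe, lower.tail = FALSE)
  beta_std <- fit$coefficients[-1L] * 1  # on SD-of-x scale, y raw
  beta_unitfree <- beta_std / stats::sd(y)  # fully unit-free weights
  loo_r2 <- if (loo) loo_r2_hat(st$Z, y) else NA_real_
  structure(list(predictors = colnames(X),
                 coefficients = stats::setNames(beta_unitfree, colnames(X)),
                 coefficients_per_day = stats::setNames(beta_std, colnames(X)),
                 intercept = fit$coefficients[1L],
                 r2 = r2, f_statistic = f, p_value = pval,
                 df_model = dfm, df_error = dfe, loo_r2 = loo_r2,
                 predictions = as.numeric(yhat), lifespans = y,
                 n = n, n_dropped = n_dropped),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS lifespan model: %d animals, %d predictor(s)\n",
              x$n, length(x$predictors)))
  cat(sprintf("  R2 = %.3f (l.o.o. %.3f), F(%d, %d) = %.2f, p = %.3g\n",
              x$r2, x$loo_r2, x$df_model, x$df_error, x$f_statistic,
              x$p_value))
  w <- sort(abs(x$coefficients), decreasing = TRUE)
  cat("  standardized weights (|w| desc):\n")
  for (nm in names(w))
    cat(sprintf("    %-24s %+ .3f\n", nm, x$coefficients[[nm]]))
  invisible(x)
}

# leave-one-out residuals via the hat-matrix shortcut; equals n refits
loo_r2_hat <- function(Z, y) {
  A <- cbind(1, Z)
  qr_ <- qr(A)
  h <- rowSums(qr.Q(qr_)^2)
  res <- stats::lm.fit(A, y)$residuals
  e_loo <- res / (1 - h)
  1 - sum(e_loo^2) / sum((y - mean(y))^2)
}

#' Leave-one-out cross-validated R-squared
#'
#' For each animal, an OLS model is fit on all other animals and used to
#' predict the held-out lifespan; the R-squared is computed from the
#' held-out residuals by the standard formula (it can be negative).
#' Computed via the exact hat-matrix identity, which equals n explicit
#' refits.
#'
#' @inheritParams ols_predict
#' @return scalar l.o.o. R-squared.
#' @export
loo_r2 <- function(features, lifespans) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(X) & !is.na(lifespans)
  X <- X[ok, , drop = FALSE]; y <- lifespans[ok]
  if (nrow(X) <= ncol(X) + 1L) stop("need n > p + 1 observations")
  st <- standardize_predictors(X)
  loo_r2_hat(st$Z, y)
}

#' The survival prediction index
#'
#' Standardized-weight OLS of lifespan on the seven early-adulthood
#' summaries: length mean and slope, motion mean and slope, texture mean
#' and slope, and autofluorescence slope.  Weights are reported in
#' descending absolute value.
#'
#' @param summaries data.frame containing columns `length_mean`,
#'   `length_slope`, `motion_mean`, `motion_slope`, `texture_mean`,
#'   `texture_slope`, `autofluorescence_slope`.
#' @param lifespans numeric, days.
#' @return a [ols_predict()] result with an extra element
#'   `weights_by_magnitude`.
#' @export
survival_prediction_index <- function(summaries, lifespans) {
  need <- c("length_mean", "length_slope", "motion_mean", "motion_slope",
            "texture_mean", "texture_slope", "autofluorescence_slope")
  missing_cols <- setdiff(need, colnames(summaries))
  if (length(missing_cols))
    stop("missing predictors: ", paste(missing_cols, collapse = ", "))
  res <- ols_predict(summaries[, need], lifespans)
  res$weights_by_magnitude <-
    res$coefficients[order(abs(res$coefficients), decreasing = TRUE)]
  res
}

#' Above/below-average diagnostic test of a lifespan prediction
#'
#' Dichotomizes predictions and observed lifespans about their respective
#' means; reports sensitivity and specificity for above-average longevity,
#' the ratio of mean lifespans between the above- and below-average
#' predicted cohorts, and a two-tailed Kolmogorov-Smirnov comparison of
#' the two cohorts' lifespan distributions.
#'
#' @param predictions predicted lifespans.
#' @param lifespans observed lifespans.
#' @return object of class `diagnostic_test`: list with `sensitivity`,
#'   `specificity`, `mean_ratio`, `ks_statistic`, `ks_p`, `table`.
#' @export
dichotomize_test <- function(predictions, lifespans) {
  stopifnot(length(predictions) == length(lifespans))
  hi_pred <- predictions > mean(predictions)
  hi_obs <- lifespans > mean(lifespans)
  if (min(table(hi_pred)) < 2L || min(table(hi_obs)) < 2L)
    stop("degenerate split: need at least 2 animals on each side of each mean")
  sens <- mean(hi_pred[hi_obs])
  spec <- mean(!hi_pred[!hi_obs])
  ks <- ks_compare(lifespans[hi_pred], lifespans[!hi_pred])
  structure(list(sensitivity = sens, specificity = spec,
                 mean_ratio = mean(lifespans[hi_pred]) /
                   mean(lifespans[!hi_pred]),
                 ks_statistic = ks$statistic, ks_p = ks$p,
                 table = table(predicted_above = hi_pred,
                               observed_above = hi_obs)),
            class = "diagnostic_test")
}

#' Gaussian kernel density estimate with Scott's rule-of-thumb bandwidth
#'
#' Kernel variance `sigma^2 * n^(-0.2)` where `sigma^2` is the sample
#' variance -- i.e. a kernel SD of `sd(x) * n^(-0.1)`.
#'
#' @param x sample (e.g. lifespans), `n >= 2` with positive variance.
#' @param n_grid evaluation grid size.
#' @param cut grid extension beyond the data range, in kernel SDs.
#' @return list with `x` (grid), `density`, `kernel_variance`, `kernel_sd`.
#' @export
lifespan_kde <- function(x, n_grid = 512, cut = 4) {
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::var(x) == 0) stop("zero variance sample")
  kv <- stats::var(x) * length(x)^(-0.2)
  ks <- sqrt(kv)
  d <- stats::density(x, bw = ks, kernel = "gaussian", n = n_grid,
                      from = min(x) - cut * ks, to = max(x) + cut * ks)
  list(x = d$x, density = d$y, kernel_variance = kv, kernel_sd = ks)
}

#' Two-sample two-tailed Kolmogorov-Smirnov comparison
#'
#' @param a,b numeric samples.
#' @return list with `statistic` and `p`.
#' @export
ks_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' R-squared with lifespan after controlling for other variables
#'
#' For each biomarker column: its univariate R-squared against lifespan,
#' and, for each control set, the R-squared after residualizing both the
#' biomarker and lifespan on the controls, expressed as a percentage of the
#' uncontrolled value.
#'
#' @param summaries data.frame of biomarker summary columns.
#' @param lifespans numeric, days.
#' @param controls named list of character vectors (control column sets).
#' @return data.frame `(biomarker, control, r2, r2_controlled,
#'   pct_remaining)`.
#' @export
partial_r2_table <- function(summaries, lifespans, controls) {
  stopifnot(is.list(controls))
  X <- as.matrix(summaries)
  resid_on <- function(v, C) {
    if (!length(C)) return(v - mean(v))
    stats::lm.fit(cbind(1, X[, C, drop = FALSE]), v)$residuals
  }
  out <- list()
  for (b in colnames(X)) {
    r2_raw <- r_squared(lifespans,
                        stats::lm.fit(cbind(1, X[, b]), lifespans)$fitted.values)
    for (cn in names(controls)) {
      C <- controls[[cn]]
      rb <- resid_on(X[, b], C)
      ry <- resid_on(lifespans, C)
      r2_ctl <- if (stats::sd(rb) < 1e-12) 0 else {
        stats::cor(rb, ry)^2
      }
      out[[length(out) + 1L]] <- data.frame(
        biomarker = b, control = cn, r2 = r2_raw, r2_controlled = r2_ctl,
        pct_remaining = 100 * r2_ctl / r2_raw, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
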