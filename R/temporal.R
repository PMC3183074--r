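# Lifespan-predictive ability as a function of age: ridge regression on all
# raw daily values of a biomarker up to each age, plus all pairwise
# interaction terms, with the penalty chosen to minimize the generalized
# cross-validation (GCV) error.

#' Expand daily values into raw + pairwise-interaction features
#'
#' Returns the raw values followed by all unordered pairwise products
#' (including squares), in deterministic order: raw columns in day order,
#' then products `(i, j)` with `i <= j` in lexicographic order.  Two days
#' expand to 2 + 3 = 5 features; six days to 6 + 21 = 27.
#'
#' @param values numeric matrix (animals x days) or vector (one animal).
#' @return numeric matrix of expanded features with descriptive column
#'   names.
#' @export
expand_features <- function(values) {
  V <- if (is.matrix(values)) values else matrix(values, nrow = 1L)
  d <- ncol(V)
  if (d < 1L) stop("need at least one day of values")
  nms <- colnames(V) %||% paste0("d", seq_len(d))
  pairs <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  inter <- V[, pairs[, 1L], drop = FALSE] * V[, pairs[, 2L], drop = FALSE]
  colnames(inter) <- paste0(nms[pairs[, 1L]], "*", nms[pairs[, 2L]])
  out <- cbind(V, inter)
  colnames(out) <- c(nms, colnames(inter))
  out
}

#' Ridge regression with GCV-selected penalty
#'
#' Predictors are standardized; the intercept is unpenalized (handled by
#' centering).  `GCV(lambda) = n SS_res(lambda) / (n - tr H(lambda))^2`
#' with `H` the ridge hat operator (its trace includes 1 for the
#' intercept), minimized over a log-spaced grid.
#'
#' @param features numeric matrix (animals x features).
#' @param lifespans numeric response.
#' @param lambda_grid penalty grid (default 50 log-spaced points in
#'   `[1e-4, 1e4]`).
#' @return object of class `ridge_gcv_model`: list with `lambda`, `gcv`
#'   (full grid), `coefficients` (standardized scale), `intercept`,
#'   `fitted`, `r2`, `edf` (effective degrees of freedom at the optimum),
#'   `scaling`.
#' @export
ridge_gcv <- function(features, lifespans,
                      lambda_grid = 10^seq(-4, 4, length.out = 50)) {
  X <- as.matrix(features)
  y <- lifespans
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 observations")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in features or response")
  mu <- colMeans(X); sdv <- apply(X, 2L, stats::sd)
  keep <- sdv > 0
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L,
             sdv[keep], "/")
  yc <- y - mean(y)
  sv <- svd(Z)
  d2 <- sv$d^2
  uy <- crossprod(sv$u, yc)
  gcv <- vapply(lambda_grid, function(l) {
    shrink <- d2 / (d2 + l)
    fit <- sv$u %*% (shrink * uy)
    rss <- sum((yc - fit)^2)
    edf <- 1 + sum(shrink)
    n * rss / (n - edf)^2
  }, numeric(1))
  best <- which.min(gcv)
  l <- lambda_grid[best]
  shrink <- sv$d / (d2 + l)
  beta <- sv$v %*% (shrink * uy)
  fitted <- as.numeric(Z %*% beta) + mean(y)
  coefs <- numeric(ncol(X)); coefs[keep] <- beta
  names(coefs) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  structure(list(lambda = l, lambda_grid = lambda_grid, gcv = gcv,
                 coefficients = coefs, intercept = mean(y),
                 fitted = fitted, r2 = r_squared(y, fitted),
                 edf = 1 + sum(d2 / (d2 + l)),
                 scaling = list(mean = mu, sd = sdv, keep = keep)),
            class = "ridge_gcv_model")
}

#' Lifespan-predictive R-squared versus age
#'
#' For each requested age `a`, all raw values of the biomarker from the
#' start day through `a`, plus all pairwise interaction terms, enter a
#' ridge regression against lifespan with GCV-chosen penalty; the in-sample
#' R-squared of the fit at the chosen penalty is reported.  Animals lacking
#' any requested in-range observation are dropped (and counted).
#'
#' @param timecourses long data.frame `(animal_id, age_days, biomarker,
#'   value)` for a single biomarker (or pass `biomarker` to filter).
#' @param lifespans named numeric vector (names = animal ids), days.
#' @param ages ages at which to evaluate (default `2:7`).
#' @param start_day first day whose value enters the features (use 3 for
#'   measures defined from day 3 onward).
#' @param biomarker optional biomarker name filter.
#' @param lambda_grid passed to [ridge_gcv()].
#' @return object of class `predictive_curve`: data.frame `(age, r2,
#'   n_features, lambda, n_animals)`, plus attribute `n_dropped`.
#' @export
predictive_curve <- function(timecourses, lifespans, ages = 2:7,
                             start_day = 2, biomarker = NULL,
                             lambda_grid = 10^seq(-4, 4, length.out = 50)) {
  tc <- timecourses
  if (!is.null(biomarker)) tc <- tc[tc$biomarker == biomarker, ]
  ages <- ages[ages >= start_day]
  # animals x days value matrix on the full requested day range
  days <- seq(start_day, max(ages))
  wide <- tapply(tc$value, list(tc$animal_id, tc$age_days), mean)
  have <- intersect(colnames(wide), as.character(days))
  wide <- wide[, have, drop = FALSE]
  complete <- rownames(wide)[stats::complete.cases(wide)]
  complete <- intersect(complete, names(lifespans))
  n_dropped <- length(unique(tc$animal_id)) - length(complete)
  if (length(complete) < 10L)
    stop("fewer than 10 animals observed at all requested ages")
  W <- wide[complete, , drop = FALSE]
  y <- lifespans[complete]
  rows <- lapply(ages, function(a) {
    use <- as.character(seq(start_day, a))
    F <- expand_features(W[, use, drop = FALSE])
    fit <- ridge_gcv(F, y, lambda_grid)
    data.frame(age = a, r2 = fit$r2, n_features = ncol(F),
               lambda = fit$lambda, n_animals = length(y))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("predictive_curve", class(out))
  out
}
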