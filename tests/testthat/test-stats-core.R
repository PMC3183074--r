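# Lifespan estimation, window summaries, OLS/F/l.o.o., the survival index,
# dichotomized diagnostics, KDE and KS.

test_that("lifespan is the midpoint of the alive/dead bracket", {
  expect_equal(estimate_lifespan(c(9, 10, 11), c(TRUE, TRUE, FALSE)), 10.5)
  expect_equal(estimate_lifespan(c(10, 14), c(TRUE, FALSE)), 12.0)
  expect_error(estimate_lifespan(c(3, 4), c(FALSE, FALSE)), "no bracket")
  cens <- estimate_lifespan(c(3, 4), c(TRUE, TRUE))
  expect_true(is.na(cens))
  expect_true(attr(cens, "censored"))
})

test_that("window summaries take the in-window mean and OLS slope", {
  ws <- window_summary(3:7, 1:5)
  expect_equal(ws$mean, 3); expect_equal(ws$slope, 1.0)
  ws2 <- window_summary(c(1, 3, 5, 7, 9), rep(4, 5))
  expect_equal(ws2$slope, 0); expect_equal(ws2$mean, 4)
  expect_equal(ws2$n, 3)  # only ages 3, 5, 7 are in window
  expect_true(is.na(window_summary(c(2, 5), c(1, 7))$slope))
  expect_error(window_summary(c(1, 2), c(1, 2)), "no in-window")
  # noisy planted slope recovered across seeds
  slopes <- vapply(1:50, function(sd) {
    set.seed(sd)
    window_summary(3:7, 2 + 1.5 * (3:7) + rnorm(5, 0, 0.4))$slope
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(50)
  expect_lt(abs(mean(slopes) - 1.5), 2 * se + 1e-9)
})

test_that("OLS results follow the R2-based F formula exactly", {
  set.seed(1)
  x <- rnorm(100)
  fit <- ols_predict(cbind(x = x), x)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["x"]), 1, tolerance = 1e-9)
  # F from the printed formula equals the ANOVA-decomposition F
  X <- cbind(a = rnorm(60), b = rnorm(60))
  y <- 0.5 * X[, 1] + rnorm(60)
  fit2 <- ols_predict(X, y)
  expect_equal(fit2$f_statistic, f_anova(X, y), tolerance = 1e-8)
  expect_equal(fit2$df_model, 2L); expect_equal(fit2$df_error, 57L)
  # univariate R2 equals the squared Pearson correlation
  fit3 <- ols_predict(cbind(a = X[, 1]), y)
  expect_equal(fit3$r2, stats::cor(X[, 1], y)^2, tolerance = 1e-10)
  # permuted labels: R2 within the null
  null95 <- stats::quantile(replicate(200, {
    ols_predict(X, sample(y), loo = FALSE)$r2
  }), 0.95)
  expect_lt(ols_predict(X, sample(y), loo = FALSE)$r2, null95 + 0.05)
  # collinearity is reported with offenders named
  expect_error(ols_predict(cbind(a = x, b = x), rnorm(100)), "collinear")
  expect_error(ols_predict(cbind(a = rep(1, 100)), x), "constant")
})

test_that("the F arithmetic matches the worked example", {
  # R2 = 0.32, p = 2 predictors, n = 500: F = 0.32*497/(0.68*2)
  r2 <- 0.32; n <- 500; p <- 2
  f <- r2 * (n - p - 1) / ((1 - r2) * p)
  expect_equal(f, 116.9, tolerance = 0.05)
  # construct data achieving R2 ~ 0.32 and verify the pipeline agrees with
  # the ANOVA oracle on it
  set.seed(2)
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- sqrt(0.32) * scale(X[, 1])[, 1] + sqrt(0.68) * rnorm(n)
  fit <- ols_predict(X, y, loo = FALSE)
  expect_equal(fit$f_statistic, f_anova(X, y), tolerance = 1e-8)
})

test_that("leave-one-out R2 equals the n-refit oracle", {
  set.seed(3)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(40)
  expect_equal(loo_r2(X, y), loo_r2_refit(X, y), tolerance = 1e-8)
  # exact linear relation: l.o.o. R2 = 1
  z <- rnorm(50)
  expect_equal(loo_r2(cbind(x = z), 2 * z + 1), 1, tolerance = 1e-9)
})

test_that("l.o.o. R2 is below in-sample R2 and often negative on noise", {
  res <- vapply(1:40, function(sd) {
    set.seed(sd)
    X <- matrix(rnorm(30 * 5), 30, 5)
    fit <- ols_predict(X, rnorm(30))
    c(fit$r2, fit$loo_r2)
  }, numeric(2))
  expect_gte(mean(res[2, ] <= res[1, ]), 0.95)
  expect_gte(mean(res[2, ] < 0), 0.5)
})

test_that("the survival index weighs only informative predictors", {
  co <- generate_cohort(cohort_config(
    n_animals = 400,
    planted_r2 = c(length = 0.4, motion = 0, texture = 0,
                   autofluorescence = 0),
    slope_sign = c(length = 1, motion = 1, texture = 1,
                   autofluorescence = -1),
    seed = 7))
  s <- summarize_cohort(co$timecourses)
  y <- co$animals$lifespan_days[match(s$animal_id, co$animals$animal_id)]
  spi <- survival_prediction_index(s, y)
  w <- spi$coefficients
  expect_gt(w["length_slope"], 0.3)
  others <- setdiff(names(w), "length_slope")
  expect_true(all(abs(w[others]) < 0.1))
  # weights are reported in descending magnitude
  expect_equal(names(spi$weights_by_magnitude)[1], "length_slope")
  # a duplicated predictor trips the collinearity check
  s2 <- s; s2$motion_mean <- s2$length_slope
  expect_error(survival_prediction_index(s2, y), "collinear")
  expect_error(survival_prediction_index(s[, 1:3], y), "missing predictors")
})

test_that("dichotomization recovers perfect and chance extremes", {
  set.seed(8)
  L <- rnorm(200, 10.7, 1.9)
  perfect <- dichotomize_test(L, L)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  chance <- dichotomize_test(rnorm(1000), rnorm(1000))
  expect_lt(abs(chance$sensitivity - 0.5), 0.06)
  expect_lt(abs(chance$specificity - 0.5), 0.06)
  expect_error(dichotomize_test(c(1, rep(2, 9)), 1:10), "degenerate")
})

test_that("balanced cohorts give balanced sensitivity and specificity", {
  set.seed(9)
  n <- 1000
  L <- rnorm(n)
  pred <- sqrt(0.32) * L + sqrt(0.68) * rnorm(n)
  dt <- dichotomize_test(pred, L)
  expect_lt(abs(dt$sensitivity - dt$specificity), 0.05)
})

test_that("the KDE uses the Scott kernel variance and integrates to 1", {
  set.seed(10)
  x <- rnorm(100, 10.7, 1.9)
  k <- lifespan_kde(x)
  expect_equal(k$kernel_variance, stats::var(x) * 100^(-0.2),
               tolerance = 1e-12)
  area <- sum(diff(k$x) * (utils::head(k$density, -1) +
                             utils::tail(k$density, -1)) / 2)
  expect_lt(abs(area - 1), 1e-3)
  expect_true(all(k$density >= 0))
  # a clearly bimodal mixture shows two local maxima
  xm <- c(rnorm(200, 5, 0.5), rnorm(200, 12, 0.5))
  km <- lifespan_kde(xm)
  d <- km$density
  peaks <- sum(d[2:(length(d) - 1)] > d[1:(length(d) - 2)] &
                 d[2:(length(d) - 1)] > d[3:length(d)] &
                 d[2:(length(d) - 1)] > 0.05 * max(d))
  expect_gte(peaks, 2)
  expect_error(lifespan_kde(rep(3, 10)), "zero variance")
})

test_that("KS comparisons match the standard two-sample test", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  disj <- ks_compare(1:10, 101:110)
  expect_equal(disj$statistic, 1)
  expect_error(ks_compare(numeric(0), x), "nonempty")
})

test_that("partial R2 controls behave on planted causal chains", {
  set.seed(11)
  n <- 1000
  C <- rnorm(n)
  M <- 0.9 * C + rnorm(n, 0, 0.44)
  L <- 0.9 * M + rnorm(n, 0, 0.44)
  S <- cbind(chain_c = C, chain_m = M, indep = rnorm(n))
  tab <- partial_r2_table(S, L, controls = list(
    self_m = "chain_m", self_c = "chain_c", none = character(0),
    indep_ctl = "indep"))
  pick <- function(b, ctl) tab$pct_remaining[tab$biomarker == b &
                                               tab$control == ctl]
  # controlling a biomarker for itself leaves nothing
  expect_equal(pick("chain_m", "self_m"), 0)
  # controlling the mediator removes most of the upstream R2 ...
  expect_lt(pick("chain_c", "self_m"), 15)
  # ... but controlling upstream leaves the mediator informative
  expect_gt(pick("chain_m", "self_c"), 40)
  # an empty control set changes nothing; an independent control changes
  # little
  expect_lt(abs(pick("chain_c", "none") - 100), 1e-6)
  expect_lt(abs(pick("chain_c", "indep_ctl") - 100), 10)
  tab2 <- partial_r2_table(cbind(x = C), L, controls = list(z = "x"))
  expect_equal(tab2$pct_remaining, 0)
})
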