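# Phenomenological biomarkers: dark/flat/exposure-corrected fluorescence
# summaries (95th percentile by default), solid-of-revolution size measures,
# the four-statistic motion score and texton-histogram texture signature,
# each mapped to days of life remaining by fold-held-out nu-SVR.

#' Fluorescence calibration frames
#'
#' @param dark dark-field frame (matrix or [image_frame()]): camera
#'   background.
#' @param flat flat-field frame: spatial illumination pattern.  Must be
#'   strictly positive after dark subtraction.
#' @return object of class `fluorescence_calibration`.
#' @export
fluorescence_calibration <- function(dark, flat) {
  d <- if (inherits(dark, "image_frame")) dark$data else dark
  f <- if (inherits(flat, "image_frame")) flat$data else flat
  stopifnot(all(dim(d) == dim(f)))
  net <- f - d
  if (any(net <= 0))
    stop("flat-field must be strictly positive after dark subtraction")
  structure(list(dark = d, flat_norm = net / mean(net)),
            class = "fluorescence_calibration")
}

#' Correct a raw fluorescence frame
#'
#' `out = (raw - dark) / normalized flat / exposure`; negative values are
#' clipped to 0.  Division by the exposure time renders frames acquired at
#' different exposures comparable.
#'
#' @param raw an [image_frame()] with `exposure_ms` set, or a matrix (then
#'   `exposure_ms` must be given).
#' @param cal a [fluorescence_calibration()].
#' @param exposure_ms exposure override, ms.
#' @return an [image_frame()] with corrected intensities (per-ms units).
#' @export
correct_fluorescence <- function(raw, cal, exposure_ms = NULL) {
  stopifnot(inherits(cal, "fluorescence_calibration"))
  img <- if (inherits(raw, "image_frame")) raw$data else raw
  expo <- exposure_ms %||%
    (if (inherits(raw, "image_frame")) raw$exposure_ms else NULL)
  if (is.null(expo) || !is.finite(expo) || expo <= 0)
    stop("a positive exposure time is required")
  stopifnot(all(dim(img) == dim(cal$dark)))
  out <- pmax((img - cal$dark) / cal$flat_norm / expo, 0)
  image_frame(out,
              channel = if (inherits(raw, "image_frame")) raw$channel else NA,
              exposure_ms = expo,
              age_days = if (inherits(raw, "image_frame")) raw$age_days else NA)
}

#' Size measures from a worm geometry
#'
#' Length is the centerline arc length; volume and surface area are the
#' solid of revolution of the half-width profile about the centerline:
#' `V = pi * integral(w^2 ds)`, `A = 2 * pi * integral(w ds)` (trapezoid
#' rule).
#'
#' @param geom a [worm_geometry()].
#' @return named vector `c(length, volume, surface_area)` in px, px^3, px^2.
#' @export
measure_size <- function(geom) {
  center <- geom$centerline
  L <- polyline_length(center)
  w <- geom$half_widths
  if (is.null(w)) w <- sqrt(rowSums((geom$left - geom$right)^2)) / 2
  s <- c(0, cumsum(sqrt(rowSums(diff(center)^2))))
  w <- stats::approx(seq(0, 1, length.out = length(w)), w,
                     xout = s / max(s))$y
  trap <- function(y) sum(diff(s) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  c(length = L, volume = pi * trap(w^2), surface_area = 2 * pi * trap(w))
}

#' Percentile summary of fluorescence in a region
#'
#' The statistic (default the 95th percentile, linear interpolation,
#' `quantile` type 7) over valid in-region pixels.
#'
#' @param img a [straightened_image()] (region taken from validity flags
#'   and the head-fraction rows), or an [image_frame()]/matrix together
#'   with `geom`.
#' @param geom a [worm_geometry()], required when `img` is a frame.
#' @param region `"whole"` or `"head"` (initial 20% of the arc length).
#' @param p percentile in `[0, 100]`.
#' @return scalar intensity.
#' @export
fluorescence_summary <- function(img, geom = NULL,
                                 region = c("whole", "head"), p = 95) {
  region <- match.arg(region)
  if (inherits(img, "straightened_image")) {
    sel <- img$valid
    if (region == "head") {
      nhead <- max(1L, floor(0.20 * nrow(sel)))
      sel[-seq_len(nhead), ] <- FALSE
    }
    px <- img$data[sel]
  } else {
    stopifnot(!is.null(geom))
    m <- if (inherits(img, "image_frame")) img$data else img
    mask <- geometry_mask(geom, dim(m), head_only = (region == "head"))
    px <- m[mask]
  }
  if (length(px) == 0L) stop("empty region")
  unname(stats::quantile(px, p / 100, type = 7))
}

#' Four-statistic motion score inputs
#'
#' Over the in-animal pixels: the fraction of pixels whose relative
#' intensity change `|a - b| / max(mean(a, b), eps)` exceeds 18%, and the
#' mean pixel-wise coefficient of variation across the frame set, before
#' and after stimulation.  Pre-stimulation change fractions are averaged
#' over consecutive pre-frame pairs (spontaneous movement); each
#' post-stimulation frame is compared against the last pre-stimulation
#' frame (stimulus-evoked movement).
#'
#' @param pre,post lists of [image_frame()]s or matrices (>= 2 frames per
#'   condition).
#' @param mask logical in-animal mask.
#' @param change_threshold relative-change cutoff (default 0.18).
#' @param eps denominator floor.
#' @return object of class `motion_statistics`: named vector
#'   `frac_changed_pre`, `frac_changed_post`, `cv_pre`, `cv_post`.
#' @export
motion_statistics <- function(pre, post, mask, change_threshold = 0.18,
                              eps = 1e-8) {
  as_mat <- function(x) if (inherits(x, "image_frame")) x$data else x
  pre <- lapply(pre, as_mat); post <- lapply(post, as_mat)
  if (length(pre) < 2L || length(post) < 2L)
    stop("at least 2 frames per condition are required")
  dims <- dim(pre[[1L]])
  all_frames <- c(pre, post)
  if (!all(vapply(all_frames, function(m) all(dim(m) == dims), logical(1))))
    stop("mismatched frame shapes")
  stopifnot(all(dim(mask) == dims))
  frac_changed <- function(a, b) {
    a <- a[mask]; b <- b[mask]
    rel <- abs(a - b) / pmax((a + b) / 2, eps)
    mean(rel > change_threshold)
  }
  fc_pre <- mean(vapply(seq_len(length(pre) - 1L), function(i)
    frac_changed(pre[[i]], pre[[i + 1L]]), numeric(1)))
  ref <- pre[[length(pre)]]
  fc_post <- mean(vapply(post, frac_changed, numeric(1), a = ref))
  cv_of <- function(frames) {
    stack <- vapply(frames, function(m) m[mask], numeric(sum(mask)))
    mu <- rowMeans(stack)
    sdv <- apply(stack, 1L, stats::sd)
    mean(sdv / pmax(abs(mu), eps))
  }
  structure(c(frac_changed_pre = fc_pre, frac_changed_post = fc_post,
              cv_pre = cv_of(pre), cv_post = cv_of(post)),
            class = "motion_statistics")
}

#' Map features to days of life remaining with fold-held-out nu-SVR
#'
#' nu-support-vector regression with an RBF kernel (defaults: the motion
#' parameters `C = 10`, `nu = 0.8`, `gamma = 0.3`; for texture signatures
#' use `C = 5`, `nu = 0.6`, `gamma = 0.004`).  Features are standardized
#' internally.  Each row's prediction comes only from models not trained on
#' that row's fold; these held-out predictions are the motion (or texture)
#' scores.
#'
#' @param features numeric matrix or data.frame.
#' @param days_remaining numeric response.
#' @param cost,nu,gamma SVR hyperparameters.
#' @param folds number of cross-validation folds (default 100, capped
#'   implicitly by the caller; must not exceed the number of rows).
#' @param fold_seed seed for the fold assignment.
#' @return object of class `svr_score_model`: list with `model` (fit on all
#'   data), `cv_predictions`, `cv_r2`, `params`, `scaling`.
#' @export
fit_days_remaining_svr <- function(features, days_remaining, cost = 10,
                                   nu = 0.8, gamma = 0.3, folds = 100,
                                   fold_seed = 1) {
  X <- as.matrix(features)
  n <- nrow(X)
  stopifnot(length(days_remaining) == n)
  if (folds > n) stop("folds must not exceed the number of rows")
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  if (cost <= 0 || gamma <= 0) stop("cost and gamma must be positive")
  mu <- colMeans(X); sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  set.seed(fold_seed)
  fold <- sample(rep_len(seq_len(folds), n))
  preds <- numeric(n)
  for (k in seq_len(folds)) {
    hold <- fold == k
    fit <- e1071::svm(Z[!hold, , drop = FALSE], days_remaining[!hold],
                      type = "nu-regression", kernel = "radial",
                      cost = cost, nu = nu, gamma = gamma, scale = FALSE)
    preds[hold] <- stats::predict(fit, Z[hold, , drop = FALSE])
  }
  full <- e1071::svm(Z, days_remaining, type = "nu-regression",
                     kernel = "radial", cost = cost, nu = nu, gamma = gamma,
                     scale = FALSE)
  structure(list(model = full, cv_predictions = preds,
                 cv_r2 = r_squared(days_remaining, preds),
                 params = c(cost = cost, nu = nu, gamma = gamma),
                 folds = folds, scaling = list(mean = mu, sd = sdv)),
            class = "svr_score_model")
}

#' Predict days of life remaining from new features
#' @param object an `svr_score_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.svr_score_model <- function(object, newdata, ...) {
  Z <- sweep(sweep(as.matrix(newdata), 2L, object$scaling$mean), 2L,
             object$scaling$sd, "/")
  stats::predict(object$model, Z)
}
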