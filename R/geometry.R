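# Straightening and registration: sample the image along perpendiculars to
# the centerline, warp each animal to an age-specific "unit worm" grid,
# refine longitudinal registration with a vulva-anchored five-control-point
# warp fit by penalized hill climbing, and mutually align a population by
# alternating mean computation (expectation) and per-image warping
# (maximization).

#' A straightened worm image
#'
#' Rows run head to tail along the arc; columns are perpendicular offsets
#' (left flank to right flank).  `valid` flags pixels that were sampled
#' inside the worm outline and inside the source frame.
#'
#' @param data numeric matrix of intensities.
#' @param valid logical matrix of the same shape.
#' @param half_widths per-row half-width of the source animal, pixels.
#' @param channel,age_days metadata.
#' @return object of class `straightened_image`.
#' @export
straightened_image <- function(data, valid, half_widths = NULL,
                               channel = NA_character_, age_days = NA_real_) {
  stopifnot(is.matrix(data), all(dim(valid) == dim(data)))
  structure(list(data = data, valid = valid, half_widths = half_widths,
                 channel = channel, age_days = age_days),
            class = "straightened_image")
}

#' Straighten an image along a worm geometry
#'
#' Bilinear sampling along perpendiculars to the centerline at 1-px arc
#' spacing.  Off-worm and off-frame samples are flagged invalid (off-frame
#' samples are set to 0).
#'
#' @param image an [image_frame()] or numeric matrix.
#' @param geom a [worm_geometry()].
#' @param half_span half the number of sampled perpendicular offsets; the
#'   column grid spans `-half_span .. half_span` pixels.  Defaults to the
#'   maximal half-width of the geometry, rounded up.
#' @return a [straightened_image()]; row 1 is the head tip.
#' @export
straighten <- function(image, geom, half_span = NULL) {
  img <- if (inherits(image, "image_frame")) image$data else image
  center <- resample_polyline(geom$centerline, 1)
  n <- nrow(center)
  w <- geom$half_widths
  if (is.null(w)) w <- sqrt(rowSums((geom$left - geom$right)^2)) / 2
  w <- stats::approx(seq(0, 1, length.out = length(w)), w,
                     xout = seq(0, 1, length.out = n))$y
  if (is.null(half_span)) half_span <- ceiling(max(w))
  if (min(center[, 1L]) < 1 || max(center[, 1L]) > nrow(img) ||
      min(center[, 2L]) < 1 || max(center[, 2L]) > ncol(img))
    stop("geometry lies outside the frame")
  tang <- rbind(center[2L, ] - center[1L, ],
                (center[3:n, , drop = FALSE] -
                   center[1:(n - 2L), , drop = FALSE]) / 2,
                center[n, ] - center[n - 1L, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  normal <- cbind(-tang[, 2L], tang[, 1L])
  offs <- seq(-half_span, half_span)
  rr <- outer(center[, 1L], rep(1, length(offs))) +
    outer(normal[, 1L], offs)
  cc <- outer(center[, 2L], rep(1, length(offs))) +
    outer(normal[, 2L], offs)
  vals <- bilinear_sample(img, as.vector(rr), as.vector(cc))
  data <- matrix(vals, n, length(offs))
  valid <- !is.na(data) & (abs(matrix(rep(offs, each = n), n)) <=
                             matrix(rep(w, length(offs)), n))
  data[is.na(data)] <- 0
  ch <- if (inherits(image, "image_frame")) image$channel else NA_character_
  ag <- if (inherits(image, "image_frame")) image$age_days else NA_real_
  straightened_image(data, valid, half_widths = w, channel = ch,
                     age_days = ag)
}

#' Build the per-age "unit worm" standard from a set of geometries
#'
#' For each integer age: the mean arc length and the mean half-width
#' profile (resampled to the standard row count).
#'
#' @param geoms list of [worm_geometry()]s.
#' @param ages numeric vector of ages (days), one per geometry.
#' @param grid `c(rows, cols)` of the standard grid (default 100 x 24).
#' @return object of class `unit_worm_standard`: list with `grid` and
#'   per-age entries `length` and `width_profile`.
#' @export
make_unit_standard <- function(geoms, ages, grid = c(100L, 24L)) {
  stopifnot(length(geoms) == length(ages))
  rows <- grid[1L]
  by_age <- split(seq_along(geoms), round(ages))
  standards <- lapply(by_age, function(ix) {
    lens <- vapply(geoms[ix], function(g) polyline_length(g$centerline),
                   numeric(1))
    profs <- vapply(geoms[ix], function(g) {
      w <- g$half_widths
      if (is.null(w)) w <- sqrt(rowSums((g$left - g$right)^2)) / 2
      stats::approx(seq(0, 1, length.out = length(w)), w,
                    xout = seq(0, 1, length.out = rows))$y
    }, numeric(rows))
    list(length = mean(lens), width_profile = rowMeans(as.matrix(profs)))
  })
  structure(list(grid = as.integer(grid), ages = as.numeric(names(by_age)),
                 standards = standards),
            class = "unit_worm_standard")
}

#' Warp a straightened image to the unit-worm grid
#'
#' Rows are resampled to the standard row count (uniform normalized arc
#' positions); columns to a normalized transverse coordinate in `[-1, 1]`
#' scaled by the source animal's own half-width profile, so anatomical
#' positions coincide across animals of different sizes.  Validity flags
#' are propagated (nearest-neighbour).
#'
#' @param straight a [straightened_image()].
#' @param standard a [make_unit_standard()]; if the animal's age has no
#'   standard, the nearest age is used with a warning.
#' @return a [straightened_image()] on the standard grid.
#' @export
warp_to_unit <- function(straight, standard) {
  stopifnot(inherits(straight, "straightened_image"),
            inherits(standard, "unit_worm_standard"))
  grid <- standard$grid
  age <- straight$age_days
  if (!is.na(age) && !(round(age) %in% standard$ages)) {
    warning(sprintf("no unit-worm standard for age %s; using nearest age %s",
                    age, standard$ages[which.min(abs(standard$ages - age))]))
  }
  nr <- nrow(straight$data); nc <- ncol(straight$data)
  src_center <- (nc + 1) / 2
  u <- seq(0, 1, length.out = grid[1L])
  src_rows <- 1 + u * (nr - 1)
  w_u <- stats::approx(seq(0, 1, length.out = length(straight$half_widths)),
                       straight$half_widths, xout = u)$y
  v <- (seq_len(grid[2L]) - (grid[2L] + 1) / 2) / ((grid[2L] - 1) / 2)
  rr <- matrix(rep(src_rows, grid[2L]), grid[1L])
  cc <- src_center + outer(w_u, v)
  vals <- bilinear_sample(straight$data, as.vector(rr), as.vector(cc))
  data <- matrix(vals, grid[1L], grid[2L])
  vmask <- straight$valid[cbind(pmin(pmax(round(as.vector(rr)), 1L), nr),
                                pmin(pmax(round(as.vector(cc)), 1L), nc))]
  valid <- matrix(vmask & !is.na(vals), grid[1L], grid[2L])
  data[is.na(data)] <- 0
  straightened_image(data, valid, half_widths = w_u,
                     channel = straight$channel, age_days = age)
}

#' A five-control-point longitudinal warp
#'
#' Control points sit at normalized arc positions 1/6 .. 5/6; the warp is
#' the monotone piecewise-linear map through `(0, 0)`,
#' `(k/6, k/6 + d_k)`, `(1, 1)` from target to source arc position.
#'
#' @param displacements numeric length-5 vector of signed offsets.
#' @param lambda deformation penalty weight.
#' @return object of class `longitudinal_warp`.
#' @export
longitudinal_warp <- function(displacements = rep(0, 5), lambda = 1) {
  stopifnot(length(displacements) == 5L)
  knots <- seq_len(5L) / 6
  src <- knots + displacements
  if (any(diff(c(0, src, 1)) <= 0))
    stop("warp must be monotone: warped positions must strictly increase")
  structure(list(control_points = knots, displacements = displacements,
                 lambda = lambda), class = "longitudinal_warp")
}

# map target arc positions (0..1) to source positions under the warp
warp_map <- function(warp, v) {
  x <- c(0, warp$control_points, 1)
  y <- c(0, warp$control_points + warp$displacements, 1)
  stats::approx(x, y, xout = v, rule = 2)$y
}

#' Apply a longitudinal warp to a straightened image
#'
#' Each output row at normalized position `v` is sampled (linearly in the
#' row direction) from the input at position `warp_map(v)`.
#'
#' @param straight a [straightened_image()].
#' @param warp a [longitudinal_warp()].
#' @return a warped [straightened_image()] on the same grid.
#' @export
apply_longitudinal_warp <- function(straight, warp) {
  nr <- nrow(straight$data)
  v <- seq(0, 1, length.out = nr)
  src <- 1 + warp_map(warp, v) * (nr - 1)
  lo <- pmin(pmax(floor(src), 1L), nr)
  hi <- pmin(lo + 1L, nr)
  f <- src - lo
  data <- straight$data[lo, , drop = FALSE] * (1 - f) +
    straight$data[hi, , drop = FALSE] * f
  valid <- straight$valid[pmin(pmax(round(src), 1L), nr), , drop = FALSE]
  straightened_image(data, valid, half_widths = straight$half_widths,
                     channel = straight$channel, age_days = straight$age_days)
}

align_objective <- function(data, valid, ref_data, ref_valid, d, lambda) {
  ok <- valid & ref_valid
  if (sum(ok) < 3L) return(-Inf)
  x <- data[ok]; y <- ref_data[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
  stats::cor(x, y) - lambda * sum(d^2)
}

#' Longitudinally align an image to a reference
#'
#' Coordinate-wise hill climbing over the five control-point displacements,
#' maximizing `cor(image o warp, reference) - lambda * sum(d^2)` over
#' jointly valid pixels.  Step sizes shrink from 0.05 to 0.005 of arc
#' length; the search stops when no single-coordinate move improves the
#' objective.  A vulva anchor (normalized arc position) initializes the
#' middle control point.
#'
#' @param straight a [straightened_image()].
#' @param reference a [straightened_image()] of the same grid shape.
#' @param lambda penalty weight (default 1, on correlation units).
#' @param vulva_position optional normalized arc position of the vulva in
#'   the source, used to initialize the middle displacement.
#' @return list with `image` (the warped [straightened_image()]) and
#'   `warp` (the fitted [longitudinal_warp()]).
#' @export
longitudinal_align <- function(straight, reference, lambda = 1,
                               vulva_position = NULL) {
  stopifnot(all(dim(straight$data) == dim(reference$data)))
  if (stats::sd(straight$data[straight$valid]) == 0) {
    warning("constant-intensity image: correlation undefined, identity warp returned")
    w <- longitudinal_warp(rep(0, 5), lambda)
    return(list(image = apply_longitudinal_warp(straight, w), warp = w))
  }
  d <- rep(0, 5)
  if (!is.null(vulva_position)) d[3L] <- vulva_position - 0.5
  knots <- seq_len(5L) / 6
  feasible <- function(d) all(diff(c(0, knots + d, 1)) > 1e-6)
  if (!feasible(d)) d <- rep(0, 5)
  obj <- function(d) {
    w <- longitudinal_warp(d, lambda)
    wi <- apply_longitudinal_warp(straight, w)
    align_objective(wi$data, wi$valid, reference$data, reference$valid,
                    d, lambda)
  }
  best <- obj(d)
  for (step in c(0.05, 0.02, 0.01, 0.005)) {
    repeat {
      improved <- FALSE
      for (k in 1:5) for (sgn in c(1, -1)) {
        cand <- d; cand[k] <- cand[k] + sgn * step
        if (!feasible(cand)) next
        val <- obj(cand)
        if (val > best + 1e-12) {
          d <- cand; best <- val; improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  w <- longitudinal_warp(d, lambda)
  list(image = apply_longitudinal_warp(straight, w), warp = w,
       objective = best)
}

#' Mutually align a population of straightened images (EM)
#'
#' Alternates computing the mean image over valid pixels (expectation) and
#' warping each image to the mean with [longitudinal_align()]
#' (maximization), until the mean image changes by less than `tol` times
#' its dynamic range (maximum absolute difference) or `max_iter`
#' iterations.
#'
#' @param images list of [straightened_image()]s on a shared grid.
#' @param lambda penalty weight passed to [longitudinal_align()].
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the mean image, as a fraction of
#'   its dynamic range.
#' @return list with `images` (aligned), `mean` (mean image matrix),
#'   `iterations`, and `objective` (mean per-image correlation with the
#'   mean, minus penalties, per iteration).
#' @export
em_align_population <- function(images, lambda = 1, max_iter = 10,
                                tol = 0.01) {
  if (length(images) < 2L) stop("at least 2 images required")
  dims <- dim(images[[1L]]$data)
  stopifnot(all(vapply(images, function(x) all(dim(x$data) == dims),
                       logical(1))))
  mean_image <- function(imgs) {
    num <- Reduce(`+`, lapply(imgs, function(x) x$data * x$valid))
    den <- Reduce(`+`, lapply(imgs, function(x) 0 + x$valid))
    m <- num / pmax(den, 1)
    list(data = m, valid = den > 0)
  }
  current <- images
  m_prev <- mean_image(current)
  objectives <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ref <- straightened_image(m_prev$data, m_prev$valid)
    fits <- lapply(images, longitudinal_align, reference = ref,
                   lambda = lambda)
    current <- lapply(fits, `[[`, "image")
    objectives <- c(objectives,
                    mean(vapply(fits, `[[`, numeric(1), "objective")))
    m_new <- mean_image(current)
    delta <- max(abs(m_new$data - m_prev$data))
    rng <- diff(range(m_new$data))
    m_prev <- m_new
    if (delta < tol * max(rng, .Machine$double.eps) || iter >= max_iter) break
  }
  list(images = current, mean = m_prev$data, iterations = iter,
       objective = objectives)
}
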