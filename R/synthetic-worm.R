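# Procedural worm-image generator: seeded brightfield and fluorescence
# frames with pixel-level ground truth (mask, centerline, vulva, hotspot
# centers).  Not photorealistic -- it renders the geometry and intensity
# structure the segmentation, straightening and measurement stages consume:
# a dark worm on a bright background with interior speckle, and fluorescence
# hotspots in head/vulva/tail/body regions over a dim body background.

#' Specification of a synthetic worm
#'
#' @param centerline_control matrix (row, col) of control points; a smooth
#'   spline is threaded through them.  Default: a gentle S-curve on a
#'   120 x 480 canvas with arc length around 300 px.
#' @param max_half_width maximal half-width, pixels.
#' @param width_profile function of normalized arc position in `[0, 1]`
#'   returning the half-width in pixels; must be positive in the interior
#'   and zero at both ends.
#' @param vulva_position normalized arc position of the vulva, strictly
#'   inside (0, 1).
#' @param hotspots data.frame with columns `region` (one of `"head"`,
#'   `"vulva"`, `"tail"`, `"body"`), `intensity`, `radius` (px).  `"body"`
#'   denotes diffuse whole-body expression; its radius is ignored.
#' @param texture_roughness scalar in `[0, 1]` scaling interior brightfield
#'   speckle (increases with simulated age).
#' @param motion_displacement rigid displacement in pixels between
#'   sequential frames.
#' @param canvas `c(rows, cols)` canvas size.
#' @param seed integer seed.
#' @return object of class `worm_spec`.
#' @export
worm_spec <- function(centerline_control = NULL,
                      max_half_width = 9,
                      width_profile = NULL,
                      vulva_position = 0.55,
                      hotspots = data.frame(region = c("head", "vulva", "tail"),
                                            intensity = c(1, 0.8, 0.6),
                                            radius = c(8, 6, 6)),
                      texture_roughness = 0.3,
                      motion_displacement = 0,
                      canvas = c(120L, 480L),
                      seed = 1) {
  if (is.null(centerline_control))
    centerline_control <- cbind(
      60 + 22 * sin(seq(0, 2.4 * pi, length.out = 7)),
      seq(90, 390, length.out = 7))
  if (is.null(width_profile)) {
    wmax <- max_half_width
    width_profile <- function(u) wmax * pmax(0, (4 * u * (1 - u)))^0.35
  }
  if (vulva_position <= 0 || vulva_position >= 1)
    stop("vulva_position must lie strictly inside (0, 1)")
  u_test <- seq(0.05, 0.95, by = 0.05)
  if (any(width_profile(u_test) <= 0))
    stop("width_profile must be positive in the interior")
  stopifnot(all(hotspots$region %in% c("head", "vulva", "tail", "body")))
  structure(list(centerline_control = centerline_control,
                 width_profile = width_profile,
                 vulva_position = vulva_position,
                 hotspots = hotspots,
                 texture_roughness = texture_roughness,
                 motion_displacement = motion_displacement,
                 canvas = as.integer(canvas), seed = as.integer(seed)),
            class = "worm_spec")
}

#' A single grayscale frame with acquisition metadata
#'
#' @param data numeric matrix of intensities.
#' @param channel `"brightfield"` or a fluorescence channel name.
#' @param exposure_ms exposure time, milliseconds.
#' @param age_days acquisition age, days.
#' @return object of class `image_frame`.
#' @export
image_frame <- function(data, channel = "brightfield", exposure_ms = 10,
                        age_days = NA_real_) {
  stopifnot(is.matrix(data))
  structure(list(data = data, channel = channel,
                 exposure_ms = exposure_ms, age_days = age_days),
            class = "image_frame")
}

#' Randomized worm specification
#'
#' Draws seeded random centerline control points (posture), maximal
#' half-width and vulva position around the defaults, for multi-animal
#' synthetic suites.
#'
#' @param seed integer seed.
#' @param ... further arguments passed to [worm_spec()].
#' @return a [worm_spec()].
#' @export
random_worm_spec <- function(seed, ...) {
  set.seed(seed * 7L + 1L)
  amp <- stats::runif(1, 12, 26)
  phase <- stats::runif(1, 0, 2 * pi)
  cycles <- stats::runif(1, 1.5, 2.8)
  cp <- cbind(60 + amp * sin(phase + seq(0, cycles * pi, length.out = 7)),
              seq(90, 390, length.out = 7))
  args <- list(...)
  args$centerline_control <- args$centerline_control %||% cp
  args$max_half_width <- args$max_half_width %||% stats::runif(1, 7.5, 10)
  args$vulva_position <- args$vulva_position %||% stats::runif(1, 0.45, 0.62)
  args$seed <- seed
  do.call(worm_spec, args)
}

# dense centerline polyline (1-px spacing) through the control points
worm_centerline <- function(spec) {
  cp <- spec$centerline_control
  s <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  t_out <- seq(0, max(s), length.out = 4L * round(max(s)))
  pts <- cbind(stats::spline(s, cp[, 1L], xout = t_out)$y,
               stats::spline(s, cp[, 2L], xout = t_out)$y)
  resample_polyline(pts, 1)
}

# rasterize the worm as a union of per-sample discs; returns mask plus the
# arc position of the owning centerline sample for each in-mask pixel
rasterize_worm <- function(center, widths, canvas, offset = c(0, 0)) {
  nr <- canvas[1L]; nc <- canvas[2L]
  mask <- matrix(FALSE, nr, nc)
  arcpos <- matrix(NA_real_, nr, nc)
  mindist <- matrix(Inf, nr, nc)
  n <- nrow(center)
  u <- seq(0, 1, length.out = n)
  for (i in seq_len(n)) {
    w <- widths[i]
    if (w <= 0) next
    r0 <- center[i, 1L] + offset[1L]; c0 <- center[i, 2L] + offset[2L]
    rr <- max(1L, floor(r0 - w)):min(nr, ceiling(r0 + w))
    cc <- max(1L, floor(c0 - w)):min(nc, ceiling(c0 + w))
    if (!length(rr) || !length(cc)) next
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    hit <- d2 <= w^2
    if (!any(hit)) next
    sub <- mindist[rr, cc, drop = FALSE]
    take <- hit & (d2 < sub)
    mask[rr, cc][hit] <- TRUE
    arcpos[rr, cc][take] <- u[i]
    mindist[rr, cc][take] <- d2[take]
  }
  list(mask = mask, arcpos = arcpos)
}

#' Render a synthetic worm image series with ground truth
#'
#' Brightfield frames show a dark worm (interior speckle scaled by
#' `texture_roughness`) on a bright background; fluorescence frames add
#' Gaussian hotspots and a low diffuse body signal.  Sequential frames are
#' rigidly displaced by `motion_displacement` pixels in seeded random
#' directions.  Camera noise (SD `noise_sd`) is added last; the ground
#' truth describes the noiseless first frame.
#'
#' @param spec a [worm_spec()].
#' @param n_frames number of brightfield frames (the fluorescence frame is
#'   rendered at the first position).
#' @param noise_sd camera noise SD (0 for noiseless frames).
#' @param age_days age metadata stamped on the frames.
#' @return list with `brightfield` (list of [image_frame()]),
#'   `fluorescence` (one [image_frame()]), and `ground_truth`: a list with
#'   `mask`, `centerline`, `arc_length`, `vulva_pixel`, `hotspot_centers`,
#'   and `widths` (per-centerline-sample half-widths).
#' @export
generate_worm_image_series <- function(spec, n_frames = 3, noise_sd = 0.01,
                                       age_days = 5) {
  stopifnot(inherits(spec, "worm_spec"))
  set.seed(spec$seed)
  center <- worm_centerline(spec)
  n <- nrow(center)
  u <- seq(0, 1, length.out = n)
  widths <- spec$width_profile(u)
  wmax <- max(widths)
  # frame offsets: rigid displacement along a random direction per step
  offsets <- matrix(0, n_frames, 2L)
  if (n_frames > 1L && spec$motion_displacement > 0) {
    for (j in 2:n_frames) {
      ang <- stats::runif(1, 0, 2 * pi)
      step <- round(spec$motion_displacement * c(sin(ang), cos(ang)))
      if (all(step == 0)) step <- c(0, round(spec$motion_displacement))
      offsets[j, ] <- offsets[j - 1L, ] + step
    }
  }
  # bounds check across all frames
  for (j in seq_len(n_frames)) {
    r <- center[, 1L] + offsets[j, 1L]; c <- center[, 2L] + offsets[j, 2L]
    if (min(r - widths) < 1 || max(r + widths) > spec$canvas[1L] ||
        min(c - widths) < 1 || max(c + widths) > spec$canvas[2L])
      stop("worm exits the canvas; enlarge the canvas or reduce motion")
  }

  ras0 <- rasterize_worm(center, widths, spec$canvas)
  # interior speckle: fixed per-worm texture field, sampled in worm-local
  # coordinates so it travels with the animal
  speckle <- matrix(stats::rnorm(prod(spec$canvas)), spec$canvas[1L])
  speckle <- window_mean(speckle, 1)  # mild spatial correlation

  render_bf <- function(off, rng_noise) {
    ras <- if (all(off == 0)) ras0 else
      rasterize_worm(center, widths, spec$canvas, off)
    img <- matrix(0.85, spec$canvas[1L], spec$canvas[2L])
    body <- ras$mask
    tex <- speckle
    if (any(off != 0)) {  # shift texture rigidly with the worm
      tex <- matrix(0, nrow(tex), ncol(tex))
      src_r <- seq_len(nrow(tex)) - off[1L]
      src_c <- seq_len(ncol(tex)) - off[2L]
      ok_r <- src_r >= 1 & src_r <= nrow(tex)
      ok_c <- src_c >= 1 & src_c <= ncol(tex)
      tex[ok_r, ok_c] <- speckle[src_r[ok_r], src_c[ok_c]]
    }
    img[body] <- 0.35 + 0.12 * spec$texture_roughness * tex[body]
    if (rng_noise > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, rng_noise), nrow(img))
    img
  }

  hotspot_region_u <- c(head = 0.08, tail = 0.94)
  centers <- list()
  fluor <- matrix(0.02, spec$canvas[1L], spec$canvas[2L])
  fluor[ras0$mask] <- fluor[ras0$mask] + 0.05  # low body background
  rows <- matrix(rep(seq_len(spec$canvas[1L]), spec$canvas[2L]), spec$canvas[1L])
  cols <- matrix(rep(seq_len(spec$canvas[2L]), each = spec$canvas[1L]), spec$canvas[1L])
  hs <- spec$hotspots
  if (nrow(hs)) {
    for (i in seq_len(nrow(hs))) {
      reg <- as.character(hs$region[i])
      if (reg == "body") {
        fluor[ras0$mask] <- fluor[ras0$mask] + hs$intensity[i]
        next
      }
      u_hs <- if (reg == "vulva") spec$vulva_position else hotspot_region_u[[reg]]
      idx <- which.min(abs(u - u_hs))
      ctr <- center[idx, ]
      centers[[length(centers) + 1L]] <-
        c(row = ctr[1L], col = ctr[2L], region = reg)
      g <- hs$intensity[i] *
        exp(-((rows - ctr[1L])^2 + (cols - ctr[2L])^2) / (2 * hs$radius[i]^2))
      fluor <- fluor + g * ras0$mask
    }
  }
  if (noise_sd > 0)
    fluor <- fluor + matrix(stats::rnorm(length(fluor), 0, noise_sd), nrow(fluor))

  vulva_idx <- which.min(abs(u - spec$vulva_position))
  gt <- list(mask = ras0$mask,
             centerline = center,
             arc_length = polyline_length(center),
             vulva_pixel = center[vulva_idx, ],
             hotspot_centers = centers,
             widths = widths,
             arcpos = ras0$arcpos)

  bf <- lapply(seq_len(n_frames), function(j)
    image_frame(render_bf(offsets[j, ], noise_sd), "brightfield", 10, age_days))
  fl <- image_frame(fluor, "gfp", 100, age_days)
  list(brightfield = bf, fluorescence = fl, ground_truth = gt)
}
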