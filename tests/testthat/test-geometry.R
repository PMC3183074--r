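# Straightening, unit-worm warping, longitudinal alignment and EM.

test_that("straightening an already-straight worm equals the crop", {
  set.seed(1)
  img <- matrix(runif(80 * 200), 80, 200)
  img <- window_mean_test <- (img + wormspan:::window_mean(img, 2)) / 2
  cl <- cbind(rep(40, 101), 50:150)
  geom <- build_outline(cl, 5, function(u) rep(8, length(u)))
  st <- straighten(img, geom, half_span = 8)
  offs <- seq(-8, 8)
  expected <- t(img[40 - offs, 50:150])
  d <- abs(st$data - expected)
  expect_lt(mean(d), 0.02 * diff(range(img)))
})

test_that("a hotspot at arc position u lands on row u * n_rows", {
  fix <- unit_worm_image(3)
  wu <- fix$unit
  prof <- apply(wu$data * wu$valid, 1, max)
  vul <- fix$spec$vulva_position
  # search near the vulva hotspot (head/tail hotspots are elsewhere)
  rows <- pmax(1, round(vul * 100) - 15):pmin(100, round(vul * 100) + 15)
  peak <- rows[which.max(prof[rows])]
  expect_lte(abs(peak - vul * 100), 2)
})

test_that("straightening approximately preserves integrated intensity", {
  fix <- segment_fixture(9, noise_sd = 0)
  # smooth pattern over the frame
  img <- outer(seq(0, 1, length.out = 120), seq(1, 2, length.out = 480))
  geom <- build_outline(fix$gt$centerline, 5, fix$spec$width_profile)
  st <- straighten(img, geom)
  mask <- geometry_mask(geom, dim(img))
  expect_lt(abs(sum(st$data[st$valid]) - sum(img[mask])) / sum(img[mask]),
            0.05)
})

test_that("unit-worm warping is the identity on standard-sized input", {
  base <- pattern_image()
  geom_like <- straightened_image(base$data, base$valid,
                                  half_widths = rep((24 - 1) / 2, 100),
                                  age_days = 5)
  std <- structure(list(grid = c(100L, 24L), ages = 5,
                        standards = list(`5` = list(length = 100,
                                                    width_profile = rep(11.5, 100)))),
                   class = "unit_worm_standard")
  wu <- warp_to_unit(geom_like, std)
  expect_lt(max(abs(wu$data - base$data)), 1e-6 * diff(range(base$data)))
})

test_that("animals of different lengths coincide after unit warping", {
  mk <- function(scale) {
    cp <- cbind(60 + 18 * sin(seq(0, 2 * pi, length.out = 7)),
                seq(240 - scale * 120, 240 + scale * 120, length.out = 7))
    sp <- worm_spec(centerline_control = cp, vulva_position = 0.55, seed = 1)
    ser <- generate_worm_image_series(sp, n_frames = 1, noise_sd = 0)
    geom <- build_outline(ser$ground_truth$centerline, 5, sp$width_profile,
                          vulva = ser$ground_truth$vulva_pixel)
    st <- straighten(ser$fluorescence, geom)
    warp_to_unit(st, make_unit_standard(list(geom), 5))
  }
  a <- mk(1); b <- mk(0.72)
  peak_row <- function(w) {
    prof <- apply(w$data * w$valid, 1, max)
    rows <- 40:70
    rows[which.max(prof[rows])]
  }
  expect_lte(abs(peak_row(a) - peak_row(b)), 2)
})

test_that("unit warping preserves the rank order of intensity summaries", {
  set.seed(2)
  scales <- runif(10, 0.5, 2)
  p95 <- t(vapply(seq_along(scales), function(i) {
    fix <- unit_worm_image(20 + i, intensity_scale = scales[i])
    c(straight = fluorescence_summary(fix$straight),
      unit = fluorescence_summary(fix$unit))
  }, numeric(2)))
  expect_gte(stats::cor(p95[, 1], p95[, 2], method = "spearman"), 0.95)
})

test_that("longitudinal warps are monotone by construction", {
  expect_error(longitudinal_warp(c(0.2, -0.2, 0, 0, 0)), "monotone")
  w <- longitudinal_warp(c(0.05, 0.02, -0.03, 0.01, 0))
  v <- seq(0, 1, length.out = 101)
  expect_true(all(diff(wormspan:::warp_map(w, v)) >= 0))
  expect_equal(wormspan:::warp_map(w, c(0, 1)), c(0, 1))
})

test_that("alignment of an image to itself keeps zero displacement", {
  img <- pattern_image()
  fit <- longitudinal_align(img, img, lambda = 1)
  expect_equal(fit$warp$displacements, rep(0, 5))
})

test_that("a known five-point warp is recovered at lambda = 0", {
  img <- pattern_image()
  true_d <- c(0.02, -0.03, 0.04, 0.0, -0.02)
  ref <- pattern_image(true_d)
  fit <- longitudinal_align(img, ref, lambda = 0)
  expect_lt(max(abs(fit$warp$displacements - true_d)), 0.01)
})

test_that("an overwhelming penalty forces the identity warp", {
  img <- pattern_image()
  ref <- pattern_image(c(0.04, 0.04, 0.04, 0, 0))
  fit <- longitudinal_align(img, ref, lambda = 1e6)
  expect_equal(fit$warp$displacements, rep(0, 5))
})

test_that("constant images yield an identity warp with a warning", {
  const <- straightened_image(matrix(1, 100, 24), matrix(TRUE, 100, 24))
  expect_warning(fit <- longitudinal_align(const, pattern_image()),
                 "constant")
  expect_equal(fit$warp$displacements, rep(0, 5))
})

test_that("hill climbing matches an exhaustive grid search on small images", {
  mk_small <- function(d = NULL) {
    u <- seq(0, 1, length.out = 32)
    base <- outer(sin(4 * pi * u) + 0.4 * cos(2 * pi * u), rep(1, 8))
    img <- straightened_image(base, matrix(TRUE, 32, 8))
    if (!is.null(d)) img <- apply_longitudinal_warp(img, longitudinal_warp(d))
    img
  }
  img <- mk_small()
  ref <- mk_small(c(0.02, 0, -0.02, 0.04, 0))
  lambda <- 1
  fit <- longitudinal_align(img, ref, lambda = lambda)
  # exhaustive search, step 0.02 in [-0.04, 0.04]^5
  grid <- seq(-0.04, 0.04, by = 0.02)
  combos <- expand.grid(grid, grid, grid, grid, grid)
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    d <- as.numeric(combos[r, ])
    w <- tryCatch(longitudinal_warp(d, lambda), error = function(e) NULL)
    if (is.null(w)) next
    wi <- apply_longitudinal_warp(img, w)
    val <- wormspan:::align_objective(wi$data, wi$valid, ref$data, ref$valid,
                                      d, lambda)
    if (val > best) best <- val
  }
  expect_gte(fit$objective, best - 0.01)
})

test_that("EM alignment: identical inputs converge immediately", {
  img <- pattern_image()
  em <- em_align_population(list(img, img, img))
  expect_equal(em$iterations, 1L)
  expect_equal(em$mean, img$data, tolerance = 1e-9)
})

test_that("EM alignment sharpens the mean and converges in few iterations", {
  set.seed(9)
  imgs <- lapply(1:30, function(i) {
    repeat {
      d <- runif(5, -0.08, 0.08)
      w <- tryCatch(longitudinal_warp(d), error = function(e) NULL)
      if (!is.null(w)) return(pattern_image(d))
    }
  })
  em <- em_align_population(imgs, lambda = 1, max_iter = 8)
  grad_energy <- function(m) sum(diff(m)^2)
  unaligned_mean <- Reduce(`+`, lapply(imgs, `[[`, "data")) / length(imgs)
  expect_gte(grad_energy(em$mean) / grad_energy(unaligned_mean), 1.2)
  expect_lte(em$iterations, 3L)
  # objective (mean correlation with the mean, minus penalties) does not
  # decrease across iterations
  if (length(em$objective) > 1L)
    expect_true(all(diff(em$objective) > -1e-6))
})
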