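# Shared fixture builders: everything is generated in code at test time.

# render a worm, train a pixel classifier on its ground truth, and segment
segment_fixture <- function(seed, n_frames = 1, noise_sd = 0.01, ...) {
  sp <- random_worm_spec(seed, ...)
  ser <- generate_worm_image_series(sp, n_frames = n_frames,
                                    noise_sd = noise_sd)
  gt <- ser$ground_truth
  feats <- patch_features(ser$brightfield[[1]], 4)
  lab <- as.vector(gt$mask)
  set.seed(seed)
  idx <- c(sample(which(lab), 400), sample(which(!lab), 400))
  clf <- train_pixel_classifier(feats[idx, ], lab[idx])
  mask <- classify_and_mask(ser$brightfield[[1]], clf)
  list(spec = sp, series = ser, gt = gt, clf = clf, mask = mask)
}

# straightened unit-worm image of a rendered worm's fluorescence channel
unit_worm_image <- function(seed, hotspots = NULL, noise_sd = 0.01,
                            intensity_scale = 1) {
  args <- list(seed)
  if (!is.null(hotspots)) args$hotspots <- hotspots
  sp <- do.call(random_worm_spec, args)
  if (intensity_scale != 1) {
    sp$hotspots$intensity <- sp$hotspots$intensity * intensity_scale
  }
  ser <- generate_worm_image_series(sp, n_frames = 1, noise_sd = noise_sd)
  gt <- ser$ground_truth
  geom <- build_outline(gt$centerline, 5, sp$width_profile,
                        vulva = gt$vulva_pixel)
  st <- straighten(ser$fluorescence, geom)
  wu <- warp_to_unit(st, make_unit_standard(list(geom), 5))
  list(unit = wu, straight = st, geom = geom, gt = gt, spec = sp)
}

# straightened image with longitudinally identifiable structure
pattern_image <- function(d = NULL, rows = 100, cols = 24) {
  u <- seq(0, 1, length.out = rows)
  base <- outer(sin(6 * pi * u) + 0.5 * sin(2 * pi * u + 1), rep(1, cols)) +
    outer(rep(1, rows), stats::dnorm(seq(-2, 2, length.out = cols)))
  img <- straightened_image(base, matrix(TRUE, rows, cols))
  if (!is.null(d)) img <- apply_longitudinal_warp(img, longitudinal_warp(d))
  img
}

# recovered R2 of lifespan on the day-window slope for one cohort seed
recovered_slope_r2 <- function(planted, seed, n = 400, loo = FALSE) {
  co <- generate_cohort(cohort_config(n_animals = n,
                                      planted_r2 = c(length = planted),
                                      seed = seed))
  s <- summarize_cohort(co$timecourses)
  y <- co$animals$lifespan_days[match(s$animal_id, co$animals$animal_id)]
  ols_predict(s[, "length_slope", drop = FALSE], y, loo = loo)
}
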