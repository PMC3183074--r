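# Pixel classifier, mask extraction, centerline search and frame pairing.

test_that("classifier separates synthetic contrast and reports accuracy", {
  fix <- segment_fixture(1)
  expect_gte(fix$clf$training_accuracy, 0.99)
})

test_that("classifier degenerate inputs behave as specified", {
  X <- cbind(mean = c(rep(0.3, 50), rep(0.9, 50)), center = rnorm(100, 0.5, 0.01))
  y <- rep(c(TRUE, FALSE), each = 50)
  expect_error(train_pixel_classifier(X, rep(TRUE, 100)), "both classes")
  # flipped labels negate the feature weights
  a <- train_pixel_classifier(X, y)
  b <- train_pixel_classifier(X, !y)
  ca <- stats::coef(a$model)[-1]; cb <- stats::coef(b$model)[-1]
  expect_equal(unname(ca), unname(-cb), tolerance = 1e-6)
  # identical features for both classes: predicted probability = class prior
  Xsame <- cbind(mean = rep(0.5, 90), center = rep(0.2, 90))
  prior <- 1 / 3
  c3 <- train_pixel_classifier(Xsame, rep(c(TRUE, FALSE, FALSE), 30))
  p <- stats::fitted(c3$model)
  expect_equal(unname(p), rep(prior, 90), tolerance = 1e-6)
})

test_that("masking keeps the largest component, fills holes, flags empties", {
  fix <- segment_fixture(2)
  dice <- 2 * sum(fix$mask & fix$gt$mask) / (sum(fix$mask) + sum(fix$gt$mask))
  expect_gte(dice, 0.90)
  expect_true(all(dim(fix$mask) == dim(fix$gt$mask)))
  # uniform background: nothing above threshold
  flat <- image_frame(matrix(0.85, 60, 60))
  expect_error(classify_and_mask(flat, fix$clf), class = "wormspan_no_animal")
  # two blobs: only the larger is retained
  img <- matrix(0.85, 80, 120)
  img[20:40, 10:80] <- 0.35   # large
  img[60:70, 95:110] <- 0.35  # small
  set.seed(1)
  img <- img + matrix(rnorm(length(img), 0, 0.005), nrow(img))
  feats <- patch_features(img, 4)
  lab <- as.vector(img < 0.6)
  idx <- c(sample(which(lab), 200), sample(which(!lab), 200))
  clf <- train_pixel_classifier(feats[idx, ], lab[idx])
  m <- classify_and_mask(img, clf)
  expect_true(mean(m[20:40, 10:80]) > 0.9)
  expect_true(all(!m[60:70, 95:110]))
})

test_that("centerline of a rectangle is its midline", {
  mask <- matrix(FALSE, 11, 50)
  mask[4:8, 1:50] <- TRUE  # midline at row 6
  cl <- extract_centerline(mask, head = c(6, 1), tail = c(6, 50), smooth = 1)
  expect_equal(unique(round(cl[, 1])), 6)
  expect_equal(polyline_len <- sum(sqrt(rowSums(diff(cl)^2))), 49,
               tolerance = 1e-9)
})

test_that("centerline recovers the synthetic arc length within 3%", {
  for (sd in c(3, 4)) {
    fix <- segment_fixture(sd)
    cl <- extract_centerline(
      fix$mask, round(fix$gt$centerline[1, ]),
      round(fix$gt$centerline[nrow(fix$gt$centerline), ]))
    len <- sum(sqrt(rowSums(diff(cl)^2)))
    expect_lt(abs(len - fix$gt$arc_length) / fix$gt$arc_length, 0.03)
  }
})

test_that("least-cost path cost matches a brute-force Dijkstra oracle", {
  set.seed(7)
  mask <- matrix(FALSE, 20, 20)
  mask[3:18, 2:19] <- TRUE
  mask[8:12, 6:10] <- FALSE  # notch forces a non-trivial detour
  cost <- wormspan:::centerline_cost(mask)
  g <- wormspan:::mask_graph(mask, cost[which(mask)])
  from <- c(4, 3); to <- c(17, 18)
  nr <- nrow(mask)
  sp <- igraph::shortest_paths(
    g$graph, from = match((from[2] - 1) * nr + from[1], g$idx),
    to = match((to[2] - 1) * nr + to[1], g$idx), output = "vpath")
  pkg_cost <- sum(cost[g$idx[as.integer(sp$vpath[[1]])][-1]])
  oracle <- brute_dijkstra_cost(mask, cost, from, to)
  expect_equal(pkg_cost, oracle, tolerance = 1e-10)
})

test_that("centerline endpoint preconditions are enforced", {
  mask <- matrix(FALSE, 11, 30); mask[4:8, ] <- TRUE
  expect_error(extract_centerline(mask, c(1, 1), c(6, 30)), "inside the mask")
  expect_error(extract_centerline(mask, c(6, 5), c(6, 5)), "coincide")
  split_mask <- mask; split_mask[, 15] <- FALSE
  expect_error(extract_centerline(split_mask, c(6, 2), c(6, 29)),
               "disconnected")
})

test_that("centerline is invariant to 90-degree rotation within 1 px", {
  fix <- segment_fixture(5)
  cl <- extract_centerline(fix$mask, round(fix$gt$centerline[1, ]),
                           round(fix$gt$centerline[nrow(fix$gt$centerline), ]))
  rot <- t(fix$mask[nrow(fix$mask):1, ])  # clockwise
  map <- function(p) c(p[2], nrow(fix$mask) + 1 - p[1])
  cl_rot <- extract_centerline(rot, map(round(fix$gt$centerline[1, ])),
                               map(round(fix$gt$centerline[nrow(fix$gt$centerline), ])))
  back <- cbind(nrow(fix$mask) + 1 - cl_rot[, 2], cl_rot[, 1])
  # directed nearest-vertex distance from rotated-back to original
  dmax <- max(apply(back, 1, function(p)
    sqrt(min(colSums((t(cl) - p)^2)))))
  expect_lte(dmax, 1.5)
})

test_that("outlines honor the width model and head fraction", {
  # straight centerline, constant half-width: area of a rounded rectangle
  cl <- cbind(rep(30, 101), 20:120)
  geom <- build_outline(cl, 5, function(u) rep(5, length(u)))
  mask <- geometry_mask(geom, c(60, 140))
  stadium <- 100 * 2 * 5 + pi * 5^2  # rectangle plus end caps
  expect_lt(abs(sum(mask) - stadium) / stadium, 0.10)
  head_mask <- geometry_mask(geom, c(60, 140), head_only = TRUE)
  expect_lt(sum(head_mask) / sum(mask), 0.30)
  # head region covers the initial 20% of arc length (within one sample)
  n <- nrow(geom$centerline)
  expect_lt(abs(max(2, ceiling(0.2 * n)) / n - 0.20), 1 / n + 1e-9)
  expect_error(build_outline(cl[1, , drop = FALSE], 5,
                             function(u) rep(5, length(u))), "degenerate")
  # synthetic worm: outline area within 10% of ground-truth mask area
  fix <- segment_fixture(6)
  geom2 <- build_outline(fix$gt$centerline, 5, fix$spec$width_profile)
  m2 <- geometry_mask(geom2, dim(fix$gt$mask))
  expect_lt(abs(sum(m2) - sum(fix$gt$mask)) / sum(fix$gt$mask), 0.10)
})

test_that("mutual-information pairing behaves as a proper MI", {
  fix <- segment_fixture(8)
  bf <- fix$series$brightfield[[1]]$data
  fl <- fix$series$fluorescence$data
  shift_cols <- function(m, k) {
    out <- matrix(stats::median(m), nrow(m), ncol(m))
    out[, (1 + k):ncol(m)] <- m[, 1:(ncol(m) - k)]
    out
  }
  cands <- list(bf, shift_cols(bf, 5), shift_cols(bf, 15))
  expect_equal(pair_brightfield_to_fluorescence(cands, fl), 1L)
  # identity is maximal; MI symmetric and nonnegative
  expect_equal(pair_brightfield_to_fluorescence(c(list(fl), cands), fl), 1L)
  expect_equal(mutual_information(bf, fl), mutual_information(fl, bf),
               tolerance = 1e-12)
  expect_gte(mutual_information(bf, fl), 0)
  expect_gte(mutual_information(fl, fl), mutual_information(bf, fl))
  # constant frames tie at MI = 0; earliest index wins
  const <- matrix(1, 10, 10)
  expect_equal(mutual_information(const, const), 0)
  expect_equal(pair_brightfield_to_fluorescence(
    list(const, const + 1), const), 1L)
  expect_error(pair_brightfield_to_fluorescence(list(), fl), "empty")
})

test_that("exposure bracketing picks the longest non-overexposed frame", {
  frames <- list(image_frame(matrix(0.2, 4, 4), exposure_ms = 1),
                 image_frame(matrix(0.8, 4, 4), exposure_ms = 10),
                 image_frame(matrix(1.0, 4, 4), exposure_ms = 100))
  expect_equal(select_exposure(frames)$exposure_ms, 10)
  expect_error(select_exposure(frames[3]), "overexposed")
})
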