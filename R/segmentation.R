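# Locating the animal in brightfield frames: a logistic pixel-patch
# classifier produces a probability map; the largest above-threshold
# connected component (holes filled) is the mask; the centerline is the
# least-cost path through the inverted Euclidean distance transform; flank
# outlines come from an age-average width model; brightfield frames are
# paired to fluorescence frames by maximal mutual information.

#' Per-pixel patch features for the nematode classifier
#'
#' For every pixel, the mean, standard deviation, minimum and maximum of
#' intensity over a square patch of the given radius, plus the center-pixel
#' value.  Borders are edge-replicated.
#'
#' @param image an [image_frame()] or numeric matrix.
#' @param radius patch radius in pixels (patch side `2 * radius + 1`).
#' @return numeric matrix, one row per pixel (column-major order), columns
#'   `mean`, `sd`, `min`, `max`, `center`.
#' @export
patch_features <- function(image, radius = 4) {
  img <- if (inherits(image, "image_frame")) image$data else image
  if (nrow(img) < 2 * radius + 1 || ncol(img) < 2 * radius + 1)
    stop("image dimensions must be at least the patch size")
  m <- window_mean(img, radius)
  m2 <- window_mean(img^2, radius)
  s <- sqrt(pmax(m2 - m^2, 0))
  cbind(mean = as.vector(m), sd = as.vector(s),
        min = as.vector(window_extremum(img, radius, "min")),
        max = as.vector(window_extremum(img, radius, "max")),
        center = as.vector(img))
}

#' Train the logistic nematode/non-nematode pixel classifier
#'
#' Maximum-likelihood logistic regression on labeled patch features.
#'
#' @param features numeric matrix of patch features (as from
#'   [patch_features()]).
#' @param inside logical vector: is the patch inside an animal?
#' @param threshold probability cutoff used downstream, in (0, 1).
#' @return object of class `pixel_classifier` with elements `model`
#'   (the fitted glm), `threshold`, `radius` inherited from the features,
#'   and `training_accuracy`.
#' @export
train_pixel_classifier <- function(features, inside, threshold = 0.5) {
  stopifnot(is.matrix(features), length(inside) == nrow(features))
  if (length(unique(inside)) < 2L)
    stop("both classes must be present in the training set")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  df <- as.data.frame(features)
  df$.inside <- as.integer(inside)
  fit <- suppressWarnings(
    stats::glm(.inside ~ ., data = df, family = stats::binomial()))
  p <- stats::fitted(fit)
  acc <- mean((p >= threshold) == inside)
  structure(list(model = fit, threshold = threshold,
                 feature_names = colnames(features),
                 training_accuracy = acc),
            class = "pixel_classifier")
}

#' Predict in-animal probability for every pixel
#' @param image an [image_frame()] or matrix.
#' @param clf a [train_pixel_classifier()] result.
#' @param radius patch radius used for feature extraction.
#' @return matrix of probabilities in `[0, 1]`.
#' @export
classify_pixels <- function(image, clf, radius = 4) {
  feats <- patch_features(image, radius)
  p <- suppressWarnings(
    stats::predict(clf$model, newdata = as.data.frame(feats),
                   type = "response"))
  img <- if (inherits(image, "image_frame")) image$data else image
  matrix(p, nrow(img), ncol(img))
}

#' Segment the animal: probability map to binary mask
#'
#' Thresholds the classifier probability map, keeps the largest connected
#' above-threshold component and fills its holes.
#'
#' @inheritParams classify_pixels
#' @return logical mask matrix.  Signals a condition of class
#'   `wormspan_no_animal` if no pixel exceeds the threshold.
#' @export
classify_and_mask <- function(image, clf, radius = 4) {
  prob <- classify_pixels(image, clf, radius)
  bin <- prob >= clf$threshold
  if (!any(bin))
    stop(structure(class = c("wormspan_no_animal", "error", "condition"),
                   list(message = "no animal found in frame", call = NULL)))
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask) > 0
  matrix(as.logical(mask), nrow(mask))
}

# brute-force-checkable node cost for the valley path
centerline_cost <- function(mask, step_penalty = 1e-3) {
  dt <- EBImage::distmap(mask)
  (max(dt) - dt) + step_penalty
}

#' Default head/tail seed points: maximal geodesic distance in the mask
#'
#' Double-sweep heuristic: geodesic-farthest point from an arbitrary mask
#' pixel, then the farthest point from that one.
#'
#' @param mask logical matrix.
#' @return list with `head` and `tail`, each `c(row, col)`.
#' @export
default_endpoints <- function(mask) {
  g <- mask_graph(mask, rep(1, sum(mask)))
  idx <- which(mask)
  far <- function(from) {
    d <- igraph::distances(g$graph, v = match(from, idx), weights = NA)
    idx[which.max(d)]
  }
  a <- far(idx[1L]); b <- far(a)
  to_rc <- function(i) c(row = (i - 1L) %% nrow(mask) + 1L,
                         col = (i - 1L) %/% nrow(mask) + 1L)
  list(head = to_rc(b), tail = to_rc(a))
}

# 8-connected directed lattice graph over mask pixels; edge weight =
# node cost of the target pixel
mask_graph <- function(mask, cost_values) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  node_of <- integer(nr * nc); node_of[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- mask[j]
    from <- c(from, node_of[idx[ok]][ok2])
    tgt <- node_of[j[ok2]]
    to <- c(to, tgt)
    w <- c(w, cost_values[tgt])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = TRUE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  list(graph = g, idx = idx)
}

#' Extract the centerline as a least-cost valley path
#'
#' The mask is Euclidean-distance-transformed; the per-pixel path cost is
#' `(max(DT) - DT) + 1e-3`, so the globally cheapest 8-connected path from
#' head to tail runs along the interior ridge of the animal with a mild
#' shortness bias.  Dijkstra's algorithm finds the path; the result is
#' resampled to uniform 1-px arc spacing.
#'
#' @param mask logical matrix (connected).
#' @param head,tail `c(row, col)` seed points inside the mask; defaults to
#'   the two mask pixels at maximal geodesic distance.
#' @param step_penalty additive per-step cost.
#' @param smooth odd window length of the endpoint-preserving running-mean
#'   smoother applied to the raw 8-connected path before resampling
#'   (removes the staircase length inflation; 1 disables smoothing).
#' @return matrix (row, col): the centerline polyline, head first.
#' @export
extract_centerline <- function(mask, head = NULL, tail = NULL,
                               step_penalty = 1e-3, smooth = 9L) {
  stopifnot(is.matrix(mask))
  if (is.null(head) || is.null(tail)) {
    ep <- default_endpoints(mask)
    if (is.null(head)) head <- ep$head
    if (is.null(tail)) tail <- ep$tail
  }
  nr <- nrow(mask)
  h_i <- (head[2L] - 1L) * nr + head[1L]
  t_i <- (tail[2L] - 1L) * nr + tail[1L]
  if (!mask[h_i] || !mask[t_i]) stop("head and tail must lie inside the mask")
  if (h_i == t_i) stop("head and tail coincide")
  cost <- centerline_cost(mask, step_penalty)
  g <- mask_graph(mask, cost[g_idx <- which(mask)])
  from <- match(h_i, g$idx); to <- match(t_i, g$idx)
  sp <- suppressWarnings(
    igraph::shortest_paths(g$graph, from = from, to = to, mode = "out",
                           output = "vpath"))
  vp <- sp$vpath[[1L]]
  if (length(vp) == 0L) stop("mask is disconnected between head and tail")
  pix <- g$idx[as.integer(vp)]
  path <- cbind((pix - 1L) %% nr + 1L, (pix - 1L) %/% nr + 1L)
  if (smooth > 1L && nrow(path) > smooth) {
    half <- smooth %/% 2L
    pad <- rbind(path[rep(1L, half), , drop = FALSE], path,
                 path[rep(nrow(path), half), , drop = FALSE])
    ker <- rep(1 / smooth, smooth)
    sm <- apply(pad, 2L, function(x)
      stats::filter(x, ker, sides = 2)[(half + 1L):(half + nrow(path))])
    sm[1L, ] <- path[1L, ]; sm[nrow(sm), ] <- path[nrow(path), ]
    path <- sm
  }
  resample_polyline(path, 1)
}

#' Worm geometry: centerline, flank outlines, vulva anchor, head region
#'
#' @param centerline polyline matrix (row, col), head first.
#' @param left,right flank polylines sharing the centerline endpoints.
#' @param vulva optional `c(row, col)` anchor.
#' @param half_widths per-centerline-sample half-widths, pixels.
#' @param head_fraction initial fraction of arc length forming the "head"
#'   region (default 0.20).
#' @return object of class `worm_geometry`.
#' @export
worm_geometry <- function(centerline, left, right, vulva = NULL,
                          half_widths = NULL, head_fraction = 0.20) {
  stopifnot(is.matrix(centerline), nrow(centerline) >= 2L)
  structure(list(centerline = centerline, left = left, right = right,
                 vulva = vulva, half_widths = half_widths,
                 head_fraction = head_fraction),
            class = "worm_geometry")
}

#' Build flank outlines from a centerline and an age-average width model
#'
#' Flanks are offset perpendicular to the centerline by the age-average
#' half-width profile; the profile is zero at both ends so flanks and
#' centerline share endpoints.
#'
#' @param centerline polyline matrix (row, col).
#' @param age animal age in days.
#' @param width_model either a function of normalized arc position
#'   returning half-widths, or a named list of such functions keyed by
#'   integer age (nearest available age is used otherwise).
#' @param vulva optional vulva anchor.
#' @return a [worm_geometry()].
#' @export
build_outline <- function(centerline, age, width_model, vulva = NULL) {
  if (nrow(centerline) < 2L || polyline_length(centerline) <= 0)
    stop("degenerate (zero-length) centerline")
  wf <- width_model
  if (is.list(width_model)) {
    ages <- as.numeric(names(width_model))
    wf <- width_model[[which.min(abs(ages - age))]]
  }
  n <- nrow(centerline)
  u <- seq(0, 1, length.out = n)
  w <- wf(u)
  w[c(1L, n)] <- 0
  tang <- rbind(centerline[2L, ] - centerline[1L, ],
                (centerline[3:n, , drop = FALSE] -
                   centerline[1:(n - 2L), , drop = FALSE]) / 2,
                centerline[n, ] - centerline[n - 1L, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  normal <- cbind(-tang[, 2L], tang[, 1L])
  worm_geometry(centerline,
                left = centerline + normal * w,
                right = centerline - normal * w,
                vulva = vulva, half_widths = w)
}

#' Rasterize a worm geometry into a mask
#'
#' Union of per-centerline-sample discs of the geometry's half-widths;
#' the region within the flank outlines up to disc discretization.
#'
#' @param geom a [worm_geometry()].
#' @param dim `c(rows, cols)` of the target mask.
#' @param head_only if `TRUE`, rasterize only the head region (initial
#'   `head_fraction` of the arc length).
#' @return logical mask.
#' @export
geometry_mask <- function(geom, dim, head_only = FALSE) {
  n <- nrow(geom$centerline)
  take <- if (head_only) seq_len(max(2L, ceiling(geom$head_fraction * n)))
          else seq_len(n)
  w <- geom$half_widths
  if (is.null(w)) {
    w <- sqrt(rowSums((geom$left - geom$right)^2)) / 2
  }
  ras <- rasterize_worm(geom$centerline[take, , drop = FALSE], w[take], dim)
  ras$mask
}

#' Mutual information between two images' intensity histograms
#'
#' Joint 2-D histogram over each image's own intensity range (default
#' 64 x 64 bins); MI in nats.  Constant images yield 0.
#'
#' @param a,b numeric matrices of equal dimension.
#' @param bins number of bins per axis.
#' @return nonnegative scalar.
#' @export
mutual_information <- function(a, b, bins = 64) {
  stopifnot(all(dim(a) == dim(b)))
  cutbin <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(rep(1L, length(x)))
    pmin(pmax(1L, as.integer(ceiling((x - rng[1L]) / diff(rng) * bins))), bins)
  }
  ia <- cutbin(as.vector(a)); ib <- cutbin(as.vector(b))
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins) / length(ia)
  pj <- matrix(joint, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
}

#' Pair a fluorescence frame with its best brightfield candidate
#'
#' Returns the index of the candidate with maximal mutual information with
#' the fluorescence frame (ties broken by earliest index).
#'
#' @param candidates list of [image_frame()]s or matrices.
#' @param fluor [image_frame()] or matrix of the fluorescence frame.
#' @param bins histogram bins per axis.
#' @return integer index into `candidates`.
#' @export
pair_brightfield_to_fluorescence <- function(candidates, fluor, bins = 64) {
  if (length(candidates) == 0L) stop("empty candidate list")
  f <- if (inherits(fluor, "image_frame")) fluor$data else fluor
  mi <- vapply(candidates, function(x) {
    m <- if (inherits(x, "image_frame")) x$data else x
    mutual_information(m, f, bins)
  }, numeric(1))
  which.max(mi)  # which.max returns the earliest maximum
}

#' Select the longest non-overexposed fluorescence frame
#'
#' Exposure bracketing reduces to taking the longest exposure whose maximal
#' intensity stays below the saturation level.
#'
#' @param frames list of [image_frame()]s.
#' @param saturation intensity treated as overexposed.
#' @return the selected [image_frame()].
#' @export
select_exposure <- function(frames, saturation = 1) {
  expo <- vapply(frames, function(f) f$exposure_ms, numeric(1))
  ok <- vapply(frames, function(f) max(f$data) < saturation, logical(1))
  if (!any(ok)) stop("all candidate frames overexposed")
  frames[[which(ok)[which.max(expo[ok])]]]
}
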