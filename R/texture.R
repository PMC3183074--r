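# Texton-based texture decrepitude: per-age-bin k-means dictionaries of
# 17x17 brightfield patches and nearest-texton histogram signatures.

# age bins: day 3-4, 5-6, ..., 15-16 (7 bins); ages beyond 16 reuse the
# last bin
texton_age_bin <- function(age) {
  if (any(age < 3)) stop("texture is defined from day 3 onward")
  pmin(floor((age - 3) / 2), 6) + 1L
}

# sample patch centers inside the mask with the full patch in bounds
sample_patch_matrix <- function(img, mask, n, patch = 17L) {
  half <- patch %/% 2L
  ok <- mask
  ok[c(seq_len(half), nrow(ok) - seq_len(half) + 1L), ] <- FALSE
  ok[, c(seq_len(half), ncol(ok) - seq_len(half) + 1L)] <- FALSE
  centers <- which(ok)
  if (!length(centers)) return(NULL)
  if (length(centers) > n) centers <- sample(centers, n)
  r <- (centers - 1L) %% nrow(img) + 1L
  c <- (centers - 1L) %/% nrow(img) + 1L
  t(vapply(seq_along(centers), function(i) {
    p <- img[(r[i] - half):(r[i] + half), (c[i] - half):(c[i] + half)]
    as.vector(p) - mean(p)  # per-patch mean removed
  }, numeric(patch * patch)))
}

#' Build the per-age-bin texton dictionary
#'
#' Brightfield patches (17 x 17 px, per-patch mean removed) are sampled
#' within the animal outlines, grouped into two-day age bins (day 3-4
#' through 15-16), and k-means clustered into 30 representative textons per
#' bin (210 overall).
#'
#' @param images list of matrices or [image_frame()]s (brightfield).
#' @param masks list of logical in-animal masks, one per image.
#' @param ages numeric ages (days), one per image; every two-day bin from
#'   3-4 to 15-16 must be represented.
#' @param n_per_bin patches sampled per bin (default 20000; scale down for
#'   small studies).
#' @param patch patch side length, pixels.
#' @param k textons per bin.
#' @param seed sampling/k-means seed.
#' @return object of class `texton_dictionary`: list with `centroids`
#'   (`(7 * k) x patch^2` matrix), `bin` (bin index per centroid), `patch`.
#' @export
build_texton_dictionary <- function(images, masks, ages, n_per_bin = 20000,
                                    patch = 17L, k = 30L, seed = 1) {
  stopifnot(length(images) == length(masks), length(images) == length(ages))
  set.seed(seed)
  imgs <- lapply(images, function(x)
    if (inherits(x, "image_frame")) x$data else x)
  bins <- texton_age_bin(ages)
  missing_bins <- setdiff(1:7, unique(bins))
  if (length(missing_bins))
    stop("no images in age bin(s): ",
         paste(sprintf("day %d-%d", 2 * missing_bins + 1, 2 * missing_bins + 2),
               collapse = ", "))
  cents <- vector("list", 7L)
  for (b in 1:7) {
    ix <- which(bins == b)
    per_img <- ceiling(n_per_bin / length(ix))
    P <- do.call(rbind, lapply(ix, function(i)
      sample_patch_matrix(imgs[[i]], masks[[i]], per_img, patch)))
    if (is.null(P) || nrow(P) < k)
      stop(sprintf("too few patches in age bin %d", b))
    km <- stats::kmeans(P, centers = k, iter.max = 50L, nstart = 1L)
    cents[[b]] <- km$centers
  }
  structure(list(centroids = do.call(rbind, cents),
                 bin = rep(1:7, each = k), patch = as.integer(patch),
                 k = as.integer(k)),
            class = "texton_dictionary")
}

# nearest-centroid index for each patch row (squared Euclidean distance)
nearest_texton <- function(P, centroids) {
  d2 <- outer(rowSums(P^2), rowSums(centroids^2), "+") -
    2 * P %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

#' Texture signature of an image
#'
#' Every in-outline patch (configurable stride) is assigned to its nearest
#' texton over all 210; the signature is the normalized 210-bin histogram
#' of assignments.
#'
#' @param image matrix or [image_frame()].
#' @param mask logical in-animal mask.
#' @param dict a [build_texton_dictionary()].
#' @param stride patch-center grid stride, pixels.
#' @return numeric vector of length `nrow(dict$centroids)` summing to 1.
#' @export
texture_signature <- function(image, mask, dict, stride = 4L) {
  img <- if (inherits(image, "image_frame")) image$data else image
  half <- dict$patch %/% 2L
  rs <- seq(half + 1L, nrow(img) - half, by = stride)
  cs <- seq(half + 1L, ncol(img) - half, by = stride)
  centers <- expand.grid(r = rs, c = cs)
  inside <- mask[cbind(centers$r, centers$c)]
  centers <- centers[inside, , drop = FALSE]
  if (!nrow(centers)) stop("no valid in-outline patches")
  P <- t(vapply(seq_len(nrow(centers)), function(i) {
    p <- img[(centers$r[i] - half):(centers$r[i] + half),
             (centers$c[i] - half):(centers$c[i] + half)]
    as.vector(p) - mean(p)
  }, numeric(dict$patch^2)))
  idx <- nearest_texton(P, dict$centroids)
  tabulate(idx, nbins = nrow(dict$centroids)) / nrow(P)
}
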