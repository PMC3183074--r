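# Eigen-image analysis of aligned, per-image-mean-subtracted fluorescence
# images.  Because the per-image mean is removed first, the components
# capture only the spatial distribution of expression, not overall
# brightness.  Scores are expressed in SD units of the training population.

# flatten a straightened image: subtract its mean over valid pixels, zero
# the invalid pixels
flatten_expression_image <- function(img) {
  x <- img$data
  v <- img$valid
  if (!any(v)) stop("image has no valid pixels")
  x <- x - mean(x[v])
  x[!v] <- 0
  as.vector(x)
}

#' Fit the expression-pattern PCA model
#'
#' Verifies (and if needed re-applies) per-image mean subtraction, centers
#' by the mean image, and eigendecomposes the image covariance (via SVD of
#' the image-by-pixel matrix, the Gram route when pixels far exceed
#' images).  Components are signed so that the mean PC loading over the
#' head region (initial 20% of rows) is positive: positive scores then
#' indicate head/vulva/tail-specific expression.
#'
#' @param images list of [straightened_image()]s on a common grid.
#' @param n_components number of components to retain (default all).
#' @return object of class `expression_pca`: list with `mean` (mean image
#'   vector), `components` (pixels x components, orthonormal columns),
#'   `score_sd` (training-score SD per component), `variance_fraction`,
#'   `grid`, `head_rows`.
#' @export
fit_expression_pca <- function(images, n_components = NULL) {
  if (length(images) < 2L) stop("at least 2 images required")
  grid <- dim(images[[1L]]$data)
  stopifnot(all(vapply(images, function(x) all(dim(x$data) == grid),
                       logical(1))))
  X <- t(vapply(images, flatten_expression_image, numeric(prod(grid))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  n <- nrow(Xc)
  sv <- svd(Xc, nu = 0)
  keep <- which(sv$d > max(sv$d) * 1e-10)
  if (!is.null(n_components)) keep <- keep[seq_len(min(n_components, length(keep)))]
  V <- sv$v[, keep, drop = FALSE]
  varfrac <- sv$d[keep]^2 / sum(sv$d^2)
  # orientation convention: positive mean loading over the head region
  head_rows <- seq_len(max(1L, floor(0.20 * grid[1L])))
  head_idx <- as.vector(outer(head_rows, (seq_len(grid[2L]) - 1L) * grid[1L], "+"))
  for (j in seq_len(ncol(V))) {
    if (mean(V[head_idx, j]) < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  sdv <- apply(scores, 2L, stats::sd)
  structure(list(mean = mu, components = V, score_sd = sdv,
                 variance_fraction = varfrac, grid = grid,
                 head_rows = head_rows),
            class = "expression_pca")
}

#' Score images along expression principal components
#'
#' Score = projection onto the component divided by the training-score SD,
#' i.e. standard deviations from the training mean along that component.
#'
#' @param model an [fit_expression_pca()] result.
#' @param images list of [straightened_image()]s; names (or
#'   `animal_ids`/`ages`) label the output rows.
#' @param component component index (default 1).
#' @param animal_ids,ages optional per-image labels; with a `window`
#'   given, rows outside `[window[1], window[2]]` days are dropped.
#' @param window optional closed age window in days.
#' @return data.frame `(animal_id, age_days, component, score)`.
#' @export
score_images <- function(model, images, component = 1L, animal_ids = NULL,
                         ages = NULL, window = NULL) {
  stopifnot(inherits(model, "expression_pca"))
  grid_ok <- vapply(images, function(x) all(dim(x$data) == model$grid),
                    logical(1))
  if (!all(grid_ok)) stop("image grid does not match the model grid")
  v <- model$components[, component]
  sdv <- model$score_sd[component]
  sc <- vapply(images, function(img) {
    x <- flatten_expression_image(img)
    sum((x - model$mean) * v) / sdv
  }, numeric(1))
  out <- data.frame(
    animal_id = animal_ids %||% names(images) %||% seq_along(images),
    age_days = ages %||% vapply(images, function(x) x$age_days, numeric(1)),
    component = component, score = sc, stringsAsFactors = FALSE)
  if (!is.null(window))
    out <- out[!is.na(out$age_days) & out$age_days >= window[1L] &
                 out$age_days <= window[2L], ]
  out
}
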