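# Shared low-level helpers: polyline resampling, bilinear sampling, small
# numerics.  All coordinates in this package are 1-based (row, col).

#' Arc length of a polyline
#'
#' @param pts numeric matrix with columns (row, col), one vertex per row.
#' @return total Euclidean length in pixels.
#' @keywords internal
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Resample a polyline to uniform arc spacing
#'
#' Linear interpolation along the cumulative chord length.  The first and
#' last vertices are always retained.
#'
#' @param pts matrix (row, col).
#' @param spacing target spacing in pixels (default 1).
#' @return matrix (row, col) with approximately uniform spacing.
#' @keywords internal
resample_polyline <- function(pts, spacing = 1) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(pts[1L, , drop = FALSE])
  n_out <- max(2L, round(total / spacing) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  cbind(stats::approx(s, pts[, 1L], xout = s_out)$y,
        stats::approx(s, pts[, 2L], xout = s_out)$y)
}

#' Bilinear interpolation into an image matrix
#'
#' Out-of-bounds queries return `NA`.
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors of (fractional) row/col positions, 1-based.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1L, c0)]
  i01 <- img[cbind(r0, c0 + 1L)]
  i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
  out
}

#' Running min/max filter over a square window
#'
#' Separable shift-and-compare implementation; border handled by edge
#' replication.
#' @keywords internal
window_extremum <- function(img, radius, op = c("min", "max")) {
  op <- match.arg(op)
  f <- if (op == "min") pmin else pmax
  shift_rows <- function(m, k) {
    nr <- nrow(m)
    idx <- pmin(pmax(seq_len(nr) + k, 1L), nr)
    m[idx, , drop = FALSE]
  }
  shift_cols <- function(m, k) {
    nc <- ncol(m)
    idx <- pmin(pmax(seq_len(nc) + k, 1L), nc)
    m[, idx, drop = FALSE]
  }
  out <- img
  for (k in seq_len(radius)) out <- f(out, shift_rows(img, k), shift_rows(img, -k))
  res <- out
  for (k in seq_len(radius)) res <- f(res, shift_cols(out, k), shift_cols(out, -k))
  res
}

#' Box-filter mean over a square window (edge-replicated)
#' @keywords internal
window_mean <- function(img, radius) {
  cums <- function(m) {
    nr <- nrow(m)
    idx <- pmin(pmax(rep(seq_len(nr), each = 1L), 1L), nr)
    m
  }
  # separable running mean via shifts (window is small, radius <= 8)
  shift_rows <- function(m, k) {
    nr <- nrow(m)
    idx <- pmin(pmax(seq_len(nr) + k, 1L), nr)
    m[idx, , drop = FALSE]
  }
  shift_cols <- function(m, k) {
    nc <- ncol(m)
    idx <- pmin(pmax(seq_len(nc) + k, 1L), nc)
    m[, idx, drop = FALSE]
  }
  acc <- img
  for (k in seq_len(radius)) acc <- acc + shift_rows(img, k) + shift_rows(img, -k)
  acc <- acc / (2 * radius + 1)
  res <- acc
  for (k in seq_len(radius)) res <- res + shift_cols(acc, k) + shift_cols(acc, -k)
  res / (2 * radius + 1)
}

#' Coefficient of determination from observed and predicted values
#' @keywords internal
r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
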