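# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.  Kept deliberately naive.

# O(V^2) Dijkstra over an 8-connected mask with per-target-node costs;
# returns the minimal total cost from one (row, col) to another.
brute_dijkstra_cost <- function(mask, cost, from, to) {
  nr <- nrow(mask)
  idx <- which(mask)
  dist <- rep(Inf, length(idx))
  pos <- match((from[2] - 1) * nr + from[1], idx)
  tgt <- match((to[2] - 1) * nr + to[1], idx)
  dist[pos] <- 0
  done <- rep(FALSE, length(idx))
  rc <- cbind((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (done[u] || is.infinite(dist[u])) break
    done[u] <- TRUE
    if (u == tgt) break
    dr <- abs(rc[, 1] - rc[u, 1]); dc <- abs(rc[, 2] - rc[u, 2])
    nb <- which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
    for (v in nb) {
      alt <- dist[u] + cost[idx[v]]
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  dist[tgt]
}

# leave-one-out R2 by n explicit refits
loo_r2_refit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  preds <- vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(cbind(1, scale(X[-i, , drop = FALSE])), y[-i])
    z <- (X[i, ] - colMeans(X[-i, , drop = FALSE])) /
      apply(X[-i, , drop = FALSE], 2, stats::sd)
    sum(fit$coefficients * c(1, z))
  }, numeric(1))
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

# F statistic from the ANOVA sums-of-squares decomposition
f_anova <- function(X, y) {
  X <- as.matrix(X)
  fit <- stats::lm.fit(cbind(1, X), y)
  yhat <- y - fit$residuals
  p <- ncol(X); n <- length(y)
  ss_model <- sum((yhat - mean(y))^2)
  ss_error <- sum(fit$residuals^2)
  (ss_model / p) / (ss_error / (n - p - 1))
}

# GCV via the explicit dense ridge hat matrix (standardized predictors,
# centered response, unpenalized intercept contributing 1 to the trace)
gcv_hat_matrix <- function(X, y, lambda) {
  Z <- scale(as.matrix(X))
  yc <- y - mean(y)
  n <- nrow(Z); p <- ncol(Z)
  H <- Z %*% solve(crossprod(Z) + lambda * diag(p), t(Z))
  rss <- sum((yc - H %*% yc)^2)
  edf <- sum(diag(H)) + 1
  n * rss / (n - edf)^2
}

# regression-based conditional-independence p-value (lm route, independent
# of the package's correlation-matrix route)
ci_p_lm <- function(data, x, y, S) {
  df <- as.data.frame(data)
  rhs <- c(colnames(df)[x], colnames(df)[S])
  f <- stats::as.formula(paste(colnames(df)[y], "~",
                               paste(rhs, collapse = "+")))
  fit <- stats::lm(f, data = df)
  stats::coef(summary(fit))[colnames(df)[x], "Pr(>|t|)"]
}

# exhaustive skeleton: edge iff X and Y are dependent given EVERY subset of
# the remaining variables
exhaustive_skeleton <- function(data, alpha) {
  p <- ncol(data)
  adj <- matrix(FALSE, p, p)
  for (x in 1:(p - 1)) for (y in (x + 1):p) {
    others <- setdiff(1:p, c(x, y))
    subsets <- unlist(lapply(0:length(others), function(k) {
      if (k == 0) list(integer(0))
      else if (length(others) == 1 && k == 1) list(others)
      else utils::combn(others, k, simplify = FALSE)
    }), recursive = FALSE)
    dependent <- all(vapply(subsets, function(S)
      ci_p_lm(data, x, y, S) <= alpha, logical(1)))
    adj[x, y] <- adj[y, x] <- dependent
  }
  dimnames(adj) <- list(colnames(data), colnames(data))
  adj
}

# nearest-texton by exhaustive per-centroid scan
nearest_texton_scan <- function(P, centroids) {
  apply(P, 1, function(p)
    which.min(apply(centroids, 1, function(cen) sum((p - cen)^2))))
}
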