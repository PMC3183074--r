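# Partial-correlation (graphical Gaussian) networks over biomarker
# summaries and lifespan: the PC algorithm's skeleton-search phase with the
# multiple-regression conditional-independence test at alpha = 0.001, and a
# cross-dataset consensus.  Edge orientation is deliberately not inferred.

# p-value of the test X independent of Y given S, via the t-test on X's
# coefficient in the regression of Y on {X} union S; computed from the
# partial correlation (algebraically identical, and symmetric in X and Y)
ci_test_p <- function(C, n, x, y, S) {
  idx <- c(x, y, S)
  sub <- C[idx, idx, drop = FALSE]
  P <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(P)) return(1)
  pc <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  pc <- max(min(pc, 1 - 1e-12), -1 + 1e-12)
  df <- n - length(S) - 2L
  if (df <= 0L) return(1)
  tstat <- pc * sqrt(df / (1 - pc^2))
  2 * stats::pt(-abs(tstat), df)
}

#' PC-algorithm skeleton search
#'
#' Starts from the complete undirected graph.  For conditioning-set sizes
#' `k = 0, 1, 2, ...`, each remaining edge (X, Y) is tested for
#' `X _||_ Y | S` over subsets `S` of the adjacent nodes of the pair with
#' `|S| = k`, using the t-test on X's coefficient in the regression of Y on
#' `{X} union S` (the partial-correlation t-test); the edge is removed as
#' soon as any test's p-value exceeds `alpha`.  Nodes and subsets are
#' processed in deterministic lexicographic order.
#'
#' @param data numeric matrix or data.frame, animals x variables
#'   (complete-case rows are used; at least `ncol + 3` required).
#' @param alpha independence-test threshold (default 0.001).
#' @param stable if `TRUE`, neighborhoods are frozen at the start of each
#'   `k` stage and all removals applied together (order-independent
#'   variant).
#' @param max_k largest conditioning-set size considered.
#' @return object of class `pc_network`: list with `nodes`, `edges`
#'   (two-column character matrix, lexicographic), `alpha`, `sepset`
#'   (named list of separating sets), `adjacency` (logical matrix).
#' @export
pc_skeleton <- function(data, alpha = 0.001, stable = FALSE,
                        max_k = Inf) {
  X <- as.matrix(data)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  vars <- colnames(X) %||% paste0("v", seq_len(ncol(X)))
  colnames(X) <- vars
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3L) stop("need at least ncol + 3 complete-case rows")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(vars[sds == 0], collapse = ", "))
  C <- stats::cor(X)
  adj <- matrix(TRUE, p, p, dimnames = list(vars, vars))
  diag(adj) <- FALSE
  sepset <- list()
  k <- 0L
  repeat {
    adj_stage <- adj
    # any edge with a big enough candidate pool?
    pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    if (!nrow(pairs)) break
    pool_sizes <- apply(pairs, 1L, function(e) {
      sum(adj_stage[e[1L], ] | adj_stage[e[2L], ]) - 2L
    })
    if (all(pool_sizes < k) || k > max_k) break
    removals <- list()
    ord <- order(pairs[, 1L], pairs[, 2L])
    for (r in ord) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (!adj[i, j]) next
      nb <- if (stable) adj_stage else adj
      cand <- sort(setdiff(which(nb[i, ] | nb[j, ]), c(i, j)))
      if (length(cand) < k) next
      subsets <- if (k == 0L) list(integer(0))
        else if (length(cand) == 1L) list(cand)  # combn(x, k) would expand 1:x
        else utils::combn(cand, k, simplify = FALSE)
      for (S in subsets) {
        if (ci_test_p(C, n, i, j, S) > alpha) {
          key <- paste(vars[i], vars[j], sep = "|")
          sepset[[key]] <- vars[S]
          if (stable) {
            removals[[length(removals) + 1L]] <- c(i, j)
          } else {
            adj[i, j] <- adj[j, i] <- FALSE
          }
          break
        }
      }
    }
    if (stable) for (e in removals) adj[e[1L], e[2L]] <- adj[e[2L], e[1L]] <- FALSE
    k <- k + 1L
  }
  ei <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- cbind(vars[ei[, 1L]], vars[ei[, 2L]])
  structure(list(nodes = vars, edges = edges, alpha = alpha,
                 sepset = sepset, adjacency = adj),
            class = "pc_network")
}

#' @export
print.pc_network <- function(x, ...) {
  cat(sprintf("PC skeleton: %d nodes, %d edges (alpha = %g)\n",
              length(x$nodes), nrow(x$edges), x$alpha))
  if (nrow(x$edges))
    cat(paste(sprintf("  %s -- %s", x$edges[, 1L], x$edges[, 2L]),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Consensus of partial-correlation networks across datasets
#'
#' An edge is solid iff it is present in every network containing both its
#' endpoints, dashed iff present in at least one but not all; a node is
#' unplaceable iff it appears in some network but carries no solid or
#' dashed edge anywhere.
#'
#' @param networks list of [pc_skeleton()] results (node sets may differ;
#'   datasets lacking a node do not veto its edges).
#' @return object of class `consensus_network`: list with `nodes`,
#'   `solid`, `dashed` (two-column matrices), `unplaceable` (character).
#' @export
consensus_network <- function(networks) {
  if (!length(networks)) stop("empty network list")
  all_nodes <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  seen <- list()
  for (nw in networks) {
    if (nrow(nw$edges))
      for (r in seq_len(nrow(nw$edges))) {
        k <- edge_key(nw$edges[r, 1L], nw$edges[r, 2L])
        seen[[k]] <- c(seen[[k]], TRUE)
      }
  }
  solid <- dashed <- matrix(character(0), 0, 2)
  pairs <- utils::combn(all_nodes, 2L)
  for (q in seq_len(ncol(pairs))) {
    a <- pairs[1L, q]; b <- pairs[2L, q]
    applicable <- Filter(function(nw) all(c(a, b) %in% nw$nodes), networks)
    if (!length(applicable)) next
    present <- vapply(applicable, function(nw) {
      any(apply(nw$edges, 1L, function(e) all(sort(e) == sort(c(a, b)))))
    }, logical(1))
    if (all(present) && length(present))
      solid <- rbind(solid, c(a, b))
    else if (any(present))
      dashed <- rbind(dashed, c(a, b))
  }
  has_edge <- unique(c(solid, dashed))
  structure(list(nodes = all_nodes, solid = solid, dashed = dashed,
                 unplaceable = setdiff(all_nodes, has_edge)),
            class = "consensus_network")
}

#' Write a network as an edge-list CSV
#'
#' Columns `(node_a, node_b, status)` with status `solid`/`dashed` for a
#' consensus network, or `solid` for a single skeleton.
#'
#' @param network a `pc_network` or `consensus_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_network_csv <- function(network, path) {
  if (inherits(network, "consensus_network")) {
    df <- rbind(
      if (nrow(network$solid))
        data.frame(node_a = network$solid[, 1L], node_b = network$solid[, 2L],
                   status = "solid"),
      if (nrow(network$dashed))
        data.frame(node_a = network$dashed[, 1L], node_b = network$dashed[, 2L],
                   status = "dashed"))
  } else {
    df <- if (nrow(network$edges))
      data.frame(node_a = network$edges[, 1L], node_b = network$edges[, 2L],
                 status = "solid")
  }
  if (is.null(df)) df <- data.frame(node_a = character(0),
                                    node_b = character(0),
                                    status = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
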