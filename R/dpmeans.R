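#' DP-means clustering
#'
#' Clusters points with the Dirichlet-process-means algorithm: points are
#' assigned to their nearest centre unless that centre lies farther than
#' the Euclidean distance threshold \code{lambda}, in which case the point
#' spawns a new cluster; after each pass centres are recomputed as cluster
#' means, and iteration stops when assignments no longer change. The
#' implied objective is the within-cluster sum of squared distances plus a
#' penalty of \code{lambda^2} per cluster. Unlike its first-stage
#' counterpart, DP-means keeps far-away single points as their own
#' clusters, which is what prunes inter-image redundancy in the texton
#' dictionary without discarding rare textures.
#'
#' The point-visit order affects the local optimum reached (a known
#' property of the algorithm); \code{restarts > 1} reruns the sweep from
#' seeded random orders and keeps the solution with the lowest objective.
#'
#' @param points numeric matrix, one point per row (N >= 1).
#' @param lambda positive distance threshold for opening a new cluster
#'   (the texton protocol uses 0.5).
#' @param maxIter maximum number of full passes (default 100).
#' @param restarts number of point orderings to try (default 1: input
#'   order, fully deterministic).
#' @param seed RNG seed for the random orderings when \code{restarts > 1}.
#' @return list with \code{centers} (k x D matrix), \code{assignments}
#'   (integer N-vector into rows of \code{centers}), \code{k}, and
#'   \code{objective}.
#' @examples
#' pts <- rbind(matrix(0.01 * 1:4, 2), matrix(5 + 0.01 * 1:4, 2))
#' dpMeans(pts, lambda = 1)$k
#' @seealso [buildDictionary()], [dpMeansObjective()]
#' @export
dpMeans <- function(points, lambda, maxIter = 100L, restarts = 1L,
                    seed = 1L) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (nrow(points) < 1L) stop("points must contain at least one row")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single positive number")
  N <- nrow(points)
  orders <- list(seq_len(N))
  if (restarts > 1L) {
    extra <- withr::with_seed(seed,
      replicate(restarts - 1L, sample.int(N), simplify = FALSE))
    orders <- c(orders, extra)
  }
  best <- NULL
  for (ord in orders) {
    fit <- dpMeansOnce(points, lambda, maxIter, ord)
    if (is.null(best) || fit$objective < best$objective - 1e-12)
      best <- fit
  }
  best
}

dpMeansOnce <- function(X, lambda, maxIter, ord) {
  N <- nrow(X)
  centers <- matrix(colMeans(X), 1L)
  assign <- integer(N)
  lam2 <- lambda^2
  for (iter in seq_len(maxIter)) {
    prev <- assign
    for (i in ord) {
      d2 <- colSums((t(centers) - X[i, ])^2)
      j <- which.min(d2)
      if (d2[j] > lam2) {
        centers <- rbind(centers, X[i, ])
        assign[i] <- nrow(centers)
      } else {
        assign[i] <- j
      }
    }
    # recompute means; drop clusters that lost all points
    keep <- sort(unique(assign))
    centers <- do.call(rbind, lapply(keep, function(k)
      colMeans(X[assign == k, , drop = FALSE])))
    assign <- match(assign, keep)
    if (identical(assign, prev)) break
  }
  obj <- sum((X - centers[assign, , drop = FALSE])^2) +
    lam2 * nrow(centers)
  list(centers = centers, assignments = assign, k = nrow(centers),
       objective = obj)
}

#' DP-means objective of a given partition
#'
#' Sum of squared Euclidean distances of points to their cluster means
#' plus \code{lambda^2} per cluster.
#'
#' @param points numeric matrix, one point per row.
#' @param assignments integer cluster labels, one per row.
#' @param lambda the DP-means distance threshold.
#' @return numeric(1), the objective value.
#' @export
dpMeansObjective <- function(points, assignments, lambda) {
  if (!is.matrix(points)) points <- as.matrix(points)
  ids <- sort(unique(assignments))
  centers <- do.call(rbind, lapply(ids, function(k)
    colMeans(points[assignments == k, , drop = FALSE])))
  sum((points - centers[match(assignments, ids), , drop = FALSE])^2) +
    lambda^2 * length(ids)
}
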