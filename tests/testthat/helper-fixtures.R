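## Shared fixtures, built once per test run. Everything is generated in
## code from fixed seeds; nothing is read from disk except the shipped
## reference dictionary.

sharedBank <- makeFilterBank()

sharedBackground <- local({
  ep <- generateEmptyPlate(nPerSubwell = 3L, seed = 5L)
  buildBackground(ep$images, ep$subwells)
})

## small dictionary for fast descriptor tests (10 + 6 images)
sharedSmallDict <- buildReferenceDictionary(seed = 3L, nPrecipitate = 10L,
                                            nCrystal = 6L, targetSize = 60L)

maskIoU <- function(a, b) sum(a & b) / sum(a | b)

## exhaustive circular-shortest-path oracle: enumerate every feasible
## closed path (independent of the DP implementation)
bruteForceCSP <- function(cost, step = 1L) {
  R <- nrow(cost); C <- ncol(cost)
  paths <- matrix(seq_len(R), ncol = 1L)
  for (j in 2:C) {
    pieces <- list()
    for (i in seq_len(nrow(paths))) {
      last <- paths[i, j - 1L]
      for (r in max(1L, last - step):min(R, last + step))
        pieces[[length(pieces) + 1L]] <- c(paths[i, ], r)
    }
    paths <- do.call(rbind, pieces)
  }
  paths <- paths[abs(paths[, 1L] - paths[, C]) <= step, , drop = FALSE]
  costs <- rowSums(matrix(cost[cbind(as.vector(paths),
                                     rep(seq_len(C), each = nrow(paths)))],
                          nrow(paths)))
  min(costs)
}

## all set partitions of 1..n (restricted growth), for the DP-means oracle
allPartitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in allPartitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

bruteForceDPMeansObjective <- function(X, lambda) {
  best <- Inf
  for (p in allPartitions(nrow(X))) {
    a <- integer(nrow(X))
    for (k in seq_along(p)) a[p[[k]]] <- k
    o <- dpMeansObjective(X, a, lambda)
    if (o < best) best <- o
  }
  best
}

## compact well-separated cluster sample in 8-d: the regime DP-means is
## designed for (within-spread << lambda << separation)
sampleClusteredPoints <- function(N, lambda, maxClusters = 3L) {
  k <- sample(seq_len(maxClusters), 1L)
  ctrs <- matrix(stats::rnorm(k * 8), k) * 3 * lambda
  ctrs[sample(k, N, replace = TRUE), , drop = FALSE] +
    matrix(stats::rnorm(N * 8, 0, lambda / (4 * sqrt(8))), N)
}
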