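## Variational Bayes Gaussian mixture with diagonal covariances.
## The number of effective components is selected by the data: the model
## starts from a generous cap and the sparse Dirichlet prior drives
## redundant components to negligible weight, which are then pruned.

vbgmmFit <- function(X, maxComponents = 30L, maxIter = 300L,
                     tol = 1e-5, pruneWeight = 1e-3, seed = 1L) {
  N <- nrow(X); D <- ncol(X)
  K <- min(maxComponents, N)
  # priors: sparse Dirichlet over weights, Gaussian-Gamma over mean/precision
  alpha0 <- 1 / K
  beta0 <- 1
  a0 <- 1
  m0 <- colMeans(X)
  v <- apply(X, 2L, stats::var)
  v[v < 1e-12] <- 1e-12
  b0 <- v                      # prior mean precision = 1/var per dimension
  km <- withr::with_seed(seed,
    suppressWarnings(stats::kmeans(X, centers = K, nstart = 3L,
                                   iter.max = 30L)))
  r <- matrix(1e-10, N, K)
  r[cbind(seq_len(N), km$cluster)] <- 1
  r <- r / rowSums(r)

  m <- matrix(0, K, D); a <- matrix(0, K, D); b <- matrix(0, K, D)
  alpha <- numeric(K); beta <- numeric(K)
  Nk <- colSums(r)
  for (iter in seq_len(maxIter)) {
    # M-step (variational posterior updates)
    Nk <- colSums(r) + 1e-12
    xbar <- t(r) %*% X / Nk                       # K x D
    S <- t(r) %*% (X^2) / Nk - xbar^2             # K x D, within variance
    S[S < 0] <- 0
    alpha <- alpha0 + Nk
    beta <- beta0 + Nk
    m <- (beta0 * matrix(m0, K, D, byrow = TRUE) + Nk * xbar) / beta
    a <- matrix(a0 + Nk / 2, K, D)
    b <- matrix(b0, K, D, byrow = TRUE) +
      0.5 * (Nk * S +
             (beta0 * Nk / beta) * (xbar - matrix(m0, K, D, byrow = TRUE))^2)
    # E-step: responsibilities
    ElnPi <- digamma(alpha) - digamma(sum(alpha))
    ElnTau <- digamma(a) - log(b)                 # K x D
    Etau <- a / b
    # E[tau_kd * (x_nd - mu_kd)^2] = Etau*(x - m)^2 + 1/beta_k
    quad <- X^2 %*% t(Etau) - 2 * X %*% t(Etau * m) +
      matrix(rowSums(Etau * m^2), N, K, byrow = TRUE)
    lnRho <- matrix(ElnPi + 0.5 * rowSums(ElnTau) -
                      0.5 * D * log(2 * pi) -
                      0.5 * D / beta, N, K, byrow = TRUE) - 0.5 * quad
    lnRho <- lnRho - apply(lnRho, 1L, max)
    rNew <- exp(lnRho)
    rNew <- rNew / rowSums(rNew)
    delta <- max(abs(rNew - r))
    r <- rNew
    if (delta < tol) break
  }
  w <- colSums(r) / N
  keep <- which(w > pruneWeight)
  if (length(keep) == 0L) keep <- which.max(w)
  rk <- r[, keep, drop = FALSE]
  list(means = m[keep, , drop = FALSE], weights = w[keep],
       assignments = max.col(rk, ties.method = "first"),
       iterations = iter)
}

#' Cluster per-pixel filter responses with a variational Bayes mixture
#'
#' Fits a diagonal-covariance Gaussian mixture by variational Bayes to a
#' set of 8-dimensional filter-response vectors. The number of mixture
#' components is determined by the data: the fit starts from a generous
#' component cap and a sparse Dirichlet prior; components whose posterior
#' weight falls below \code{pruneWeight} are discarded. No per-image
#' parameter selection is required, which is what makes this suitable as
#' the first clustering stage of texton-dictionary construction (typical
#' droplet images yield on the order of 8-15 components).
#'
#' @param responses numeric matrix, one response vector per row (at least
#'   two distinct rows).
#' @param maxComponents upper bound on mixture size (default 30).
#' @param pruneWeight minimum posterior weight for a component to survive
#'   (default 1e-3).
#' @param seed RNG seed for the k-means initialisation (mandatory for
#'   reproducible dictionaries).
#' @return list with \code{centers} (component means, one per row),
#'   \code{weights}, and \code{assignments} (per-row hard component
#'   labels, indexing rows of \code{centers}).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(400, 0, 0.1), ncol = 8),
#'            matrix(rnorm(400, 3, 0.1), ncol = 8))
#' fit <- clusterImageTextons(X)
#' nrow(fit$centers)
#' @seealso [buildDictionary()], [dpMeans()]
#' @export
clusterImageTextons <- function(responses, maxComponents = 30L,
                                pruneWeight = 1e-3, seed = 1L) {
  if (!is.matrix(responses)) responses <- as.matrix(responses)
  if (nrow(unique(responses)) < 2L)
    stop("need at least two distinct response vectors to cluster")
  fit <- vbgmmFit(responses, maxComponents = maxComponents,
                  pruneWeight = pruneWeight, seed = seed)
  list(centers = fit$means, weights = fit$weights,
       assignments = fit$assignments)
}
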