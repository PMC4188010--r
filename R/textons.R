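#' Label pixels with their nearest texton
#'
#' Assigns every in-mask pixel the index of the dictionary entry closest
#' to its 8-component filter-response vector (Euclidean distance, ties to
#' the lowest index). Pixels outside the mask, and pixels within the
#' filter border recorded by [applyFilterBank()], are left unlabelled
#' (\code{NA}).
#'
#' @param responses H x W x 8 response array from [applyFilterBank()].
#' @param dict a [TextonDictionary-class] object.
#' @param mask optional logical H x W matrix; \code{NULL} labels every
#'   non-border pixel.
#' @return integer H x W matrix of dictionary indices (1..K), \code{NA}
#'   for excluded pixels.
#' @examples
#' d <- new("TextonDictionary",
#'          centers = rbind(rep(0, 8), rep(1, 8)),
#'          source = c("precipitate", "crystal"), lambda = 0.5)
#' resp <- array(0, c(4, 4, 8))
#' labelPixels(resp, d)[2, 2]
#' @seealso [textonHistogram()]
#' @export
labelPixels <- function(responses, dict, mask = NULL) {
  stopifnot(is(dict, "TextonDictionary"))
  dims <- dim(responses)
  if (length(dims) != 3L || dims[3L] != 8L)
    stop("responses must be an H x W x 8 array")
  H <- dims[1L]; W <- dims[2L]
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  border <- attr(responses, "border")
  if (!is.null(border) && border > 0L) {
    bm <- matrix(FALSE, H, W)
    keepR <- (border + 1L):(H - border)
    keepC <- (border + 1L):(W - border)
    if (length(keepR) && length(keepC)) bm[keepR, keepC] <- TRUE
    mask <- mask & bm
  }
  labels <- matrix(NA_integer_, H, W)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  X <- matrix(responses, H * W, 8L)[idx, , drop = FALSE]
  C <- dict@centers
  # squared distances N x K via the expansion trick; ties -> lowest index
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C)
  d2 <- sweep(d2, 2L, rowSums(C^2), "+")
  labels[idx] <- max.col(-d2, ties.method = "first")
  labels
}

#' Texton frequency histogram
#'
#' Counts the occurrences of each texton label over the labelled pixels of
#' a texton map. The resulting frequency histogram (length = dictionary
#' size) is the final numerical descriptor of a droplet image; its sum
#' equals the number of in-mask labelled pixels.
#'
#' @param map integer label matrix from [labelPixels()] (\code{NA} =
#'   excluded).
#' @param dictSize the dictionary size K.
#' @return integer vector of length \code{dictSize}; attribute
#'   \code{nPixels} holds the labelled pixel count (equal to the sum).
#' @seealso [labelPixels()], [chi2Distance()]
#' @export
textonHistogram <- function(map, dictSize) {
  lab <- map[!is.na(map)]
  if (length(lab) && (min(lab) < 1L || max(lab) > dictSize))
    stop("labels outside 1..dictSize")
  counts <- tabulate(lab, nbins = dictSize)
  attr(counts, "nPixels") <- length(lab)
  counts
}

#' Chi-squared distance between texton histograms
#'
#' Both histograms are normalised to unit sum, then
#' \eqn{d(x, y) = \frac{1}{2} \sum_i (x_i - y_i)^2 / (x_i + y_i)}, with
#' empty bins (zero in both) contributing nothing; each squared bin
#' difference is weighted inversely by the summed bin mass. The distance
#' is symmetric, non-negative and zero exactly for identical normalised
#' histograms.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return numeric(1) in \[0, 1\].
#' @examples
#' chi2Distance(c(1, 0), c(0, 1))  # 1
#' @export
chi2Distance <- function(x, y) {
  if (length(x) != length(y))
    stop("histograms must have equal length")
  if (sum(x) > 0) x <- x / sum(x)
  if (sum(y) > 0) y <- y / sum(y)
  s <- x + y
  nz <- s > 0
  0.5 * sum((x[nz] - y[nz])^2 / s[nz])
}

#' Ward clustering of droplet histograms
#'
#' Agglomerative hierarchical clustering (Ward's minimum-variance
#' criterion) of texton histograms under the chi-squared distance of
#' [chi2Distance()], used to validate that the descriptors group droplets
#' with similar precipitation patterns.
#'
#' @param histograms numeric matrix with one histogram per row, or a list
#'   of equal-length histograms.
#' @param nClusters number of clusters to cut the tree into (at most the
#'   number of histograms).
#' @return integer vector of cluster labels; the \code{hclust} tree is
#'   attached as attribute \code{tree}.
#' @export
wardCluster <- function(histograms, nClusters) {
  if (is.list(histograms)) histograms <- do.call(rbind, histograms)
  n <- nrow(histograms)
  if (nClusters > n)
    stop("nClusters must not exceed the number of histograms")
  P <- histograms / pmax(rowSums(histograms), 1e-300)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- P[i, ]
    rest <- (i + 1L):n
    s <- sweep(P[rest, , drop = FALSE], 2L, xi, "+")
    dif <- sweep(P[rest, , drop = FALSE], 2L, xi, "-")
    ratio <- ifelse(s > 0, dif^2 / s, 0)
    d[i, rest] <- d[rest, i] <- 0.5 * rowSums(ratio)
  }
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  labels <- stats::cutree(tree, k = nClusters)
  attr(labels, "tree") <- tree
  labels
}
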