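#' Gradient and shape features for fault detection
#'
#' Masks the well frame using the registered background, z-scores the
#' remaining well interior, and summarises its gradient-magnitude image by
#' the mean, standard deviation, skewness and kurtosis plus the
#' distribution of absolute gradients over 50 fixed unit-width bins
#' centred at 0..49 (values beyond the last bin are clipped into it) — 54
#' gradient statistics in total. Appended are the area, well-relative
#' centroid, eccentricity (distance between ellipse foci over the major
#' axis) and major/minor axis lengths of the segmented droplet (all zero
#' when the droplet could not be segmented), for a 60-entry feature
#' vector.
#'
#' @param image numeric grey matrix (0-255).
#' @param reg a [WellRegistration-class] for this image.
#' @param bg a [BackgroundModel-class].
#' @param subwell subwell position name (default: first in \code{bg}).
#' @param boundary a [DropletBoundary-class], or \code{NULL} for an
#'   unsegmentable droplet.
#' @return named numeric vector of length 60.
#' @seealso [trainFaultClassifier()], [predictFault()]
#' @export
faultFeatures <- function(image, reg, bg, subwell = NULL,
                          boundary = NULL) {
  FM <- if (is.null(subwell)) bg@frameMasks[[1L]] else
    bg@frameMasks[[subwell]]
  n <- nrow(image); m <- ncol(image)
  FMs <- matrix(TRUE, n, m)
  ri <- max(1L, 1L + reg@dy):min(n, n + reg@dy)
  ci <- max(1L, 1L + reg@dx):min(m, m + reg@dx)
  FMs[ri, ci] <- FM[ri - reg@dy, ci - reg@dx]
  interior <- !FMs

  z <- image * 0
  v <- image[interior]
  sdv <- stats::sd(v)
  if (is.finite(sdv) && sdv > 0) z[interior] <- (v - mean(v)) / sdv
  g <- gradientMagnitude(z)
  gv <- g[interior]

  mu <- mean(gv); sg <- stats::sd(gv)
  if (!is.finite(sg) || sg == 0) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((gv - mu)^3) / sg^3
    kurt <- mean((gv - mu)^4) / sg^4
  }
  bins <- tabulate(pmin(floor(abs(gv)), 49) + 1L, nbins = 50L)
  bins <- bins / max(sum(bins), 1L)

  if (is.null(boundary)) {
    shape <- c(area = 0, centroid_r = 0, centroid_c = 0,
               eccentricity = 0, major_axis = 0, minor_axis = 0)
  } else {
    p <- boundary@properties
    wellCtr <- c((n + 1) / 2 + reg@dy, (m + 1) / 2 + reg@dx)
    shape <- c(area = p$area,
               centroid_r = p$centroid[1L] - wellCtr[1L],
               centroid_c = p$centroid[2L] - wellCtr[2L],
               eccentricity = p$eccentricity,
               major_axis = p$majorAxis, minor_axis = p$minorAxis)
  }
  out <- c(grad_mean = mu, grad_sd = sg, grad_skew = skew,
           grad_kurtosis = kurt,
           stats::setNames(bins, paste0("grad_bin", 0:49)), shape)
  out
}

#' Train the fault random forest
#'
#' Fits a seeded two-class random forest (good vs faulty) on fault
#' feature vectors and reports out-of-bag accuracy.
#'
#' @param features numeric matrix, one [faultFeatures()] vector per row.
#' @param labels factor or character vector with levels \code{"good"} and
#'   \code{"faulty"}.
#' @param nTrees number of trees (default 500).
#' @param seed RNG seed (training is deterministic given the seed).
#' @return a [FaultClassifier-class] object.
#' @export
trainFaultClassifier <- function(features, labels, nTrees = 500L,
                                 seed = 1L) {
  labels <- factor(labels, levels = c("good", "faulty"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present in the training labels")
  rf <- withr::with_seed(seed,
    randomForest::randomForest(x = as.data.frame(features), y = labels,
                               ntree = nTrees))
  oob <- 1 - rf$err.rate[nTrees, "OOB"]
  new("FaultClassifier", forest = rf, oobAccuracy = unname(oob),
      seed = as.integer(seed))
}

#' Classify droplets as good or faulty
#'
#' Faulty droplets (empty wells, undersized drops, off-frame wells) are
#' excluded from the texton pipeline and listed in the run report.
#'
#' @param model a [FaultClassifier-class] object.
#' @param features numeric matrix (or single vector) of fault features.
#' @return data.frame with columns \code{verdict} (\code{"good"} or
#'   \code{"faulty"}) and \code{pFaulty} (posterior probability of the
#'   faulty class).
#' @export
predictFault <- function(model, features) {
  stopifnot(is(model, "FaultClassifier"))
  if (is.null(dim(features))) features <- matrix(features, 1L,
    dimnames = list(NULL, names(features)))
  df <- as.data.frame(features)
  prob <- stats::predict(model@forest, df, type = "prob")[, "faulty"]
  data.frame(verdict = ifelse(prob >= 0.5, "faulty", "good"),
             pFaulty = as.numeric(prob))
}
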