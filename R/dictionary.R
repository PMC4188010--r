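## Texton dictionary construction: per-image VB-GMM centres, concatenated
## and de-duplicated by DP-means, run separately for the precipitation and
## crystal training sets so that crystal-related textures stay represented.

## Per-image stage-1 clustering: normalise, downscale, filter, subsample
## pixel responses, VB-GMM. Returns centres and, when a region mask is
## supplied, the fraction of each centre's supporting pixels inside it.
imageStage1Centers <- function(image, bank, scale, maxPixels, seed,
                               dropletMask = NULL, regionMask = NULL) {
  img <- toGreyFullRange(image)
  mu <- mean(img); sd <- stats::sd(img)
  img <- if (sd > 0) (img - mu) / sd else img * 0
  newDim <- pmax(round(dim(img) * scale), 1L)
  small <- EBImage::resize(img, w = newDim[1L], h = newDim[2L])
  resp <- applyFilterBank(small, bank)
  border <- attr(resp, "border")
  H <- nrow(small); W <- ncol(small)
  keep <- matrix(FALSE, H, W)
  if (H > 2 * border && W > 2 * border)
    keep[(border + 1L):(H - border), (border + 1L):(W - border)] <- TRUE
  if (!is.null(dropletMask)) {
    dm <- EBImage::resize(dropletMask * 1, w = newDim[1L],
                          h = newDim[2L]) >= 0.5
    keep <- keep & dm
  }
  idx <- which(keep)
  if (length(idx) < 16L) return(NULL)
  if (length(idx) > maxPixels)
    idx <- withr::with_seed(seed, sort(sample(idx, maxPixels)))
  X <- matrix(resp, H * W, 8L)[idx, , drop = FALSE]
  fit <- clusterImageTextons(X, seed = seed)
  inRegion <- NULL
  if (!is.null(regionMask)) {
    rm <- EBImage::resize(regionMask * 1, w = newDim[1L],
                          h = newDim[2L]) >= 0.5
    inside <- rm[idx]
    inRegion <- vapply(seq_len(nrow(fit$centers)), function(k) {
      sup <- fit$assignments == k
      if (!any(sup)) 0 else mean(inside[sup])
    }, numeric(1))
  }
  list(centers = fit$centers, inRegion = inRegion)
}

orderDictionary <- function(centers, source) {
  first <- which.min(sqrt(rowSums(centers^2)))
  d <- sqrt(colSums((t(centers) - centers[first, ])^2))
  ord <- order(d)
  list(centers = centers[ord, , drop = FALSE], source = source[ord])
}

## Merge the closest pair of centres until exactly `target` remain.
## A merged entry keeps the "crystal" tag if either member carried it,
## so crystal representation is never silently lost.
mergeToTarget <- function(centers, source, target) {
  while (nrow(centers) > target) {
    d <- as.matrix(stats::dist(centers))
    diag(d) <- Inf
    ij <- arrayInd(which.min(d), dim(d))
    i <- min(ij); j <- max(ij)
    centers[i, ] <- (centers[i, ] + centers[j, ]) / 2
    if (source[j] == "crystal") source[i] <- "crystal"
    centers <- centers[-j, , drop = FALSE]
    source <- source[-j]
  }
  list(centers = centers, source = source)
}

#' Build a texton dictionary by two-stage clustering
#'
#' Stage 1 clusters the filter responses of each training image
#' independently with a variational Bayes Gaussian mixture
#' ([clusterImageTextons()]); the resulting per-image centres are
#' concatenated. Stage 2 removes inter-image redundancy with DP-means
#' ([dpMeans()]): once over the centres from the precipitation image set
#' and, separately, over the crystal-related centres from the
#' crystal-containing image set. A centre counts as crystal-related when
#' at least half of its supporting pixels fall inside the image's crystal
#' mask. The two resulting texton sets are concatenated and ordered so the
#' first entry is the lowest-magnitude texton and the rest are sorted by
#' distance to it.
#'
#' With \code{targetSize} given, the DP-means threshold is calibrated by
#' bisection so the final dictionary has exactly that many entries; since
#' the cluster count is a step function of the threshold, an unattainable
#' exact size is resolved by merging the closest centre pair of the
#' smallest larger dictionary. With \code{targetSize = NULL} the fixed
#' \code{lambda} is used as-is.
#'
#' @param precipitateImages list of grey image matrices (0-255) showing
#'   precipitation patterns.
#' @param crystalImages list of grey image matrices containing crystals.
#' @param crystalMasks list of logical matrices (same sizes as
#'   \code{crystalImages}) marking crystal pixels.
#' @param lambda DP-means distance threshold (default 0.5).
#' @param targetSize optional exact dictionary size (e.g. 300 for the
#'   reference dictionary).
#' @param bank filter bank (default [makeFilterBank()]).
#' @param scale image downscale factor before filtering (default 0.25).
#' @param precipitateMasks,crystalDropletMasks optional lists of droplet
#'   masks restricting which pixels of each image enter stage 1.
#' @param maxPixels per-image cap on response vectors fed to stage 1
#'   (default 2000, subsampled with the seed).
#' @param seed RNG seed; the build is fully reproducible given the seed.
#' @return a [TextonDictionary-class] object.
#' @seealso [referenceDictionary()], [dropletDescriptor()]
#' @export
buildDictionary <- function(precipitateImages, crystalImages, crystalMasks,
                            lambda = 0.5, targetSize = NULL,
                            bank = makeFilterBank(), scale = 0.25,
                            precipitateMasks = NULL,
                            crystalDropletMasks = NULL,
                            maxPixels = 2000L, seed = 1L) {
  if (length(precipitateImages) < 1L || length(crystalImages) < 1L)
    stop("need at least one image in each training set")
  if (length(crystalMasks) != length(crystalImages))
    stop("crystalMasks must match crystalImages")

  elt <- function(lst, i) if (is.null(lst)) NULL else lst[[i]]
  # content-derived seed offset: identical duplicated images get identical
  # stage-1 subsampling and initialisation, so stage 2 can collapse them
  contentSeed <- function(img) as.integer(round(sum(img)) %% 65536)

  precC <- list()
  for (i in seq_along(precipitateImages)) {
    st <- imageStage1Centers(precipitateImages[[i]], bank, scale, maxPixels,
                             seed = seed + contentSeed(precipitateImages[[i]]),
                             dropletMask = elt(precipitateMasks, i))
    if (!is.null(st)) precC[[length(precC) + 1L]] <- st$centers
  }
  precC <- do.call(rbind, precC)

  crysC <- list()
  for (i in seq_along(crystalImages)) {
    st <- imageStage1Centers(crystalImages[[i]], bank, scale, maxPixels,
                             seed = seed + contentSeed(crystalImages[[i]]),
                             dropletMask = elt(crystalDropletMasks, i),
                             regionMask = crystalMasks[[i]])
    if (is.null(st)) next
    sel <- st$inRegion >= 0.5
    if (any(sel))
      crysC[[length(crysC) + 1L]] <- st$centers[sel, , drop = FALSE]
  }
  crysC <- if (length(crysC)) do.call(rbind, crysC) else NULL
  if (is.null(crysC))
    warning("no crystal-related cluster centres found; ",
            "building a precipitate-only dictionary")

  assemble <- function(lam) {
    p <- dpMeans(precC, lam)$centers
    out <- list(centers = p,
                source = rep("precipitate", nrow(p)))
    if (!is.null(crysC)) {
      cc <- dpMeans(crysC, lam)$centers
      out$centers <- rbind(out$centers, cc)
      out$source <- c(out$source, rep("crystal", nrow(cc)))
    }
    out
  }

  usedLambda <- lambda
  if (is.null(targetSize)) {
    dict <- assemble(lambda)
  } else {
    lo <- 1e-4
    hi <- max(stats::dist(rbind(precC, crysC))) + 1
    kLo <- nrow(assemble(lo)$centers)
    if (kLo < targetSize) {
      warning("training set yields only ", kLo,
              " distinct textons; targetSize unreachable")
      dict <- assemble(lo); usedLambda <- lo
    } else {
      best <- NULL; bestLam <- NA_real_
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        cand <- assemble(mid)
        k <- nrow(cand$centers)
        if (k >= targetSize && (is.null(best) ||
                                k < nrow(best$centers))) {
          best <- cand; bestLam <- mid
        }
        if (k == targetSize) break
        if (k > targetSize) lo <- mid else hi <- mid
      }
      dict <- best; usedLambda <- bestLam
      if (nrow(dict$centers) > targetSize)
        dict <- mergeToTarget(dict$centers, dict$source, targetSize)
    }
  }
  dict <- orderDictionary(dict$centers, dict$source)
  rownames(dict$centers) <- NULL
  new("TextonDictionary", centers = dict$centers, source = dict$source,
      lambda = usedLambda)
}

#' Write a texton dictionary to a plain tabular file
#'
#' One row per texton: a \code{source} column followed by the eight
#' response-channel values, tab-separated. The DP-means threshold is kept
#' in a header comment.
#'
#' @param dict a [TextonDictionary-class] object.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTextonDictionary <- function(dict, path) {
  stopifnot(is(dict, "TextonDictionary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# texton dictionary; lambda=%.17g", dict@lambda), con)
  df <- data.frame(source = dict@source,
                   signif(dict@centers, 9))
  names(df) <- c("source", paste0("v", 1:8))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a texton dictionary written by [writeTextonDictionary()]
#'
#' @param path path to the tabular dictionary file.
#' @return a [TextonDictionary-class] object.
#' @export
readTextonDictionary <- function(path) {
  first <- readLines(path, n = 1L)
  lambda <- if (grepl("lambda=", first))
    as.numeric(sub(".*lambda=", "", first)) else NA_real_
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  new("TextonDictionary",
      centers = as.matrix(df[, paste0("v", 1:8)]),
      source = as.character(df$source), lambda = lambda)
}

#' The shipped reference texton dictionary
#'
#' Loads the 300-entry dictionary distributed with the package. It was
#' built by [buildReferenceDictionary()] from the seeded synthetic training
#' corpus (100 precipitation and 52 crystal-containing fixtures) — a
#' synthetic stand-in sized and structured like a production dictionary;
#' for real imagers a dictionary should be rebuilt from real droplets with
#' the same protocol.
#'
#' @return a [TextonDictionary-class] object with 300 entries.
#' @examples
#' d <- referenceDictionary()
#' nTextons(d)
#' @export
referenceDictionary <- function() {
  readTextonDictionary(system.file("extdata",
                                   "reference_textons_synthetic.tsv",
                                   package = "dropRank", mustWork = TRUE))
}

#' Build the reference dictionary from the synthetic corpus
#'
#' Generates the seeded synthetic training corpus (100 precipitation
#' fixtures and 52 crystal-containing fixtures with ground-truth crystal
#' masks) and runs the size-calibrated two-stage clustering to a 300-entry
#' dictionary.
#'
#' @param seed RNG seed controlling fixture generation, pixel subsampling
#'   and stage-1 initialisations.
#' @param nPrecipitate,nCrystal training set sizes (defaults 100 and 52).
#' @param targetSize final dictionary size (default 300).
#' @param ... further arguments passed to [buildDictionary()].
#' @return a [TextonDictionary-class] object.
#' @seealso [referenceDictionary()]
#' @export
buildReferenceDictionary <- function(seed = 1L, nPrecipitate = 100L,
                                     nCrystal = 52L, targetSize = 300L,
                                     ...) {
  classes <- c("precipitate", "crystal", "microcrystal_shower")
  precImgs <- vector("list", nPrecipitate)
  precMasks <- vector("list", nPrecipitate)
  for (i in seq_len(nPrecipitate)) {
    cls <- c("precipitate", "clear", "phase_separation")[1L + (i %% 3L)]
    w <- generateWell(fixtureSpec(cls, seed = seed * 100000 + i))
    precImgs[[i]] <- w$image
    precMasks[[i]] <- w$truth$dropletMask
  }
  crysImgs <- vector("list", nCrystal)
  crysMasks <- vector("list", nCrystal)
  crysDropMasks <- vector("list", nCrystal)
  for (i in seq_len(nCrystal)) {
    cls <- if (i %% 3L == 0L) "microcrystal_shower" else "crystal"
    w <- generateWell(fixtureSpec(cls, seed = seed * 100000 + 50000 + i))
    crysImgs[[i]] <- w$image
    crysMasks[[i]] <- w$truth$crystalMask
    crysDropMasks[[i]] <- w$truth$dropletMask
  }
  buildDictionary(precImgs, crysImgs, crysMasks,
                  targetSize = targetSize,
                  precipitateMasks = precMasks,
                  crystalDropletMasks = crysDropMasks,
                  seed = seed, ...)
}
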