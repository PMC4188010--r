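#' Texton descriptor of a segmented droplet
#'
#' Runs the droplet preprocessing and feature chain: shadow gamma
#' correction over the droplet, radial boundary extension, z-score
#' normalisation and downscaling to the working resolution, filtering
#' with the rotation-invariant bank, nearest-texton labelling and the
#' final frequency histogram. Pixels of the extension ring and of the
#' filter border are never counted.
#'
#' @param image numeric grey matrix (0-255) containing the droplet.
#' @param boundary a [DropletBoundary-class] from [segmentDroplet()], or
#'   any object with a droplet mask (a logical matrix is accepted and
#'   wrapped).
#' @param bank filter bank (default [makeFilterBank()]).
#' @param dict a [TextonDictionary-class].
#' @param scale working-resolution downscale factor (default 0.25).
#' @param gammaSigma low-pass sigma of the shadow correction (default 1).
#' @return integer histogram of length \code{nTextons(dict)} with
#'   attribute \code{nPixels}; also carries attribute \code{labels} (the
#'   texton map at working resolution).
#' @examples
#' \dontrun{
#' bank <- makeFilterBank()
#' dict <- referenceDictionary()
#' w <- generateWell(fixtureSpec("precipitate", seed = 3))
#' b <- maskToBoundary(w$truth$dropletMask)
#' h <- dropletDescriptor(w$image, b, bank, dict)
#' }
#' @seealso [processWellImage()]
#' @export
dropletDescriptor <- function(image, boundary, bank = makeFilterBank(),
                              dict, scale = 0.25, gammaSigma = 1) {
  if (is.matrix(boundary) && is.logical(boundary))
    boundary <- maskToBoundary(boundary)
  stopifnot(is(boundary, "DropletBoundary"), is(dict, "TextonDictionary"))
  img <- gammaCorrect(image, mask = boundary@mask, sigma = gammaSigma)
  ext <- extendBoundary(img, boundary)
  region <- ext$dropletMask | ext$exclusionMask
  pd <- normalizeAndScale(ext$image, ext$dropletMask, scale = scale,
                          normMask = region)
  resp <- applyFilterBank(pd@image, bank)
  labels <- labelPixels(resp, dict, mask = pd@validMask)
  h <- textonHistogram(labels, nTextons(dict))
  attr(h, "labels") <- labels
  h
}

#' Wrap a ground-truth droplet mask as a boundary object
#'
#' Builds a [DropletBoundary-class] from a binary droplet mask (e.g. a
#' synthetic ground-truth mask), tracing the radius per degree about the
#' mask centroid. Useful for running the descriptor chain when
#' segmentation is not under study.
#'
#' @param mask logical matrix with a single droplet region.
#' @return a [DropletBoundary-class] object.
#' @export
maskToBoundary <- function(mask) {
  if (!any(mask)) stop("mask is empty")
  props <- maskShapeProperties(mask)
  ctr <- props$centroid
  rMax <- max(nrow(mask), ncol(mask))
  radii <- maskRadiiByDegree(mask, ctr, rMax)
  new("DropletBoundary", center = ctr, radiusByDegree = radii,
      mask = mask, properties = props, attempt = "plain")
}

#' Process one well image end to end
#'
#' Full per-image pipeline: grey conversion and contrast stretch,
#' background registration, optional fault screening, droplet
#' segmentation (with gamma/blur fallbacks) and the texton descriptor.
#'
#' @param image numeric grey or colour array.
#' @param bg a [BackgroundModel-class].
#' @param subwell subwell position of the image.
#' @param bank filter bank.
#' @param dict texton dictionary.
#' @param faultModel optional [FaultClassifier-class]; faulty droplets
#'   are not processed further.
#' @param config list merged over the defaults of [segmentDroplet()];
#'   entries \code{scale} and \code{gammaSigma} feed the descriptor
#'   stage, \code{maxShift} the registration.
#' @return list with \code{status} (\code{"ok"}, \code{"faulty"} or
#'   \code{"unsegmentable"}), \code{histogram} (or \code{NULL}),
#'   \code{registration}, \code{boundary}, \code{fault} (verdict row or
#'   \code{NULL}).
#' @export
processWellImage <- function(image, bg, subwell = NULL,
                             bank = makeFilterBank(), dict,
                             faultModel = NULL, config = list()) {
  cfg <- utils::modifyList(list(scale = 0.25, gammaSigma = 1,
                                maxShift = 10L), config)
  img <- toGreyFullRange(image)
  reg <- registerWell(img, bg, subwell = subwell,
                      maxShift = cfg$maxShift)
  boundary <- withCallingHandlers(
    segmentDroplet(img, reg, bg, subwell = subwell, config = config),
    warning = function(w) invokeRestart("muffleWarning"))
  fault <- NULL
  if (!is.null(faultModel)) {
    fv <- faultFeatures(img, reg, bg, subwell = subwell,
                        boundary = boundary)
    fault <- predictFault(faultModel, fv)
    if (fault$verdict == "faulty")
      return(list(status = "faulty", histogram = NULL,
                  registration = reg, boundary = boundary,
                  fault = fault))
  }
  if (is.null(boundary))
    return(list(status = "unsegmentable", histogram = NULL,
                registration = reg, boundary = NULL, fault = fault))
  h <- dropletDescriptor(img, boundary, bank, dict, scale = cfg$scale,
                         gammaSigma = cfg$gammaSigma)
  list(status = "ok", histogram = h, registration = reg,
       boundary = boundary, fault = fault)
}

#' Process and score a whole plate
#'
#' Runs [processWellImage()] over every image of a plate manifest, scores
#' the successful droplets with a ranking forest and returns the ranking
#' together with a per-image status log (faulty and unsegmentable
#' droplets are excluded from the ranking and reported).
#'
#' @param images named list of image matrices (names = manifest ids), or
#'   \code{NULL} to read from \code{manifest$path}.
#' @param manifest data.frame with \code{id}, \code{plate}, \code{well},
#'   \code{subwell} (and \code{path} when \code{images} is \code{NULL}).
#' @param bg a [BackgroundModel-class].
#' @param bank filter bank.
#' @param dict texton dictionary.
#' @param ranker a [TextonRanker-class].
#' @param faultModel optional [FaultClassifier-class].
#' @param mode ranking mode, see [rankPlate()].
#' @param config see [processWellImage()].
#' @return list with \code{ranking} (a [PlateRanking-class]),
#'   \code{scores} (data.frame of scored droplets) and \code{log}
#'   (data.frame: id, status).
#' @export
processPlate <- function(images, manifest, bg, bank = makeFilterBank(),
                         dict, ranker, faultModel = NULL,
                         mode = "by_subwell", config = list()) {
  n <- nrow(manifest)
  status <- character(n)
  hists <- vector("list", n)
  for (i in seq_len(n)) {
    img <- if (is.null(images)) readDropletImage(manifest$path[i]) else
      images[[manifest$id[i]]]
    res <- processWellImage(img, bg, subwell = manifest$subwell[i],
                            bank = bank, dict = dict,
                            faultModel = faultModel, config = config)
    status[i] <- res$status
    if (res$status == "ok") hists[[i]] <- as.numeric(res$histogram)
  }
  ok <- status == "ok"
  log <- data.frame(id = manifest$id, status = status,
                    stringsAsFactors = FALSE)
  if (!any(ok))
    return(list(ranking = NULL, scores = NULL, log = log))
  H <- do.call(rbind, hists[ok])
  scores <- scoreDroplets(ranker, H,
                          manifest[ok, c("id", "plate", "well", "subwell")])
  list(ranking = rankPlate(scores, mode = mode), scores = scores,
       log = log)
}

#' @useDynLib dropRank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom withr with_seed
NULL
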