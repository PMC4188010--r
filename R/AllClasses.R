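#' @import methods
NULL

#' Rotation-invariant texture filter bank
#'
#' A bank of 38 anisotropic Gaussian-derivative kernels: edge (first
#' derivative) and bar (second derivative) filters at six orientations and
#' three scales each, plus a rotationally symmetric Gaussian and a Laplacian
#' of Gaussian. Orientation responses are later collapsed by taking the
#' maximum per scale, so the bank yields eight rotation-invariant response
#' channels per pixel.
#'
#' @slot kernels list of 38 odd-square numeric matrices sharing one support.
#' @slot info data.frame with one row per kernel: \code{kind}
#'   (\code{"edge"}, \code{"bar"}, \code{"gaussian"}, \code{"log"}),
#'   \code{scale} (1-based scale index; \code{NA} for the symmetric
#'   filters), \code{orientation} (1-based orientation index; \code{NA}
#'   likewise), \code{sigma_x}, \code{sigma_y}.
#' @slot scaleFactor numeric(1), multiplier applied to the canonical sigma
#'   values of the bank (default 0.5, i.e. the bank at half its original
#'   scale).
#' @slot support integer(1), kernel side length (odd).
#'
#' @seealso [makeFilterBank()], [applyFilterBank()]
#' @name FilterBank-class
#' @rdname FilterBank-class
#' @exportClass FilterBank
setClass("FilterBank",
  representation(
    kernels = "list",
    info = "data.frame",
    scaleFactor = "numeric",
    support = "integer"
  )
)

setValidity("FilterBank", function(object) {
  msg <- NULL
  if (length(object@kernels) != 38L)
    msg <- c(msg, "a filter bank must contain exactly 38 kernels")
  if (nrow(object@info) != length(object@kernels))
    msg <- c(msg, "info must have one row per kernel")
  tab <- table(object@info$kind)
  counts <- as.integer(tab[c("edge", "bar", "gaussian", "log")])
  if (!identical(counts, c(18L, 18L, 1L, 1L)))
    msg <- c(msg, "bank must hold 18 edge, 18 bar, 1 gaussian, 1 log kernel")
  sup <- object@support
  if (sup %% 2L != 1L)
    msg <- c(msg, "kernel support must be odd")
  ok <- vapply(object@kernels, function(k)
    is.matrix(k) && all(dim(k) == sup), logical(1))
  if (!all(ok))
    msg <- c(msg, "all kernels must be square matrices of the shared support")
  if (length(object@scaleFactor) != 1L || object@scaleFactor <= 0)
    msg <- c(msg, "scaleFactor must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Texton dictionary
#'
#' An ordered list of texton prototypes: cluster centres in the
#' 8-dimensional space of collapsed filter-bank responses. Entry 1 is the
#' lowest-magnitude texton and the remaining entries are sorted by their
#' Euclidean distance to entry 1. Each entry is tagged with the image set it
#' came from (precipitation or crystal training images).
#'
#' @slot centers numeric matrix, K x 8, one texton per row.
#' @slot source character vector of length K, each \code{"precipitate"} or
#'   \code{"crystal"}.
#' @slot lambda numeric(1), the DP-means distance threshold that produced
#'   the dictionary (after calibration, if any).
#'
#' @seealso [buildDictionary()], [labelPixels()], [referenceDictionary()]
#' @name TextonDictionary-class
#' @rdname TextonDictionary-class
#' @exportClass TextonDictionary
setClass("TextonDictionary",
  representation(
    centers = "matrix",
    source = "character",
    lambda = "numeric"
  )
)

setValidity("TextonDictionary", function(object) {
  msg <- NULL
  K <- nrow(object@centers)
  if (K < 1L)
    msg <- c(msg, "dictionary must contain at least one texton")
  if (ncol(object@centers) != 8L)
    msg <- c(msg, "textons must be 8-dimensional response vectors")
  if (length(object@source) != K)
    msg <- c(msg, "source must tag every texton")
  if (!all(object@source %in% c("precipitate", "crystal")))
    msg <- c(msg, "source tags must be 'precipitate' or 'crystal'")
  if (K > 1L) {
    d <- sqrt(colSums((t(object@centers) - object@centers[1L, ])^2))
    if (any(diff(d) < -1e-8))
      msg <- c(msg, "entries must be sorted by distance to entry 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-subwell empty-plate background model
#'
#' Pixel-wise mean images of empty wells, one per subwell position of a
#' plate type, used to locate the well frame by rigid registration and to
#' seed droplet segmentation.
#'
#' @slot backgrounds named list of numeric matrices (grey images, 0-255),
#'   one per subwell position.
#' @slot frameMasks named list of logical matrices marking well-frame
#'   pixels in each background (dark frame structure), same names as
#'   \code{backgrounds}.
#' @slot plateType character(1) identifier of the plate type.
#'
#' @seealso [buildBackground()], [registerWell()]
#' @name BackgroundModel-class
#' @rdname BackgroundModel-class
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  representation(
    backgrounds = "list",
    frameMasks = "list",
    plateType = "character"
  )
)

setValidity("BackgroundModel", function(object) {
  msg <- NULL
  if (length(object@backgrounds) < 1L)
    msg <- c(msg, "at least one subwell background is required")
  if (!identical(names(object@backgrounds), names(object@frameMasks)))
    msg <- c(msg, "backgrounds and frameMasks must share subwell names")
  if (is.null(msg)) TRUE else msg
})

#' Rigid registration of a well image against its background
#'
#' The integer x/y translation minimising the pixel-to-pixel difference
#' between a well image and the empty-plate background of its subwell.
#'
#' @slot dx integer(1), column offset (positive = image shifted right).
#' @slot dy integer(1), row offset (positive = image shifted down).
#' @slot residual numeric(1), mean absolute pixel difference at the optimum.
#'
#' @seealso [registerWell()]
#' @name WellRegistration-class
#' @rdname WellRegistration-class
#' @exportClass WellRegistration
setClass("WellRegistration",
  representation(dx = "integer", dy = "integer", residual = "numeric")
)

#' Traced droplet boundary
#'
#' Result of circular-shortest-path droplet segmentation: a boundary radius
#' for each integer angular degree around a centre inside the droplet, the
#' filled binary mask, and shape properties of the mask.
#'
#' @slot center numeric(2), (row, col) of the polar origin.
#' @slot radiusByDegree numeric(360), boundary radius in pixels at angles
#'   0..359 degrees.
#' @slot mask logical matrix, filled droplet mask in image coordinates.
#' @slot properties list with \code{area}, \code{centroid} (row, col),
#'   \code{eccentricity}, \code{majorAxis}, \code{minorAxis} computed from
#'   the mask second moments.
#' @slot attempt character(1), which segmentation attempt produced the
#'   boundary: \code{"plain"}, \code{"gamma"} or \code{"blur"}.
#'
#' @seealso [segmentDroplet()]
#' @name DropletBoundary-class
#' @rdname DropletBoundary-class
#' @exportClass DropletBoundary
setClass("DropletBoundary",
  representation(
    center = "numeric",
    radiusByDegree = "numeric",
    mask = "matrix",
    properties = "list",
    attempt = "character"
  )
)

setValidity("DropletBoundary", function(object) {
  msg <- NULL
  if (length(object@radiusByDegree) != 360L)
    msg <- c(msg, "radiusByDegree must have one entry per degree (360)")
  if (any(!is.finite(object@radiusByDegree)) ||
      any(object@radiusByDegree <= 0))
    msg <- c(msg, "boundary radii must be positive and finite")
  if (is.null(msg)) TRUE else msg
})

#' Normalised, rescaled droplet ready for filtering
#'
#' The gamma-corrected, boundary-extended droplet after z-score intensity
#' normalisation and downscaling to the working resolution of the texton
#' dictionary.
#'
#' @slot image numeric matrix, mean 0 and standard deviation 1 before
#'   rescaling.
#' @slot validMask logical matrix, pixels of the original droplet that may
#'   contribute to the texton histogram (extension ring and filter border
#'   excluded).
#' @slot scale numeric(1), the downscale factor applied (default 0.25).
#'
#' @seealso [normalizeAndScale()], [dropletDescriptor()]
#' @name ProcessedDroplet-class
#' @rdname ProcessedDroplet-class
#' @exportClass ProcessedDroplet
setClass("ProcessedDroplet",
  representation(image = "matrix", validMask = "matrix", scale = "numeric")
)

#' Ranked droplet scores for a set of plates
#'
#' Posterior scores of the "interesting" (crystalline) class for each
#' droplet, with plate/well/subwell identity and the viewing order implied
#' by descending score.
#'
#' @slot scores data.frame with columns \code{id}, \code{plate},
#'   \code{well}, \code{subwell}, \code{score}, \code{rank}; one row per
#'   ranked unit, sorted by rank.
#' @slot mode character(1), \code{"by_subwell"} (every droplet ranked) or
#'   \code{"by_well"} (wells ranked by the maximum score of their
#'   subwells).
#'
#' @seealso [rankPlate()], [profileSummary()]
#' @name PlateRanking-class
#' @rdname PlateRanking-class
#' @exportClass PlateRanking
setClass("PlateRanking",
  representation(scores = "data.frame", mode = "character")
)

setValidity("PlateRanking", function(object) {
  msg <- NULL
  s <- object@scores
  need <- c("id", "plate", "well", "subwell", "score", "rank")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("scores must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (nrow(s) && (any(s$score < 0) || any(s$score > 1)))
      msg <- c(msg, "scores must lie in [0, 1]")
    if (nrow(s) && !identical(sort(s$rank), seq_len(nrow(s))))
      msg <- c(msg, "ranks must be a permutation of 1..n")
  }
  if (!object@mode %in% c("by_subwell", "by_well"))
    msg <- c(msg, "mode must be 'by_subwell' or 'by_well'")
  if (is.null(msg)) TRUE else msg
})

#' Random forest droplet ranker
#'
#' A two-class random forest trained on texton histograms, whose posterior
#' probability for the "interesting" class is used directly as a ranking
#' score (no classification threshold is ever applied).
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot classes character(2), class labels
#'   (\code{c("uninteresting", "interesting")}).
#' @slot nTextons integer(1), expected histogram length.
#' @slot seed integer(1), RNG seed used for training.
#'
#' @seealso [trainRanker()], [scoreDroplets()]
#' @name TextonRanker-class
#' @rdname TextonRanker-class
#' @exportClass TextonRanker
setClass("TextonRanker",
  representation(forest = "ANY", classes = "character",
                 nTextons = "integer", seed = "integer")
)

#' Random forest fault classifier
#'
#' A two-class random forest over gradient statistics and droplet shape
#' features that flags dispensing/imaging faults (empty wells, undersized
#' drops, off-frame wells) before texture analysis.
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot oobAccuracy numeric(1), out-of-bag accuracy of the training run.
#' @slot seed integer(1), RNG seed used for training.
#'
#' @seealso [trainFaultClassifier()], [predictFault()]
#' @name FaultClassifier-class
#' @rdname FaultClassifier-class
#' @exportClass FaultClassifier
setClass("FaultClassifier",
  representation(forest = "ANY", oobAccuracy = "numeric", seed = "integer")
)
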