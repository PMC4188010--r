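#' @include AllClasses.R
NULL

#' Number of textons in a dictionary
#'
#' @param x a [TextonDictionary-class] object.
#' @return integer(1), the dictionary size K.
#' @examples
#' d <- new("TextonDictionary", centers = matrix(0, 1, 8),
#'          source = "precipitate", lambda = 0.5)
#' nTextons(d)
#' @export
setGeneric("nTextons", function(x) standardGeneric("nTextons"))

#' @rdname nTextons
#' @export
setMethod("nTextons", "TextonDictionary", function(x) nrow(x@centers))

#' Texton prototype matrix of a dictionary
#'
#' @param x a [TextonDictionary-class] object.
#' @return K x 8 numeric matrix of texton centres.
#' @export
setGeneric("textonCenters", function(x) standardGeneric("textonCenters"))

#' @rdname textonCenters
#' @export
setMethod("textonCenters", "TextonDictionary", function(x) x@centers)

#' Source tags of dictionary entries
#'
#' @param x a [TextonDictionary-class] object.
#' @return character vector, \code{"precipitate"} or \code{"crystal"} per
#'   entry.
#' @export
setGeneric("textonSource", function(x) standardGeneric("textonSource"))

#' @rdname textonSource
#' @export
setMethod("textonSource", "TextonDictionary", function(x) x@source)

#' Kernel list of a filter bank
#'
#' @param x a [FilterBank-class] object.
#' @return list of kernel matrices.
#' @export
setGeneric("filterKernels", function(x) standardGeneric("filterKernels"))

#' @rdname filterKernels
#' @export
setMethod("filterKernels", "FilterBank", function(x) x@kernels)

#' Kernel metadata of a filter bank
#'
#' @param x a [FilterBank-class] object.
#' @return data.frame with kind/scale/orientation/sigma columns, one row
#'   per kernel.
#' @export
setGeneric("filterInfo", function(x) standardGeneric("filterInfo"))

#' @rdname filterInfo
#' @export
setMethod("filterInfo", "FilterBank", function(x) x@info)

#' Droplet mask of a traced boundary
#'
#' @param x a [DropletBoundary-class] object.
#' @return logical matrix in image coordinates.
#' @export
setGeneric("boundaryMask", function(x) standardGeneric("boundaryMask"))

#' @rdname boundaryMask
#' @export
setMethod("boundaryMask", "DropletBoundary", function(x) x@mask)

#' Boundary radii by angular degree
#'
#' @param x a [DropletBoundary-class] object.
#' @return numeric(360), radius in pixels at 0..359 degrees.
#' @export
setGeneric("boundaryRadii", function(x) standardGeneric("boundaryRadii"))

#' @rdname boundaryRadii
#' @export
setMethod("boundaryRadii", "DropletBoundary", function(x) x@radiusByDegree)

#' Score table of a plate ranking
#'
#' @param x a [PlateRanking-class] object.
#' @return data.frame sorted by rank with id, plate, well, subwell, score
#'   and rank columns.
#' @export
setGeneric("rankedScores", function(x) standardGeneric("rankedScores"))

#' @rdname rankedScores
#' @export
setMethod("rankedScores", "PlateRanking", function(x) x@scores)

setMethod("show", "FilterBank", function(object) {
  cat(sprintf(
    "FilterBank: %d kernels (%dx%d support), scale factor %.3g\n",
    length(object@kernels), object@support, object@support,
    object@scaleFactor))
  tab <- table(object@info$kind)
  cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                  collapse = "  "), "\n", sep = "")
})

setMethod("show", "TextonDictionary", function(object) {
  tab <- table(object@source)
  cat(sprintf("TextonDictionary: %d textons (lambda = %.4g)\n",
              nrow(object@centers), object@lambda))
  cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                  collapse = "  "), "\n", sep = "")
})

setMethod("show", "BackgroundModel", function(object) {
  d <- dim(object@backgrounds[[1L]])
  cat(sprintf("BackgroundModel '%s': %d subwell(s), %dx%d px\n",
              object@plateType, length(object@backgrounds), d[1L], d[2L]))
})

setMethod("show", "WellRegistration", function(object) {
  cat(sprintf("WellRegistration: dx=%d dy=%d (residual %.4g)\n",
              object@dx, object@dy, object@residual))
})

setMethod("show", "DropletBoundary", function(object) {
  cat(sprintf(
    "DropletBoundary: centre (%.1f, %.1f), mean radius %.1f px, area %d px (%s attempt)\n",
    object@center[1L], object@center[2L],
    mean(object@radiusByDegree), object@properties$area, object@attempt))
})

setMethod("show", "PlateRanking", function(object) {
  cat(sprintf("PlateRanking (%s): %d units over %d plate(s)\n",
              object@mode, nrow(object@scores),
              length(unique(object@scores$plate))))
  if (nrow(object@scores))
    print(utils::head(object@scores, 5L))
})

setMethod("show", "TextonRanker", function(object) {
  cat(sprintf("TextonRanker: %d trees on %d-bin histograms (seed %d)\n",
              object@forest$ntree, object@nTextons, object@seed))
})

setMethod("show", "FaultClassifier", function(object) {
  cat(sprintf("FaultClassifier: %d trees, OOB accuracy %.3f (seed %d)\n",
              object@forest$ntree, object@oobAccuracy, object@seed))
})
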