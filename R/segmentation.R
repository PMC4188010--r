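#' Build per-subwell background models from empty-plate images
#'
#' Averages, pixel-wise, all empty-well images of each subwell position of
#' a plate type. The averages serve two purposes: locating the well in new
#' images by rigid registration and suppressing the well-frame edges
#' during droplet segmentation. Frame pixels are extracted from each
#' background by intensity thresholding (the frame is the dark plastic
#' structure) and lightly dilated.
#'
#' Each empty-well image is contrast-stretched with [toGreyFullRange()]
#' before averaging (unless \code{stretch = FALSE}), so backgrounds live
#' on the same intensity scale as the stretched query images they are
#' compared against.
#'
#' @param images list of grey image matrices (0-255) of empty wells.
#' @param subwells character vector, the subwell position of each image.
#' @param plateType identifier for the plate type (default
#'   \code{"synthetic"}).
#' @param stretch contrast-stretch each image first (default TRUE).
#' @return a [BackgroundModel-class] object.
#' @examples
#' imgs <- replicate(4, matrix(runif(100, 100, 200), 10), simplify = FALSE)
#' bg <- buildBackground(imgs, rep(c("a", "b"), 2))
#' @seealso [registerWell()], [segmentDroplet()]
#' @export
buildBackground <- function(images, subwells, plateType = "synthetic",
                            stretch = TRUE) {
  if (length(images) < 1L) stop("need at least one empty-well image")
  if (length(subwells) != length(images))
    stop("subwells must label every image")
  if (stretch) images <- lapply(images, toGreyFullRange)
  pos <- sort(unique(subwells))
  bgs <- lapply(pos, function(p) {
    sub <- images[subwells == p]
    Reduce(`+`, sub) / length(sub)
  })
  names(bgs) <- pos
  frames <- lapply(bgs, function(bg) {
    thr <- (stats::quantile(bg, 0.02) + stats::quantile(bg, 0.98)) / 2
    EBImage::dilate(bg < thr, EBImage::makeBrush(5L, "disc")) > 0
  })
  names(frames) <- pos
  new("BackgroundModel", backgrounds = bgs, frameMasks = frames,
      plateType = plateType)
}

#' Rigidly register a well image against its background
#'
#' Exhaustively searches integer translations within \code{maxShift}
#' pixels for the one minimising the mean absolute pixel difference
#' between the image and the shifted background (over their overlap).
#' Ties are broken by the smallest \code{|dx| + |dy|}, then
#' lexicographically on (dy, dx).
#'
#' @param image numeric grey matrix.
#' @param bg a [BackgroundModel-class] object or a background matrix.
#' @param subwell subwell position name (when \code{bg} is a model).
#' @param maxShift search radius in pixels (default 10).
#' @return a [WellRegistration-class] object; positive \code{dx}/\code{dy}
#'   mean the well content sits right/down of its background position.
#' @export
registerWell <- function(image, bg, subwell = NULL, maxShift = 10L) {
  B <- if (is(bg, "BackgroundModel")) {
    if (is.null(subwell)) bg@backgrounds[[1L]] else bg@backgrounds[[subwell]]
  } else bg
  if (!all(dim(image) == dim(B)))
    stop("image and background must have the same size")
  n <- nrow(image); m <- ncol(image)
  best <- NULL
  for (dy in -maxShift:maxShift) {
    ri <- max(1L, 1L + dy):min(n, n + dy)        # image rows
    rb <- ri - dy                                 # background rows
    for (dx in -maxShift:maxShift) {
      ci <- max(1L, 1L + dx):min(m, m + dx)
      cb <- ci - dx
      res <- mean(abs(image[ri, ci] - B[rb, cb]))
      cand <- list(dx = dx, dy = dy, res = res)
      if (is.null(best) ||
          res < best$res - 1e-12 ||
          (abs(res - best$res) <= 1e-12 &&
           (abs(dx) + abs(dy) < abs(best$dx) + abs(best$dy) ||
            (abs(dx) + abs(dy) == abs(best$dx) + abs(best$dy) &&
             (dy < best$dy || (dy == best$dy && dx < best$dx))))))
        best <- cand
    }
  }
  new("WellRegistration", dx = as.integer(best$dx),
      dy = as.integer(best$dy), residual = best$res)
}

#' Circular shortest path through a polar cost matrix
#'
#' Finds the row index per column minimising the summed cost, subject to a
#' maximum row change of \code{step} between consecutive columns and
#' circular closure (the wrap from the last column back to the first obeys
#' the same constraint). The constrained dynamic programme is run from
#' every candidate start row and the global minimum is returned, so the
#' solution is exact.
#'
#' @param cost numeric matrix (rows = radii, columns = angles), all values
#'   finite; at least 2 rows.
#' @param step maximum row change per column (default 1).
#' @return integer vector of 1-based row indices, one per column, with
#'   attribute \code{cost} (the minimal total).
#' @examples
#' cost <- matrix(1, 5, 8); cost[3, ] <- 0
#' unique(circularShortestPath(cost))
#' @seealso [segmentDroplet()]
#' @export
circularShortestPath <- function(cost, step = 1L) {
  if (!is.matrix(cost) || nrow(cost) < 2L)
    stop("cost must be a matrix with at least 2 rows")
  if (any(!is.finite(cost)))
    stop("cost matrix must be finite")
  .cspExact(cost, as.integer(step))
}

## Polar sampling of an image about `center` at integer radii 1..rMax and
## integer degrees 0..359; rows are radii, columns angles.
polarSample <- function(img, center, rMax) {
  theta <- (0:359) * pi / 180
  rr <- outer(seq_len(rMax), -sin(theta))
  cc <- outer(seq_len(rMax), cos(theta))
  matrix(bilinearSample(img, center[1L] + rr, center[2L] + cc),
         rMax, 360L)
}

## One segmentation attempt on a prepared intensity image. Returns the
## boundary radii and diagnostic quantities, or NULL if the path search
## is impossible.
segmentAttempt <- function(img, frameMask, center, rMax, step, rMin = 4L) {
  grad <- gradientMagnitude(EBImage::gblur(img, sigma = 1))
  grad[frameMask] <- 0
  polarCost <- polarSample(-grad, center, rMax)
  rows <- rMin:rMax
  if (length(rows) < 2L) return(NULL)
  path <- circularShortestPath(polarCost[rows, , drop = FALSE], step = step)
  radii <- rows[path]
  n <- nrow(img); m <- ncol(img)
  pr <- matrix(seq_len(n), n, m) - center[1L]
  pc <- matrix(seq_len(m), n, m, byrow = TRUE) - center[2L]
  rad <- sqrt(pr^2 + pc^2)
  ang <- (round(atan2(-pr, pc) * 180 / pi) %% 360) + 1L
  mask <- rad <= radii[ang] + 0.5
  # fraction of boundary path pixels lying on the (suppressed) frame
  th <- (0:359) * pi / 180
  br <- clamp(round(center[1L] - radii * sin(th)), 1, n)
  bc <- clamp(round(center[2L] + radii * cos(th)), 1, m)
  onFrame <- mean(frameMask[cbind(br, bc)])
  list(radii = radii, mask = mask, onFrame = onFrame)
}

#' Segment the droplet with a circular shortest path
#'
#' Traces the droplet boundary on the gradient-magnitude image: well-frame
#' pixels (known from the registered background) are suppressed so the
#' path cannot lock onto the strong frame edges; the image is transformed
#' to polar coordinates about a seed point inside the droplet (the
#' centroid of the background-subtracted foreground) and the circular
#' shortest path over the negated gradient yields the boundary radius at
#' each degree. If the traced region is implausible (area outside 2-95%
#' of the well interior, or more than 10% of the boundary on the frame),
#' the search is retried on a gamma-corrected image (low-pass sigma 10,
#' which flattens large dark precipitate masses without touching the
#' high-frequency droplet rim) and finally on a blurred image.
#'
#' @param image numeric grey matrix (0-255).
#' @param reg a [WellRegistration-class] for this image.
#' @param bg a [BackgroundModel-class].
#' @param subwell subwell position name (default: first in \code{bg}).
#' @param config list of tuning parameters: \code{step} (path smoothness,
#'   default 1), \code{fgThreshold} (foreground |difference| threshold,
#'   grey levels, default 12), \code{areaRange} (plausible droplet area as
#'   a fraction of the well interior, default \code{c(0.02, 0.95)}),
#'   \code{maxFrameFrac} (default 0.1), \code{gammaSigma} (fallback
#'   low-pass sigma, default 10), \code{blurSigma} (final fallback blur,
#'   default 3).
#' @return a [DropletBoundary-class] object, or \code{NULL} (with a
#'   warning) when every attempt fails; unsegmentable droplets are
#'   excluded downstream.
#' @seealso [circularShortestPath()], [extendBoundary()]
#' @export
segmentDroplet <- function(image, reg, bg, subwell = NULL,
                           config = list()) {
  cfg <- utils::modifyList(list(step = 1L, fgThreshold = 12,
                                areaRange = c(0.02, 0.95),
                                maxFrameFrac = 0.10, minFgFraction = 0.4,
                                minForeground = 800L,
                                gammaSigma = 10, blurSigma = 3), config)
  B <- if (is.null(subwell)) bg@backgrounds[[1L]] else
    bg@backgrounds[[subwell]]
  FM <- if (is.null(subwell)) bg@frameMasks[[1L]] else
    bg@frameMasks[[subwell]]
  n <- nrow(image); m <- ncol(image)

  # shift background and frame to the registered position
  shift <- function(M, fill) {
    out <- matrix(fill, n, m)
    ri <- max(1L, 1L + reg@dy):min(n, n + reg@dy)
    ci <- max(1L, 1L + reg@dx):min(m, m + reg@dx)
    out[ri, ci] <- M[ri - reg@dy, ci - reg@dx]
    out
  }
  Bs <- shift(B, mean(B))
  FMs <- shift(FM, TRUE)

  interior <- !FMs
  # drop border-connected exterior: keep the largest connected non-frame
  # region containing the image centre neighbourhood
  wellArea <- sum(interior)
  # centre the difference on its interior median: per-image contrast
  # stretching shifts the photometric scale relative to the background,
  # and the droplet should stand out against that global offset
  diffImg <- image - Bs
  diffImg <- abs(diffImg - stats::median(diffImg[interior]))
  fg <- EBImage::gblur(diffImg, sigma = 2) > cfg$fgThreshold & interior
  if (sum(fg) < cfg$minForeground) {
    warning("droplet unsegmentable: no droplet foreground against the ",
            "background model")
    return(NULL)
  }
  seed <- maskShapeProperties(fg)$centroid
  seed <- clamp(seed, c(9, 9), c(n - 8, m - 8))
  rMax <- floor(min(seed[1L] - 1, seed[2L] - 1,
                    n - seed[1L], m - seed[2L]))
  if (rMax < 8L) {
    warning("droplet unsegmentable: seed too close to the image border")
    return(NULL)
  }

  attempts <- list(
    plain = function() image,
    gamma = function() gammaCorrect(image, sigma = cfg$gammaSigma),
    blur = function() as.matrix(EBImage::gblur(image,
                                               sigma = cfg$blurSigma))
  )
  chosen <- NULL
  fgArea <- sum(fg)
  for (nm in names(attempts)) {
    att <- segmentAttempt(attempts[[nm]](), FMs, seed, rMax,
                          step = cfg$step)
    if (is.null(att)) next
    areaFrac <- sum(att$mask & interior) / wellArea
    ok <- areaFrac >= cfg$areaRange[1L] && areaFrac <= cfg$areaRange[2L] &&
      att$onFrame <= cfg$maxFrameFrac &&
      sum(att$mask) >= cfg$minFgFraction * fgArea
    if (ok) {
      chosen <- list(att = att, name = nm)
      break
    }
  }
  if (is.null(chosen)) {
    warning("droplet unsegmentable: no boundary attempt succeeded")
    return(NULL)
  }
  att <- chosen$att
  props <- maskShapeProperties(att$mask)
  new("DropletBoundary", center = seed,
      radiusByDegree = as.numeric(att$radii), mask = att$mask,
      properties = props, attempt = chosen$name)
}
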