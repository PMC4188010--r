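#' Convert to grey and stretch contrast to the full 0-255 range
#'
#' Linearly maps the image so its minimum becomes 0 and its maximum 255.
#' Colour arrays (H x W x 3) are first converted to luminance. A constant
#' image maps to 0 everywhere.
#'
#' @param image numeric matrix or H x W x 3 array.
#' @return numeric matrix with range exactly \[0, 255\] (or all zero).
#' @examples
#' rng <- range(toGreyFullRange(matrix(50:150, 10)))
#' stopifnot(rng[1] == 0, rng[2] == 255)
#' @export
toGreyFullRange <- function(image) {
  if (length(dim(image)) == 3L)
    image <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
      0.114 * image[, , 3L]
  lo <- min(image); hi <- max(image)
  if (hi <= lo) return(image * 0)
  (image - lo) / (hi - lo) * 255
}

#' Non-uniform gamma correction for droplet shadows
#'
#' Corrects shadows around droplet rims by a per-pixel gamma
#' \eqn{\hat I = 255 (I / 255)^{\gamma}} where \eqn{\gamma} is the
#' low-pass-filtered intensity normalised to \[0, 1\] (clamped below at
#' \code{gammaMin}). Dark neighbourhoods therefore get low gamma and a
#' strong intensity boost, while bright regions (gamma near 1) are left
#' nearly untouched; the correction is monotone in the original intensity
#' and preserves the 0-255 range.
#'
#' @param droplet numeric grey matrix (0-255).
#' @param mask optional logical matrix; pixels outside it are returned
#'   unchanged.
#' @param sigma standard deviation of the Gaussian low-pass filter in
#'   pixels (default 1; droplet-segmentation fallback uses 10 to flatten
#'   large dark precipitate masses).
#' @param gammaMin lower clamp on gamma (default 0.05), preventing blow-up
#'   in near-black regions.
#' @return numeric matrix, corrected intensities in \[0, 255\].
#' @seealso [segmentDroplet()], [dropletDescriptor()]
#' @export
gammaCorrect <- function(droplet, mask = NULL, sigma = 1,
                         gammaMin = 0.05) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  imLP <- EBImage::gblur(droplet, sigma = sigma)
  gam <- clamp(imLP / 255, gammaMin, 1)
  out <- 255 * (clamp(droplet, 0, 255) / 255)^gam
  if (!is.null(mask)) out[!mask] <- droplet[!mask]
  out
}

## Boundary radius per integer degree about `center`, measured on a mask:
## the last radius (1 px steps) whose bilinear mask sample stays >= 0.5.
maskRadiiByDegree <- function(mask, center, rMax) {
  theta <- (0:359) * pi / 180
  radii <- numeric(360)
  m <- mask * 1
  for (j in 1:360) {
    r <- seq_len(rMax)
    rr <- center[1L] - r * sin(theta[j])
    cc <- center[2L] + r * cos(theta[j])
    v <- bilinearSample(m, rr, cc)
    out <- which(v < 0.5)
    radii[j] <- if (length(out) == 0L) rMax else max(out[1L] - 1L, 1L)
  }
  radii
}

#' Extend a droplet radially beyond its boundary
#'
#' Converts the cropped segmented droplet to polar form about its mask
#' centroid (radial sampling 1 px, angular 1 degree, 360 columns) and, for
#' each angular column, replaces the 13 radial pixels beyond the droplet
#' boundary (half the 25 px filter support + 1) with the median intensity
#' of the ten boundary-adjacent pixels inside the droplet. The median
#' resists outliers from imperfect segmentation. The extended polar image
#' is mapped back to Cartesian space, giving every original edge pixel a
#' plausible neighbourhood for filtering, while the added ring itself is
#' flagged for exclusion from the final histogram.
#'
#' @param droplet numeric grey matrix containing the droplet.
#' @param boundary a [DropletBoundary-class] object (its mask defines the
#'   droplet).
#' @param pad number of radial pixels to add per column (default 13).
#' @param inner number of boundary-adjacent pixels whose median fills the
#'   pad (default 10).
#' @return list with \code{image} (cropped, padded Cartesian image),
#'   \code{dropletMask} (original droplet pixels in the crop),
#'   \code{exclusionMask} (the added ring), \code{polar} (the padded polar
#'   image, (R + pad) rows x 360 columns, radius increasing down rows),
#'   \code{polarRadii} (boundary radius per degree in the crop frame) and
#'   \code{center} (polar origin in crop coordinates).
#' @export
extendBoundary <- function(droplet, boundary, pad = 13L, inner = 10L) {
  stopifnot(is(boundary, "DropletBoundary"))
  mask <- boundary@mask
  if (!any(mask)) stop("boundary mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  margin <- pad + 3L
  r0 <- max(min(idx[, 1L]) - margin, 1L)
  r1 <- min(max(idx[, 1L]) + margin, nrow(droplet))
  c0 <- max(min(idx[, 2L]) - margin, 1L)
  c1 <- min(max(idx[, 2L]) + margin, ncol(droplet))
  crop <- droplet[r0:r1, c0:c1]
  cmask <- mask[r0:r1, c0:c1]
  props <- maskShapeProperties(cmask)
  ctr <- props$centroid
  # R: half the larger dimension of the segmented droplet's bounding box
  bb <- which(cmask, arr.ind = TRUE)
  R <- ceiling(max(diff(range(bb[, 1L])), diff(range(bb[, 2L])), 2) / 2)
  radii <- maskRadiiByDegree(cmask, ctr, R)

  theta <- (0:359) * pi / 180
  nR <- R + pad
  rr <- outer(seq_len(nR), -sin(theta))   # row offsets, nR x 360
  cc <- outer(seq_len(nR), cos(theta))
  polar <- matrix(bilinearSample(crop, ctr[1L] + rr, ctr[2L] + cc),
                  nR, 360L)
  medians <- numeric(360)
  for (j in 1:360) {
    rb <- radii[j]
    lo <- max(rb - inner + 1L, 1L)
    medians[j] <- stats::median(polar[lo:rb, j])
    polar[(rb + 1L):(rb + pad), j] <- medians[j]
  }

  # back to Cartesian: fill ring pixels (r in (rb, rb + pad]) with the
  # median of their (nearest) angular column
  n <- nrow(crop); m <- ncol(crop)
  pr <- matrix(seq_len(n), n, m) - ctr[1L]
  pc <- matrix(seq_len(m), n, m, byrow = TRUE) - ctr[2L]
  rad <- sqrt(pr^2 + pc^2)
  ang <- (round(atan2(-pr, pc) * 180 / pi) %% 360) + 1L
  rb <- radii[ang]
  ring <- !cmask & rad > rb & rad <= rb + pad
  out <- crop
  out[ring] <- medians[ang[ring]]
  list(image = out, dropletMask = cmask, exclusionMask = ring,
       polar = polar, polarRadii = radii, center = ctr,
       offset = c(r0, c0), pad = as.integer(pad))
}

#' Normalise intensities and downscale to the working resolution
#'
#' Z-scores the droplet region (mean 0, standard deviation 1 over the
#' droplet plus its extension ring) for intensity invariance, then
#' downscales image and mask bilinearly by \code{scale} to match the
#' resolution at which the texton dictionary was built (default 0.25;
#' imagers with different native resolution use a different factor, e.g.
#' 0.5, to approach the same effective resolution of roughly 4.5 um per
#' pixel).
#'
#' @param image numeric grey matrix (e.g. the padded droplet crop).
#' @param mask logical matrix of droplet pixels eligible for histogram
#'   counting (the extension ring is excluded here already).
#' @param scale downscale factor in (0, 1\] (default 0.25).
#' @param normMask optional logical matrix over which the z-score moments
#'   are computed (default: whole image).
#' @return a [ProcessedDroplet-class] object.
#' @export
normalizeAndScale <- function(image, mask, scale = 0.25,
                              normMask = NULL) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  region <- if (is.null(normMask)) rep(TRUE, length(image)) else normMask
  mu <- mean(image[region]); sd <- stats::sd(image[region])
  z <- if (is.finite(sd) && sd > 0) (image - mu) / sd else image * 0
  newDim <- pmax(round(dim(image) * scale), 1L)
  img <- EBImage::resize(z, w = newDim[1L], h = newDim[2L])
  msk <- EBImage::resize(mask * 1, w = newDim[1L], h = newDim[2L]) >= 0.5
  new("ProcessedDroplet", image = img, validMask = msk, scale = scale)
}
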