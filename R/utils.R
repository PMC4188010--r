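#' Read a droplet image as a grey matrix
#'
#' Reads a PNG or TIFF image and returns a numeric matrix of grey values in
#' 0-255. Colour images are converted to luminance (Rec. 601 weights) before
#' any contrast adjustment.
#'
#' @param path path to a .png, .tif or .tiff file.
#' @return numeric matrix (rows x cols) of intensities in \[0, 255\].
#' @seealso [toGreyFullRange()]
#' @export
readDropletImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    img <- if (nc >= 3L)
      0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    else img[, , 1L]
  }
  img * 255
}

#' Write a grey matrix as a PNG image
#'
#' @param image numeric matrix of intensities in \[0, 255\].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeDropletImage <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

## Pad a matrix by mirror reflection (no edge duplication), width w on each
## side. Requires w < min(dim).
reflectPad <- function(x, w) {
  n <- nrow(x); m <- ncol(x)
  stopifnot(w < n, w < m)
  ri <- c((w + 1L):2L, 1L:n, (n - 1L):(n - w))
  ci <- c((w + 1L):2L, 1L:m, (m - 1L):(m - w))
  x[ri, ci]
}

## Correlation of image with kernel (odd square), reflected borders,
## output same size. EBImage::filter2 uses FFT; borders are made explicit
## by mirror padding so its circular wrap never touches real pixels.
convolveReflect <- function(image, kernel) {
  w <- (nrow(kernel) - 1L) %/% 2L
  pad <- reflectPad(image, w)
  out <- EBImage::filter2(pad, kernel, boundary = "circular")
  out[(w + 1L):(w + nrow(image)), (w + 1L):(w + ncol(image)), drop = FALSE]
}

## Gradient magnitude by central differences (edges by one-sided diff).
gradientMagnitude <- function(image) {
  n <- nrow(image); m <- ncol(image)
  gx <- image; gy <- image
  gy[] <- (image[pmin(seq_len(n) + 1L, n), ] -
           image[pmax(seq_len(n) - 1L, 1L), ]) / 2
  gx[] <- (image[, pmin(seq_len(m) + 1L, m)] -
           image[, pmax(seq_len(m) - 1L, 1L)]) / 2
  sqrt(gx^2 + gy^2)
}

## Bilinear sampling of matrix `img` at fractional (row, col) positions.
## Positions outside the image are clamped to the border.
bilinearSample <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r <- pmin(pmax(r, 1), n)
  c <- pmin(pmax(c, 1), m)
  r0 <- pmin(floor(r), n - 1L); c0 <- pmin(floor(c), m - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * n + r0
  v00 <- img[i00];       v10 <- img[i00 + 1]
  v01 <- img[i00 + n];   v11 <- img[i00 + n + 1]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

## Shape descriptors from a binary mask via second central moments
## (ellipse-equivalent). Centroid is (row, col) in image coordinates.
maskShapeProperties <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  if (area == 0L)
    return(list(area = 0L, centroid = c(NA_real_, NA_real_),
                eccentricity = 0, majorAxis = 0, minorAxis = 0))
  mu <- colMeans(idx)
  r <- idx[, 1L] - mu[1L]; c <- idx[, 2L] - mu[2L]
  # 1/12 term: second moment of a unit square pixel
  mrr <- mean(r^2) + 1 / 12; mcc <- mean(c^2) + 1 / 12; mrc <- mean(r * c)
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2
  l2 <- (mrr + mcc - common) / 2
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
  list(area = area, centroid = unname(mu), eccentricity = ecc,
       majorAxis = major, minorAxis = minor)
}

## Disk mask helper: TRUE where (row - cr)^2 + (col - cc)^2 <= rad^2.
diskMask <- function(nrow, ncol, cr, cc, rad) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc2 <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rr - cr)^2 + (cc2 - cc)^2 <= rad^2
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
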