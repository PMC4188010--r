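test_that("contrast stretch maps any image onto the full 0-255 range", {
  img <- matrix(seq(50, 150, length.out = 100), 10)
  out <- toGreyFullRange(img)
  expect_equal(range(out), c(0, 255))
  # already full range -> unchanged
  full <- matrix(c(0, 255, 100, 30), 2)
  expect_equal(toGreyFullRange(full), full)
  # constant image degenerates to zero
  expect_equal(toGreyFullRange(matrix(7, 4, 4)), matrix(0, 4, 4))
  # colour input: luminance then stretch
  col <- array(runif(48, 0.2, 0.6), c(4, 4, 3))
  out2 <- toGreyFullRange(col)
  expect_equal(dim(out2), c(4L, 4L))
  expect_equal(range(out2), c(0, 255))
})

test_that("gamma correction boosts dark rims, fixes bright regions, stays monotone", {
  bright <- matrix(255, 30, 30)
  expect_equal(gammaCorrect(bright), bright, tolerance = 1e-9)
  # dark-rim disk: rim mean increases, centre barely moves
  n <- 101
  d <- sqrt((row(matrix(0, n, n)) - 51)^2 + (col(matrix(0, n, n)) - 51)^2)
  img <- matrix(240, n, n)
  img[d > 35 & d <= 42] <- 70
  out <- gammaCorrect(img)
  rim <- d > 35 & d <= 42
  centre <- d <= 20
  expect_gt(mean(out[rim]), mean(img[rim]))
  expect_lt(max(abs(out[centre] - img[centre])), 2)
  # range preserved on arbitrary input
  set.seed(6)
  noisy <- matrix(runif(900, 0, 255), 30)
  o1 <- gammaCorrect(noisy)
  expect_true(all(o1 >= 0 & o1 <= 255))
  expect_error(gammaCorrect(noisy, sigma = 0), "positive")
})

test_that("boundary extension pads exactly 13 radial pixels with the inner median", {
  n <- 201
  mask <- get("diskMask", asNamespace("dropRank"))(n, n, 101, 101, 70)
  img <- matrix(180, n, n)
  img[!mask] <- 60
  b <- maskToBoundary(mask)
  ext <- extendBoundary(img, b)
  expect_equal(ncol(ext$polar), 360L)
  expect_equal(ext$pad, 13L)
  # polar rows: R (half the larger droplet dimension) + 13 pad rows
  idxm <- which(mask, arr.ind = TRUE)
  R <- ceiling(max(diff(range(idxm[, 1])), diff(range(idxm[, 2]))) / 2)
  expect_equal(nrow(ext$polar), R + 13L)
  # constant disk: the pad equals the constant within interpolation error
  for (j in seq(1, 360, by = 30)) {
    rb <- ext$polarRadii[j]
    expect_lt(max(abs(ext$polar[(rb + 1):(rb + 13), j] - 180)), 1)
  }
  # Cartesian ring: 13 px thick, filled with the column medians
  ring <- ext$exclusionMask
  expect_true(any(ring))
  expect_lt(max(abs(ext$image[ring] - 180)), 1)
  # ring pixels all lie within (r, r + 13 + 1] of the centroid
  idx <- which(ring, arr.ind = TRUE)
  rr <- sqrt((idx[, 1] - ext$center[1])^2 + (idx[, 2] - ext$center[2])^2)
  expect_true(all(rr > 69 & rr <= 70 + 14))
  # the droplet itself is untouched
  expect_equal(ext$image[ext$dropletMask], img[mask])
})

test_that("edge crystals stop leaking into boundary labels once extended", {
  # crystal touching the droplet boundary: without extension the strong
  # droplet edge dominates the labels of boundary-adjacent pixels
  n <- 161
  mask <- get("diskMask", asNamespace("dropRank"))(n, n, 81, 81, 60)
  img <- matrix(170, n, n); img[!mask] <- 40
  d <- sqrt((row(img) - 81)^2 + (col(img) - 81)^2)
  img[d <= 60 & d > 50 & abs(row(img) - 81) < 4] <- 250  # edge needle
  b <- maskToBoundary(mask)
  ext <- extendBoundary(img, b)
  # same crop geometry without the extension ring (original dark exterior)
  nr <- nrow(ext$image); nc <- ncol(ext$image)
  raw <- img[ext$offset[1] + seq_len(nr) - 1L,
             ext$offset[2] + seq_len(nc) - 1L]
  pdExt <- normalizeAndScale(ext$image, ext$dropletMask, scale = 0.5)
  pdRaw <- normalizeAndScale(raw, ext$dropletMask, scale = 0.5)
  labExt <- labelPixels(applyFilterBank(pdExt@image, sharedBank),
                        sharedSmallDict, pdExt@validMask)
  labRaw <- labelPixels(applyFilterBank(pdRaw@image, sharedBank),
                        sharedSmallDict, pdRaw@validMask)
  common <- !is.na(labExt) & !is.na(labRaw)
  expect_gt(sum(labExt[common] != labRaw[common]), 0)
})

test_that("normalisation gives mean 0 / sd 1 and scaling shrinks dims", {
  set.seed(9)
  img <- matrix(runif(400 * 400, 10, 240), 400)
  mask <- matrix(TRUE, 400, 400)
  pd <- normalizeAndScale(img, mask, scale = 0.25)
  expect_s4_class(pd, "ProcessedDroplet")
  expect_equal(dim(pd@image), c(100L, 100L))
  expect_equal(dim(pd@validMask), c(100L, 100L))
  # the z-score happens before scaling: verify on an unscaled run
  pd1 <- normalizeAndScale(img, mask, scale = 1)
  expect_lt(abs(mean(pd1@image)), 1e-6)
  expect_lt(abs(sd(pd1@image) - 1), 1e-6)
  # affine intensity invariance
  pd2 <- normalizeAndScale(3.7 * img + 21, mask, scale = 0.25)
  expect_equal(pd2@image, pd@image, tolerance = 1e-9)
  expect_error(normalizeAndScale(img, mask, scale = 0), "scale")
})
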