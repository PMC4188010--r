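tinyDict <- function(K = 5L, seed = 1L) {
  set.seed(seed)
  ctr <- matrix(rnorm(K * 8), K)
  first <- which.min(sqrt(rowSums(ctr^2)))
  ctr <- ctr[order(sqrt(colSums((t(ctr) - ctr[first, ])^2))), ,
             drop = FALSE]
  new("TextonDictionary", centers = ctr,
      source = rep("precipitate", K), lambda = 0.5)
}

test_that("pixels are labelled with their nearest texton (brute-force oracle)", {
  dict <- tinyDict(7)
  set.seed(3)
  resp <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  labels <- labelPixels(resp, dict)
  # exhaustive nearest-neighbour scan, pixel by pixel
  for (i in seq_len(16)) for (j in seq_len(16)) {
    d <- sqrt(colSums((t(textonCenters(dict)) - resp[i, j, ])^2))
    expect_identical(labels[i, j], which.min(d))
  }
})

test_that("exact matches, ties and masks are handled in labelling", {
  dict <- tinyDict(4)
  resp <- array(0, c(3, 3, 8))
  resp[2, 2, ] <- textonCenters(dict)[3, ]
  lab <- labelPixels(resp, dict)
  expect_identical(lab[2, 2], 3L)
  # equidistant pixel -> lowest index wins
  two <- new("TextonDictionary",
             centers = rbind(rep(0, 8), rep(2, 8)),
             source = rep("precipitate", 2), lambda = 0.5)
  mid <- array(1, c(2, 2, 8))
  expect_true(all(labelPixels(mid, two) == 1L))
  # masked pixels stay unlabelled and never reach the histogram
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
  lab2 <- labelPixels(mid, two, mask)
  expect_identical(is.na(lab2), !mask)
  expect_equal(sum(textonHistogram(lab2, 2)), 2L)
})

test_that("filter-border pixels are excluded from labelling", {
  dict <- tinyDict(3)
  resp <- applyFilterBank(matrix(runif(60 * 60, 0, 255), 60), sharedBank)
  lab <- labelPixels(resp, dict)
  b <- attr(resp, "border")
  expect_true(all(is.na(lab[seq_len(b), ])))
  expect_true(all(is.na(lab[, seq_len(b)])))
  expect_true(all(!is.na(lab[(b + 1):(60 - b), (b + 1):(60 - b)])))
})

test_that("histogram conserves the labelled pixel count", {
  dict <- tinyDict(6)
  set.seed(8)
  resp <- array(rnorm(20 * 20 * 8), c(20, 20, 8))
  mask <- matrix(runif(400) > 0.4, 20)
  lab <- labelPixels(resp, dict, mask)
  h <- textonHistogram(lab, 6)
  expect_length(h, 6L)
  expect_equal(sum(h), sum(mask))
  expect_equal(attr(h, "nPixels"), sum(mask))
  # empty mask -> zero histogram
  h0 <- textonHistogram(labelPixels(resp, dict, mask & FALSE), 6)
  expect_equal(sum(h0), 0L)
  # uniform map
  m <- matrix(2L, 10, 10)
  expect_equal(textonHistogram(m, 4)[2], 100L, ignore_attr = TRUE)
})

test_that("chi-squared distance: closed form, identity, symmetry, range", {
  expect_equal(chi2Distance(c(1, 0), c(0, 1)), 1)
  expect_equal(chi2Distance(c(3, 1), c(3, 1)), 0)
  # scale invariance through normalisation
  expect_equal(chi2Distance(c(2, 6), c(1, 3)), 0)
  set.seed(5)
  for (i in 1:20) {
    x <- rpois(30, 5); y <- rpois(30, 5)
    d <- chi2Distance(x, y)
    expect_equal(d, chi2Distance(y, x))
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
  expect_error(chi2Distance(1:3, 1:4), "equal length")
})

test_that("Ward clustering under the chi-squared distance splits distinct textures", {
  dict <- sharedSmallDict
  hs <- list(); truth <- integer(0)
  for (s in 1:4) {
    for (cl in c("precipitate", "crystal")) {
      patch <- makeTexturePatch(cl, size = 96, seed = 20 + s)
      z <- (patch - mean(patch)) / sd(patch)
      resp <- applyFilterBank(z, sharedBank)
      h <- textonHistogram(labelPixels(resp, dict), nTextons(dict))
      hs[[length(hs) + 1L]] <- as.numeric(h)
      truth <- c(truth, match(cl, c("precipitate", "crystal")))
    }
  }
  H <- do.call(rbind, hs)
  lab <- wardCluster(H, 2L)
  # perfect split up to label swap
  expect_equal(length(unique(lab[truth == 1])), 1L)
  expect_equal(length(unique(lab[truth == 2])), 1L)
  expect_false(lab[1] == lab[2])
  # permutation invariance of the induced partition
  perm <- sample(nrow(H))
  lab2 <- wardCluster(H[perm, ], 2L)
  agree <- outer(lab2, lab2, "==") == outer(lab[perm], lab[perm], "==")
  expect_true(all(agree))
  # n clusters = n items -> singletons
  labn <- wardCluster(H, nrow(H))
  expect_equal(sort(unique(labn)), seq_len(nrow(H)))
  expect_error(wardCluster(H, nrow(H) + 1L), "exceed")
})
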