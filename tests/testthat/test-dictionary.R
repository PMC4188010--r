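microTrainingSet <- function(nPrec = 4L, nCrys = 2L, seed0 = 3100L) {
  prec <- lapply(seq_len(nPrec), function(i)
    generateWell(fixtureSpec(c("precipitate", "clear")[1 + i %% 2],
                             seed = seed0 + i)))
  crys <- lapply(seq_len(nCrys), function(i)
    generateWell(fixtureSpec("crystal", seed = seed0 + 50 + i)))
  list(precImgs = lapply(prec, `[[`, "image"),
       precMasks = lapply(prec, function(w) w$truth$dropletMask),
       crysImgs = lapply(crys, `[[`, "image"),
       crysMasks = lapply(crys, function(w) w$truth$crystalMask),
       crysDrops = lapply(crys, function(w) w$truth$dropletMask))
}

test_that("two-stage dictionary build is reproducible and well-formed", {
  ts <- microTrainingSet()
  build <- function() buildDictionary(
    ts$precImgs, ts$crysImgs, ts$crysMasks, lambda = 0.5,
    bank = sharedBank, precipitateMasks = ts$precMasks,
    crystalDropletMasks = ts$crysDrops, seed = 11L)
  d1 <- build()
  d2 <- build()
  expect_identical(textonCenters(d1), textonCenters(d2))
  expect_s4_class(d1, "TextonDictionary")
  expect_gt(nTextons(d1), 1L)
  expect_true(all(textonSource(d1) %in% c("precipitate", "crystal")))
  expect_true(any(textonSource(d1) == "crystal"))
  # entry-1 distance ordering is non-decreasing
  ctr <- textonCenters(d1)
  dist1 <- sqrt(colSums((t(ctr) - ctr[1, ])^2))
  expect_false(is.unsorted(dist1))
})

test_that("duplicated training images do not inflate the dictionary", {
  ts <- microTrainingSet(nPrec = 2L, nCrys = 1L)
  d1 <- buildDictionary(ts$precImgs, ts$crysImgs, ts$crysMasks,
                        lambda = 0.5, bank = sharedBank,
                        precipitateMasks = ts$precMasks,
                        crystalDropletMasks = ts$crysDrops, seed = 2L)
  # duplicate every image (with its own stage-1 seed, as in a real run
  # over a duplicated directory): stage 2 must remove the redundancy
  d2 <- buildDictionary(c(ts$precImgs, ts$precImgs),
                        c(ts$crysImgs, ts$crysImgs),
                        c(ts$crysMasks, ts$crysMasks),
                        lambda = 0.5, bank = sharedBank,
                        precipitateMasks = c(ts$precMasks, ts$precMasks),
                        crystalDropletMasks = c(ts$crysDrops, ts$crysDrops),
                        seed = 2L)
  expect_equal(nTextons(d2), nTextons(d1))
  expect_equal(textonCenters(d2), textonCenters(d1), tolerance = 1e-12)
})

test_that("size calibration lands the dictionary on the exact target", {
  expect_equal(nTextons(sharedSmallDict), 60L)
  expect_equal(table(textonSource(sharedSmallDict))[["crystal"]] > 0, TRUE)
})

test_that("a crystal-free crystal set degrades to a precipitate-only dictionary", {
  ts <- microTrainingSet(nPrec = 2L, nCrys = 1L)
  emptyMask <- list(ts$crysMasks[[1]] & FALSE)
  expect_warning(
    d <- buildDictionary(ts$precImgs, ts$crysImgs, emptyMask,
                         lambda = 0.5, bank = sharedBank,
                         precipitateMasks = ts$precMasks,
                         crystalDropletMasks = ts$crysDrops, seed = 4L),
    "precipitate-only")
  expect_true(all(textonSource(d) == "precipitate"))
})

test_that("the shipped reference dictionary has 300 ordered entries", {
  d <- referenceDictionary()
  expect_equal(nTextons(d), 300L)
  expect_equal(ncol(textonCenters(d)), 8L)
  ctr <- textonCenters(d)
  dist1 <- sqrt(colSums((t(ctr) - ctr[1, ])^2))
  expect_false(is.unsorted(dist1))
  expect_true(all(textonSource(d) %in% c("precipitate", "crystal")))
})

test_that("dictionary files round-trip through the tabular format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTextonDictionary(sharedSmallDict, path)
  d2 <- readTextonDictionary(path)
  expect_equal(textonCenters(d2), textonCenters(sharedSmallDict),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(textonSource(d2), textonSource(sharedSmallDict))
  expect_equal(d2@lambda, sharedSmallDict@lambda)
})
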