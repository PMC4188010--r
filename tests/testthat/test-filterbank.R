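test_that("bank composition: 38 kernels, 18+18 oriented, 2 symmetric", {
  bank <- sharedBank
  expect_s4_class(bank, "FilterBank")
  expect_length(filterKernels(bank), 38L)
  info <- filterInfo(bank)
  expect_equal(sum(info$kind == "edge"), 18L)
  expect_equal(sum(info$kind == "bar"), 18L)
  expect_equal(sum(info$kind == "gaussian"), 1L)
  expect_equal(sum(info$kind == "log"), 1L)
  # 6 orientations x 3 scales for each oriented family
  for (kind in c("edge", "bar")) {
    sub <- info[info$kind == kind, ]
    expect_equal(as.vector(table(sub$scale)), rep(6L, 3L))
    expect_equal(as.vector(table(sub$orientation)), rep(3L, 6L))
  }
  # kernel count holds for other scale factors too
  expect_length(filterKernels(makeFilterBank(1)), 38L)
})

test_that("kernel normalisation: zero-mean L1 for edge/bar/LoG, unit-sum Gaussian", {
  k <- filterKernels(sharedBank)
  info <- filterInfo(sharedBank)
  zeroMean <- info$kind != "gaussian"
  sums <- vapply(k, sum, numeric(1))
  expect_lt(max(abs(sums[zeroMean])), 1e-12)
  expect_equal(sums[[37L]], 1, tolerance = 1e-12)
  l1 <- vapply(k, function(x) sum(abs(x)), numeric(1))
  expect_equal(unname(l1[zeroMean]), rep(1, 37L), tolerance = 1e-12)
  # all kernels share one odd square support (25 at the default half scale)
  dims <- vapply(k, function(x) dim(x), integer(2))
  expect_true(all(dims == 25L))
})

test_that("non-positive scale factor is rejected", {
  expect_error(makeFilterBank(0), "positive")
  expect_error(makeFilterBank(-1), "positive")
})

test_that("responses collapse to 8 channels; constant image gives zero response", {
  img <- matrix(137, 40, 40)
  resp <- applyFilterBank(img, sharedBank)
  expect_equal(dim(resp), c(40L, 40L, 8L))
  # zero-mean kernels: edge, bar and LoG channels vanish on a constant
  expect_lt(max(abs(resp[, , c(1:6, 8)])), 1e-10)
  # the Gaussian (unit-sum) channel reproduces the constant
  expect_equal(as.vector(resp[, , 7L]), rep(137, 1600L), tolerance = 1e-10)
  expect_error(applyFilterBank(matrix(0, 10, 10), sharedBank), "support")
})

test_that("max-collapse dominance: collapsed channels equal one per-orientation response", {
  img <- makeTexturePatch("precipitate", size = 48, seed = 2)
  resp <- applyFilterBank(img, sharedBank)
  info <- filterInfo(sharedBank)
  conv <- get("convolveReflect", asNamespace("dropRank"))
  for (s in 1:3) {
    for (kind in c("edge", "bar")) {
      idx <- which(info$kind == kind & info$scale == s)
      all6 <- vapply(idx, function(i)
        conv(img, filterKernels(sharedBank)[[i]]), matrix(0, 48, 48))
      chan <- resp[, , (if (kind == "edge") 0L else 3L) + s]
      # each collapsed value matches an orientation response (in
      # magnitude for edge, signed for bar) at that pixel
      target <- if (kind == "edge") abs(all6) else all6
      hit <- apply(abs(target - as.vector(chan)) < 1e-9, c(1, 2), any)
      expect_true(all(hit))
      # and it has the maximal magnitude over orientations
      expect_equal(abs(chan), apply(abs(all6), c(1, 2), max),
                   tolerance = 1e-9)
    }
  }
})

test_that("channel histograms are stable under 30-degree rotation", {
  patch <- makeTexturePatch("precipitate", size = 120, seed = 4)
  rot <- EBImage::rotate(patch, 30, output.dim = c(120, 120),
                         bg.col = mean(patch))
  r0 <- applyFilterBank(patch, sharedBank)
  r1 <- applyFilterBank(as.matrix(rot), sharedBank)
  # compare response distributions over a central disk untouched by
  # rotation borders
  centre <- get("diskMask", asNamespace("dropRank"))(120, 120, 60.5, 60.5, 35)
  for (ch in c(1:6, 8L)) {
    a <- r0[, , ch][centre]
    b <- r1[, , ch][centre]
    brks <- stats::quantile(c(a, b), seq(0, 1, length.out = 11))
    brks[1] <- -Inf; brks[11] <- Inf
    ha <- tabulate(cut(a, brks, labels = FALSE), 10)
    hb <- tabulate(cut(b, brks, labels = FALSE), 10)
    expect_lt(chi2Distance(ha, hb), 0.05)
  }
})

test_that("filter bank serialises to one row per kernel", {
  tab <- filterBankTable(sharedBank)
  expect_equal(nrow(tab), 38L)
  expect_equal(ncol(tab), 5L + 25L^2)
  expect_equal(unname(unlist(tab[1, paste0("v", 1:625)])),
               as.vector(filterKernels(sharedBank)[[1]]))
})
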