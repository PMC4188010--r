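## small descriptor corpus over ground-truth masks (segmentation is
## exercised elsewhere; here the ranking machinery is under test)
rankCorpus <- function(classes, seed0) {
  H <- matrix(0, length(classes), nTextons(sharedSmallDict))
  for (i in seq_along(classes)) {
    w <- generateWell(fixtureSpec(classes[i], seed = seed0 + i))
    h <- dropletDescriptor(w$image, w$truth$dropletMask,
                           bank = sharedBank, dict = sharedSmallDict)
    H[i, ] <- as.numeric(h)
  }
  H
}

sharedRankTrain <- local({
  classes <- c(rep("crystal", 10), rep("microcrystal_shower", 4),
               rep("clear", 10), rep("precipitate", 8))
  list(H = rankCorpus(classes, 1200L),
       labels = ifelse(seq_along(classes) <= 14, "interesting",
                       "uninteresting"),
       classes = classes)
})

test_that("descriptor histograms have dictionary length and conserve pixels", {
  w <- generateWell(fixtureSpec("precipitate", seed = 1501))
  h <- dropletDescriptor(w$image, w$truth$dropletMask, bank = sharedBank,
                         dict = sharedSmallDict)
  expect_length(h, nTextons(sharedSmallDict))
  lab <- attr(h, "labels")
  expect_equal(sum(h), sum(!is.na(lab)))
  expect_equal(attr(h, "nPixels"), sum(h))
})

test_that("the ranker requires both classes and is seeded", {
  expect_error(trainRanker(sharedRankTrain$H,
                           rep("interesting", nrow(sharedRankTrain$H))),
               "both classes")
  m1 <- trainRanker(sharedRankTrain$H, sharedRankTrain$labels,
                    nTrees = 150L, seed = 3L)
  m2 <- trainRanker(sharedRankTrain$H, sharedRankTrain$labels,
                    nTrees = 150L, seed = 3L)
  expect_identical(scoreDroplets(m1, sharedRankTrain$H)$score,
                   scoreDroplets(m2, sharedRankTrain$H)$score)
})

test_that("crystal-class droplets score above clear droplets", {
  m <- trainRanker(sharedRankTrain$H, sharedRankTrain$labels,
                   nTrees = 200L, seed = 9L)
  testClasses <- c(rep("crystal", 5), rep("clear", 5))
  Ht <- rankCorpus(testClasses, 4300L)
  s <- scoreDroplets(m, Ht)$score
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(mean(s[1:5]), mean(s[6:10]))
  # rank order does not depend on presentation order
  perm <- sample(10)
  s2 <- scoreDroplets(m, Ht[perm, ])$score
  expect_equal(s2, s[perm], tolerance = 1e-12)
})

test_that("well-mode ranking takes the maximum over subwells", {
  sc <- data.frame(
    id = sprintf("i%02d", 1:6), plate = "P1",
    well = rep(1:2, each = 3), subwell = rep(c("a", "b", "c"), 2),
    score = c(0.2, 0.9, 0.4, 0.1, 0.3, 0.2))
  r <- rankPlate(sc, mode = "by_well")
  tab <- rankedScores(r)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$score, c(0.9, 0.3))
  expect_equal(tab$well, c(1L, 2L))
  # subwell mode ranks every droplet 1..n, descending score
  r2 <- rankPlate(sc, mode = "by_subwell")
  t2 <- rankedScores(r2)
  expect_equal(t2$rank, 1:6)
  expect_equal(t2$score, sort(sc$score, decreasing = TRUE))
  # deterministic tie-break by id
  tie <- sc; tie$score <- 0.5
  expect_equal(rankedScores(rankPlate(tie))$id, sort(tie$id))
})

test_that("profile summary matches a direct counting oracle and is monotone", {
  set.seed(77)
  plates <- sprintf("P%02d", 1:12)
  rows <- do.call(rbind, lapply(plates, function(p) {
    n <- 24
    data.frame(id = sprintf("%s_%02d", p, 1:n), plate = p,
               well = rep(1:8, each = 3), subwell = rep(c("a", "b", "c"), 8),
               score = runif(n))
  }))
  crystal <- setNames(runif(nrow(rows)) < 0.15, rows$id)
  rk <- rankPlate(rows)
  cutoffs <- c(0.8, 0.5, 0.2, 0.1, 0.05, 0.01)
  prof <- profileSummary(rk, cutoffs, labels = crystal)
  # direct counting oracle, computed independently of the ranking object
  for (i in seq_along(cutoffs)) {
    ct <- cutoffs[i]
    found <- mean(vapply(split(rows, rows$plate), function(p)
      any(crystal[p$id] & p$score > ct), logical(1)))
    unseen <- mean(vapply(split(rows, rows$plate), function(p) {
      un <- !crystal[p$id]
      mean(p$score[un] < ct)
    }, numeric(1)))
    expect_equal(prof$platesFound[i], found)
    expect_equal(prof$meanUnseenUninteresting[i], unseen)
  }
  # monotone trade-off along the decreasing cutoff grid
  expect_true(all(diff(prof$platesFound) >= 0))
  expect_true(all(diff(prof$meanUnseenUninteresting) <= 0))
  # degenerate cutoffs
  ext <- profileSummary(rk, c(0, 1), labels = crystal)
  expect_equal(ext$platesFound[1], 1)
  expect_equal(ext$meanUnseenUninteresting[1], 0)
  expect_equal(ext$platesFound[2], 0)
  expect_equal(ext$meanUnseenUninteresting[2], 1)
})

test_that("human score labels map at the >= 3 threshold", {
  lab <- labelsFromScores(c(1, 2, 3, 5, 10, NA))
  expect_equal(as.character(lab),
               c("uninteresting", "uninteresting", "interesting",
                 "interesting", "interesting", "uninteresting"))
})
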