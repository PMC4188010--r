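#' Train the droplet ranking forest
#'
#' Fits a seeded two-class random forest (500 trees by default) on raw
#' texton histogram counts with "interesting" (crystals or crystalline
#' behaviour) versus "uninteresting" labels. The forest is never used to
#' classify: its posterior probability for the interesting class becomes
#' the droplet score. In the original labelling protocol, human scores of
#' 3 and above map to interesting; lower or missing scores map to
#' uninteresting ([labelsFromScores()]).
#'
#' @param histograms numeric matrix, one texton histogram per row.
#' @param labels factor or character with levels \code{"uninteresting"}
#'   and \code{"interesting"} (both must occur).
#' @param nTrees number of trees (default 500).
#' @param seed RNG seed; training is deterministic given the seed.
#' @return a [TextonRanker-class] object.
#' @seealso [scoreDroplets()], [rankerCrossValidate()]
#' @export
trainRanker <- function(histograms, labels, nTrees = 500L, seed = 1L) {
  histograms <- as.matrix(histograms)
  labels <- factor(labels, levels = c("uninteresting", "interesting"))
  if (any(is.na(labels)))
    stop("labels must be 'uninteresting' or 'interesting'")
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present in the training labels")
  colnames(histograms) <- paste0("t", seq_len(ncol(histograms)))
  rf <- withr::with_seed(seed,
    randomForest::randomForest(x = as.data.frame(histograms), y = labels,
                               ntree = nTrees))
  new("TextonRanker", forest = rf,
      classes = c("uninteresting", "interesting"),
      nTextons = ncol(histograms), seed = as.integer(seed))
}

#' Map human droplet scores to ranking labels
#'
#' Integer scores of 3 and above (microcrystals and mountable crystals)
#' are "interesting"; scores below 3 and unscored droplets (\code{NA})
#' are "uninteresting".
#'
#' @param scores integer vector of human labels (1-10) with \code{NA} for
#'   unscored droplets.
#' @return factor with levels \code{"uninteresting"},
#'   \code{"interesting"}.
#' @export
labelsFromScores <- function(scores) {
  factor(ifelse(!is.na(scores) & scores >= 3, "interesting",
                "uninteresting"),
         levels = c("uninteresting", "interesting"))
}

#' Score droplets with the ranking forest
#'
#' Returns the posterior probability of the interesting class for each
#' droplet: 1 means likely to contain crystals or crystalline behaviour,
#' 0 means uninteresting. No threshold is applied; the scores are meant
#' to be used directly as a ranking key.
#'
#' @param model a [TextonRanker-class] object.
#' @param histograms numeric matrix of texton histograms (one per row).
#' @param manifest optional data.frame with columns \code{id},
#'   \code{plate}, \code{well}, \code{subwell} parallel to the histogram
#'   rows.
#' @return data.frame with manifest columns (or a generated \code{id})
#'   plus \code{score} in \[0, 1\].
#' @export
scoreDroplets <- function(model, histograms, manifest = NULL) {
  stopifnot(is(model, "TextonRanker"))
  histograms <- as.matrix(histograms)
  if (ncol(histograms) != model@nTextons)
    stop("histogram length does not match the model (",
         model@nTextons, " textons)")
  colnames(histograms) <- paste0("t", seq_len(ncol(histograms)))
  p <- stats::predict(model@forest, as.data.frame(histograms),
                      type = "prob")[, "interesting"]
  if (is.null(manifest))
    manifest <- data.frame(id = sprintf("img%04d", seq_len(nrow(histograms))),
                           plate = "plate1", well = seq_len(nrow(histograms)),
                           subwell = "a", stringsAsFactors = FALSE)
  cbind(manifest, score = as.numeric(p))
}

#' Rank droplets or wells by score
#'
#' Sorts by descending posterior score (ties broken by id for a stable,
#' reproducible viewing order). In \code{by_well} mode the subwells of a
#' well are aggregated by their maximum score, since the subwells share
#' the same chemistry and one crystalline subwell makes the whole well
#' worth viewing.
#'
#' @param scores data.frame from [scoreDroplets()] (columns \code{id},
#'   \code{plate}, \code{well}, \code{subwell}, \code{score}).
#' @param mode \code{"by_subwell"} (default) or \code{"by_well"}.
#' @return a [PlateRanking-class] object.
#' @export
rankPlate <- function(scores, mode = c("by_subwell", "by_well")) {
  mode <- match.arg(mode)
  s <- scores
  if (mode == "by_well") {
    sp <- split(s, interaction(s$plate, s$well, drop = TRUE))
    s <- do.call(rbind, lapply(sp, function(g) {
      top <- g[which.max(g$score), , drop = FALSE]
      top$subwell <- NA_character_
      top
    }))
    rownames(s) <- NULL
  }
  ord <- order(-s$score, s$id)
  s <- s[ord, , drop = FALSE]
  s$rank <- seq_len(nrow(s))
  rownames(s) <- NULL
  new("PlateRanking", scores = s[, c("id", "plate", "well", "subwell",
                                     "score", "rank")], mode = mode)
}

#' Cutoff trade-off profile over ranked plates
#'
#' For each score cutoff, reports the fraction of plates in which at
#' least one labelled crystal droplet scores above the cutoff (crystals
#' "found" when only images above the cutoff are inspected) and the mean
#' per-plate fraction of uninteresting droplets scoring below it (work
#' saved). When labels are supplied the per-plate rank of the first
#' labelled crystal is attached as attribute \code{firstCrystalRank}.
#'
#' @param ranking a [PlateRanking-class] object.
#' @param cutoffs numeric vector of score cutoffs (default
#'   \code{c(0.8, 0.5, 0.2, 0.1, 0.05, 0.01)}).
#' @param labels optional named logical vector (names = unit ids, TRUE =
#'   labelled crystal).
#' @return data.frame with columns \code{cutoff}, \code{platesFound}
#'   (fraction in \[0, 1\]; \code{NA} without labels) and
#'   \code{meanUnseenUninteresting} (fraction in \[0, 1\]).
#' @export
profileSummary <- function(ranking,
                           cutoffs = c(0.8, 0.5, 0.2, 0.1, 0.05, 0.01),
                           labels = NULL) {
  stopifnot(is(ranking, "PlateRanking"))
  s <- rankedScores(ranking)
  plates <- split(s, s$plate)
  isCrystal <- if (is.null(labels)) NULL else labels[s$id]
  out <- lapply(cutoffs, function(ct) {
    found <- NA_real_
    if (!is.null(labels)) {
      found <- mean(vapply(plates, function(p) {
        cr <- labels[p$id]
        any(cr & p$score > ct)
      }, logical(1)))
    }
    unseen <- mean(vapply(plates, function(p) {
      un <- if (is.null(labels)) rep(TRUE, nrow(p)) else !labels[p$id]
      if (!any(un)) return(NA_real_)
      mean(p$score[un] < ct)
    }, numeric(1)), na.rm = TRUE)
    data.frame(cutoff = ct, platesFound = found,
               meanUnseenUninteresting = unseen)
  })
  res <- do.call(rbind, out)
  if (!is.null(labels)) {
    fcr <- vapply(plates, function(p) {
      cr <- labels[p$id]
      if (!any(cr)) NA_real_ else min(p$rank[cr])
    }, numeric(1))
    # ranks are global over all plates; recompute within plate
    fcrWithin <- vapply(plates, function(p) {
      cr <- labels[p$id]
      if (!any(cr)) return(NA_real_)
      ord <- order(-p$score, p$id)
      min(which(cr[ord]))
    }, numeric(1))
    attr(res, "firstCrystalRank") <- fcrWithin
  }
  res
}

#' Cross-validate the ranking forest
#'
#' K-fold cross-validation reporting the area under the ROC curve
#' (computed from the rank statistic of the held-out scores) and the
#' accuracy at a 0.5 cutoff.
#'
#' @param histograms numeric matrix of texton histograms.
#' @param labels labels as for [trainRanker()].
#' @param nFolds number of folds (default 10).
#' @param nTrees trees per fold (default 500).
#' @param seed RNG seed for fold assignment and training.
#' @return list with \code{auc}, \code{accuracy}, and the per-droplet
#'   held-out \code{scores}.
#' @export
rankerCrossValidate <- function(histograms, labels, nFolds = 10L,
                                nTrees = 500L, seed = 1L) {
  histograms <- as.matrix(histograms)
  labels <- factor(labels, levels = c("uninteresting", "interesting"))
  n <- nrow(histograms)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(nFolds), n)))
  scores <- numeric(n)
  for (f in seq_len(nFolds)) {
    test <- folds == f
    model <- trainRanker(histograms[!test, , drop = FALSE], labels[!test],
                         nTrees = nTrees, seed = seed + f)
    scores[test] <- scoreDroplets(model,
                                  histograms[test, , drop = FALSE])$score
  }
  pos <- scores[labels == "interesting"]
  neg <- scores[labels == "uninteresting"]
  # Mann-Whitney form of the AUC, ties counted half
  auc <- (sum(rank(c(pos, neg))[seq_along(pos)]) -
            length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  acc <- mean((scores >= 0.5) == (labels == "interesting"))
  list(auc = auc, accuracy = acc, scores = scores)
}
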