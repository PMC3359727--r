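# Recursive regression partition tree over the six-feature vector, the 0-6
# diffraction-score scale, interpretation bands and rule-mapped suggestions.

#' Map a crystallization outcome to the 0--6 diffraction score
#'
#' Ordinal outcome scale: 0 no crystals; 1 crystals but no diffraction;
#' 2 diffraction worse than 10.00 A; 3 10.00--4.01 A; 4 4.00--2.81 A;
#' 5 2.80--2.01 A; 6 2.00 A or better.  Each printed range includes its
#' endpoints, so the boundaries map as 10.00 -> 3, 4.00 -> 4, 2.80 -> 5,
#' 2.00 -> 6.
#'
#' @param outcome `"no_crystals"`, `"no_diffraction"`, or the best
#'   diffraction resolution in Angstrom (numeric > 0).
#' @return integer score 0--6.
#' @examples
#' resolutionToScore("no_crystals")  # 0
#' resolutionToScore(3.5)            # 4
#' @export
resolutionToScore <- function(outcome) {
  if (is.character(outcome)) {
    return(switch(outcome,
                  no_crystals = 0L,
                  no_diffraction = 1L,
                  stop("unknown outcome '", outcome, "'")))
  }
  res <- as.numeric(outcome)
  stopifnot(res > 0)
  if (res <= 2.00) 6L
  else if (res <= 2.80) 5L
  else if (res <= 4.00) 4L
  else if (res <= 10.00) 3L
  else 2L
}

#' Interpretation band for a mean diffraction score
#'
#' @param meanScore predicted mean score.
#' @param bands data.frame with columns `min` and `text`; the highest band
#'   whose `min` does not exceed `meanScore` applies.
#' @return interpretation text.
#' @export
interpretScore <- function(meanScore, bands = defaultScoreBands()) {
  bands <- bands[order(bands$min), ]
  hit <- max(which(bands$min <= meanScore))
  bands$text[hit]
}

#' @rdname interpretScore
#' @export
defaultScoreBands <- function() {
  data.frame(
    min = c(-Inf, 1, 2.5, 4.5),
    text = c("not likely to form crystals",
             "may form crystals; diffraction quality uncertain",
             "likely to form crystals; diffraction may need optimization",
             "likely to form crystals with diffraction of 2.8 Å or better"),
    stringsAsFactors = FALSE)
}

scoreHistogram <- function(scores) {
  h <- tabulate(as.integer(round(scores)) + 1L, nbins = 7L)
  names(h) <- as.character(0:6)
  h
}

# --- training -------------------------------------------------------------

nodeOf <- function(y) {
  list(leaf = TRUE, mean = mean(y), n = length(y),
       train_hist = as.list(scoreHistogram(y)),
       test_hist = as.list(setNames(rep(0L, 7L), as.character(0:6))))
}

# Best split of (x, y) on one feature: thresholds at midpoints between
# adjacent observed values; missing x routed to the child with more
# observed samples (ties to the left).  Returns NULL when no split leaves
# both children with >= minLeaf samples and positive gain.
bestSplitOneFeature <- function(x, y, minLeaf) {
  obs <- which(!is.na(x))
  if (length(obs) < 2L) return(NULL)
  vals <- sort(unique(x[obs]))
  if (length(vals) < 2L) return(NULL)
  thresholds <- (vals[-1] + vals[-length(vals)]) / 2
  sse <- function(v) if (length(v) <= 1L) 0 else sum((v - mean(v))^2)
  parentSse <- sse(y)
  best <- NULL
  for (thr in thresholds) {
    leftObs <- !is.na(x) & x <= thr
    rightObs <- !is.na(x) & x > thr
    missTo <- if (sum(leftObs) >= sum(rightObs)) "left" else "right"
    left <- leftObs | (is.na(x) & missTo == "left")
    right <- rightObs | (is.na(x) & missTo == "right")
    if (sum(left) < minLeaf || sum(right) < minLeaf) next
    gain <- parentSse - sse(y[left]) - sse(y[right])
    if (is.null(best) || gain > best$gain + 1e-12)
      best <- list(threshold = thr, gain = gain, missTo = missTo,
                   left = left, right = right)
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

growNode <- function(X, y, depth, params) {
  node <- nodeOf(y)
  if (length(y) < 2L * params$minLeaf || depth >= params$maxDepth ||
      length(unique(y)) == 1L)
    return(node)
  best <- NULL
  for (feat in colnames(X)) {
    cand <- bestSplitOneFeature(X[[feat]], y, params$minLeaf)
    if (!is.null(cand) &&
        (is.null(best) || cand$gain > best$gain + 1e-12))
      best <- c(cand, list(feature = feat))
  }
  if (is.null(best)) return(node)
  node$leaf <- FALSE
  node$feature <- best$feature
  node$threshold <- best$threshold
  node$missing <- best$missTo
  node$left <- growNode(X[best$left, , drop = FALSE], y[best$left],
                        depth + 1L, params)
  node$right <- growNode(X[best$right, , drop = FALSE], y[best$right],
                         depth + 1L, params)
  node
}

#' Train a recursive regression partition tree
#'
#' CART-style greedy binary splitting: each split maximizes the reduction in
#' the sum of squared deviations of the diffraction scores, with candidate
#' thresholds at midpoints between adjacent observed feature values.
#' Splitting stops at `minLeaf` samples per child, `maxDepth`, or zero gain.
#' Missing feature values are routed to the child holding more observed
#' samples; the route is stored per node and reused at prediction time.
#'
#' @param cohort data.frame with the six feature columns (`r_dsf`, `yield`,
#'   `r_sec`, `p_maj`, `mw_mono`, `l_dis`; `NA` = missing) and a `score`
#'   column of 0--6 outcomes.
#' @param minLeaf minimum training samples per leaf.
#' @param maxDepth maximum tree depth.
#' @param features feature columns the tree may split on.
#' @return a [RegressionTree-class].
#' @export
trainTree <- function(cohort, minLeaf = 5L, maxDepth = 5L,
                      features = intersect(FEATURE_NAMES, colnames(cohort))) {
  stopifnot("score" %in% colnames(cohort))
  y <- as.numeric(cohort$score)
  if (length(y) < 1L) stop("empty training cohort")
  X <- cohort[, features, drop = FALSE]
  params <- list(minLeaf = as.integer(minLeaf), maxDepth = as.integer(maxDepth))
  root <- growNode(X, y, 0L, params)
  new("RegressionTree", root = root, params = params, features = features)
}

# --- prediction -----------------------------------------------------------

routeVector <- function(node, v, path = NULL) {
  if (is.null(path))
    path <- data.frame(feature = character(0), threshold = numeric(0),
                       direction = character(0), favorable = logical(0),
                       imputed = logical(0))
  if (isTRUE(node$leaf)) return(list(node = node, path = path))
  x <- v[node$feature]
  imputed <- is.na(x)
  goLeft <- if (imputed) node$missing == "left" else x <= node$threshold
  child <- if (goLeft) node$left else node$right
  other <- if (goLeft) node$right else node$left
  favorable <- if (abs(child$mean - other$mean) < 1e-12) NA
               else child$mean > other$mean
  path <- rbind(path, data.frame(
    feature = node$feature, threshold = node$threshold,
    direction = if (goLeft) "le" else "gt", favorable = favorable,
    imputed = imputed))
  routeVector(child, v, path)
}

#' Predict the crystallization outcome for a sample
#'
#' Routes a feature vector down the tree and reports the mean diffraction
#' score of the co-routed training samples, the interpretation band, the
#' training (and test, when attached) outcome histograms at the leaf, and
#' the decision path.  Each path step is marked favorable when the taken
#' branch has the higher child mean, unfavorable when lower, neutral (`NA`)
#' on ties; steps taken via the stored missing-route are flagged `imputed`.
#'
#' @param tree a [RegressionTree-class].
#' @param fv a [FeatureVector-class] (or named numeric vector); `mw_mono`
#'   must be present, other features may be missing.
#' @param bands interpretation bands, see [interpretScore()].
#' @param ... unused.
#' @return a [CrystalPrediction-class].
#' @export
setMethod("predictOutcome", "RegressionTree",
          function(tree, fv, bands = defaultScoreBands(), ...) {
  v <- if (is(fv, "FeatureVector")) fv@values else fv
  if (!"mw_mono" %in% names(v) || is.na(v["mw_mono"]))
    stop("mw_mono is required for prediction")
  r <- routeVector(tree@root, v)
  leaf <- r$node
  new("CrystalPrediction",
      meanScore = leaf$mean,
      interpretation = interpretScore(leaf$mean, bands),
      trainHist = unlist(leaf$train_hist),
      testHist = unlist(leaf$test_hist),
      path = r$path, leafN = as.integer(leaf$n))
})

#' Attach test-set outcome histograms to a tree
#'
#' Routes an independent test cohort through a trained tree and stores the
#' per-leaf outcome histograms, so predictions can display both training and
#' test distributions.
#'
#' @param tree a [RegressionTree-class].
#' @param cohort data.frame with feature columns and `score`.
#' @return the tree with `test_hist` filled in at every leaf.
#' @export
attachTestCohort <- function(tree, cohort) {
  addOne <- function(node, v, score) {
    if (isTRUE(node$leaf)) {
      h <- unlist(node$test_hist)
      h <- h + scoreHistogram(score)
      node$test_hist <- as.list(h)
      return(node)
    }
    x <- v[node$feature]
    goLeft <- if (is.na(x)) node$missing == "left" else x <= node$threshold
    if (goLeft) node$left <- addOne(node$left, v, score)
    else node$right <- addOne(node$right, v, score)
    node
  }
  for (i in seq_len(nrow(cohort))) {
    v <- unlist(cohort[i, tree@features, drop = TRUE])
    tree@root <- addOne(tree@root, v, cohort$score[i])
  }
  tree
}

# --- suggestions ----------------------------------------------------------

#' Default advice catalog for unfavorable decision-path splits
#'
#' @return named list mapping feature name to advice text.
#' @export
defaultAdvice <- function() {
  list(
    l_dis = paste("Truncate the construct to remove predicted disordered",
                  "regions; removal of predicted disorder is an obvious",
                  "first step."),
    r_dsf = paste("Screen buffers, additives or ligands to stabilize the",
                  "fold (high initial fluorescence suggests exposed",
                  "hydrophobic surface)."),
    yield = paste("Modify expression and purification protocols to improve",
                  "the yield (alternative vectors, tags, hosts or",
                  "conditions)."),
    r_sec = paste("Modify purification to improve the SEC profile toward a",
                  "single symmetric peak (polishing steps, buffer",
                  "optimization)."),
    p_maj = paste("Reduce aggregation/polydispersity before crystallization",
                  "(buffer screening, additives, removing aggregates by",
                  "SEC)."),
    mw_mono = paste("Consider alternative construct boundaries or domain",
                    "truncations to adjust the crystallizable unit."))
}

#' Suggestions for moving a sample to a better category
#'
#' For every unfavorable split on the decision path, emits the advice
#' configured for that feature.  When the sample already falls in a
#' top-scoring leaf but no crystals have been obtained yet, the single
#' suggestion is instead a pointer to additional crystallization screens
#' and high-throughput screening facilities.
#'
#' @param pred a [CrystalPrediction-class].
#' @param noCrystalsYet set `TRUE` when the sample has not yet crystallized
#'   despite a favorable prediction.
#' @param advice advice catalog, see [defaultAdvice()].
#' @param topScore leaf mean at or above which a sample counts as
#'   top-category.
#' @return character vector of advice items (possibly empty).
#' @export
crystallizationSuggestions <- function(pred, noCrystalsYet = FALSE,
                                       advice = defaultAdvice(),
                                       topScore = 4.5) {
  stopifnot(is(pred, "CrystalPrediction"))
  if (pred@meanScore >= topScore && noCrystalsYet) {
    return(paste("Promising sample with no crystals yet: try additional",
                 "crystallization screens and high-throughput screening",
                 "facilities."))
  }
  bad <- pred@path$feature[!is.na(pred@path$favorable) &
                           !pred@path$favorable]
  unlist(advice[unique(bad)], use.names = FALSE)
}

# --- JSON tree definitions ------------------------------------------------

#' Write / read a tree definition as JSON
#'
#' The JSON mirrors the node list: internal nodes carry `feature`,
#' `threshold`, `missing` (`"left"`/`"right"`), `mean`, `n` and `left`/
#' `right` children; leaves carry `leaf: true`, `mean`, `n`, `train_hist`
#' and `test_hist` (counts over scores 0--6).  This lets a published tree be
#' encoded verbatim and run through [predictOutcome()].
#'
#' @param tree a [RegressionTree-class]. @param path JSON file.
#' @return `readTreeJson` returns the [RegressionTree-class].
#' @export
writeTreeJson <- function(tree, path) {
  obj <- list(format = "crystalcast_tree", version = 1,
              params = tree@params, features = as.list(tree@features),
              root = tree@root)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTreeJson
#' @export
readTreeJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "crystalcast_tree"))
    stop("not a tree definition file")
  fixNode <- function(n) {
    n$leaf <- isTRUE(n$leaf)
    n$mean <- as.numeric(n$mean)
    n$n <- as.integer(n$n)
    if (!n$leaf) {
      n$threshold <- as.numeric(n$threshold)
      n$left <- fixNode(n$left)
      n$right <- fixNode(n$right)
    }
    n
  }
  new("RegressionTree", root = fixNode(obj$root),
      params = lapply(obj$params, as.integer),
      features = unlist(obj$features))
}

collectLeaves <- function(node) {
  if (isTRUE(node$leaf)) return(list(node))
  c(collectLeaves(node$left), collectLeaves(node$right))
}

setMethod("meanScore", "CrystalPrediction", function(x) x@meanScore)

setMethod("predictionPath", "CrystalPrediction", function(x) x@path)

setMethod("show", "RegressionTree", function(object) {
  depth <- function(n) if (isTRUE(n$leaf)) 0L
                       else 1L + max(depth(n$left), depth(n$right))
  leaves <- collectLeaves(object@root)
  cat(sprintf("RegressionTree: %d leaves, depth %d (minLeaf %d, maxDepth %d)\n",
              length(leaves), depth(object@root), object@params$minLeaf,
              object@params$maxDepth))
  printNode <- function(n, indent) {
    pad <- strrep("  ", indent)
    if (isTRUE(n$leaf)) {
      cat(sprintf("%sleaf: mean %.3g (n = %d)\n", pad, n$mean, n$n))
    } else {
      cat(sprintf("%s%s <= %.6g (missing -> %s)\n", pad, n$feature,
                  n$threshold, n$missing))
      printNode(n$left, indent + 1L)
      printNode(n$right, indent + 1L)
    }
  }
  printNode(object@root, 1L)
})

setMethod("show", "CrystalPrediction", function(object) {
  cat(sprintf("CrystalPrediction: mean diffraction score %.3g (n = %d)\n",
              object@meanScore, object@leafN))
  cat(sprintf("  %s\n", object@interpretation))
  cat("  outcome histogram (train):",
      paste(sprintf("%d:%d", 0:6, object@trainHist), collapse = " "), "\n")
  if (sum(object@testHist) > 0)
    cat("  outcome histogram (test): ",
        paste(sprintf("%d:%d", 0:6, object@testHist), collapse = " "), "\n")
  p <- object@path
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s %s %.6g [%s]%s\n", p$feature[i],
                if (p$direction[i] == "le") "<=" else ">", p$threshold[i],
                if (is.na(p$favorable[i])) "neutral"
                else if (p$favorable[i]) "favorable" else "unfavorable",
                if (p$imputed[i]) " (missing value, majority route)" else ""))
})
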