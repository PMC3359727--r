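# Regression partition tree: score binning, training, prediction,
# suggestions, JSON definitions.

test_that("diffraction-score binning matches the outcome scale exactly", {
  expect_identical(resolutionToScore("no_crystals"), 0L)
  expect_identical(resolutionToScore("no_diffraction"), 1L)
  expect_identical(resolutionToScore(15), 2L)
  expect_identical(resolutionToScore(7), 3L)
  expect_identical(resolutionToScore(3.5), 4L)
  expect_identical(resolutionToScore(2.5), 5L)
  expect_identical(resolutionToScore(1.8), 6L)
  # Printed ranges include their endpoints.
  expect_identical(resolutionToScore(10.00), 3L)
  expect_identical(resolutionToScore(4.01), 3L)
  expect_identical(resolutionToScore(4.00), 4L)
  expect_identical(resolutionToScore(2.81), 4L)
  expect_identical(resolutionToScore(2.80), 5L)
  expect_identical(resolutionToScore(2.01), 5L)
  expect_identical(resolutionToScore(2.00), 6L)
  expect_identical(resolutionToScore(10.01), 2L)
  expect_error(resolutionToScore("maybe"), "unknown outcome")
})

test_that("a planted single-split rule is recovered with zero training
           error", {
  co <- makePlantedCohort(n = 60, threshold = 40, sigma = 0)
  tree <- trainTree(co)
  expect_identical(tree@root$feature, "l_dis")
  # Threshold between the straddling observed values.
  lo <- max(co$l_dis[co$l_dis <= 40])
  hi <- min(co$l_dis[co$l_dis > 40])
  expect_gt(tree@root$threshold, lo)
  expect_lt(tree@root$threshold, hi)
  # Training MSE 0.
  preds <- vapply(seq_len(nrow(co)), function(i)
    meanScore(predictOutcome(tree, unlist(co[i, 1:6]))), numeric(1))
  expect_equal(preds, as.numeric(co$score))
})

test_that("stopping rules: constant outcomes and tiny cohorts give a
           single leaf", {
  co <- makePlantedCohort(n = 30)
  co$score <- 4
  t1 <- trainTree(co)
  expect_true(t1@root$leaf)
  expect_equal(t1@root$mean, 4)
  co2 <- makePlantedCohort(n = 8)[1:2, ]
  t2 <- trainTree(co2, minLeaf = 5)
  expect_true(t2@root$leaf)
})

test_that("every leaf mean equals the mean of its routed training
           outcomes exactly", {
  for (seed in 1:5) {
    co <- makePlantedCohort(n = 80, sigma = 1, seed = seed)
    tree <- trainTree(co, minLeaf = 4, maxDepth = 4)
    means <- vapply(seq_len(nrow(co)), function(i)
      routeOracle(tree@root, unlist(co[i, 1:6])), numeric(1))
    # Group rows by leaf mean and verify against the routed outcomes.
    for (m in unique(means)) {
      expect_equal(m, mean(co$score[means == m]), tolerance = 1e-12)
    }
    # Histogram totals equal routed counts.
    leaves <- CrystalCast:::collectLeaves(tree@root)
    for (lf in leaves)
      expect_identical(sum(unlist(lf$train_hist)), lf$n)
  }
})

test_that("chosen splits match exhaustive brute-force search on small
           single-feature cohorts", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    x <- round(runif(n, 0, 10), 1)
    y <- sample(0:6, n, replace = TRUE)
    co <- data.frame(l_dis = x, score = y)
    tree <- trainTree(co, minLeaf = 1L, maxDepth = 1L,
                      features = "l_dis")
    oracle <- bruteBestSplit(x, y, minLeaf = 1L)
    if (is.null(oracle) || oracle$gain <= 1e-12) {
      expect_true(tree@root$leaf)
    } else {
      expect_false(tree@root$leaf)
      # Same gain as the exhaustive optimum; same threshold when unique.
      sse <- function(v) sum((v - mean(v))^2)
      thr <- tree@root$threshold
      gain <- sse(y) - sse(y[x <= thr]) - sse(y[x > thr])
      expect_equal(gain, oracle$gain, tolerance = 1e-9)
    }
  }
})

test_that("planted thresholds are recovered from noisy cohorts", {
  hits <- 0L
  for (seed in 1:20) {
    co <- makePlantedCohort(n = 100, threshold = 40, sigma = 0.5,
                            seed = seed)
    tree <- trainTree(co)
    lo <- max(co$l_dis[co$l_dis <= 40])
    hi <- min(co$l_dis[co$l_dis > 40])
    if (!tree@root$leaf && tree@root$feature == "l_dis" &&
        tree@root$threshold > lo && tree@root$threshold < hi)
      hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("prediction is invariant to training-cohort permutation and
           missing features follow the stored majority route", {
  co <- makePlantedCohort(n = 60, sigma = 0.5, seed = 3)
  t1 <- trainTree(co)
  set.seed(4)
  t2 <- trainTree(co[sample(nrow(co)), ])
  fv <- featureVector(mw_mono = 40000, l_dis = 10, r_dsf = 0.2,
                      yield = 3, r_sec = 0.1, p_maj = 0.9)
  expect_equal(meanScore(predictOutcome(t1, fv)),
               meanScore(predictOutcome(t2, fv)))
  # Missing feature at the root split: routed to the majority child,
  # flagged as imputed, deterministically.
  fvMiss <- featureVector(mw_mono = 40000)
  p1 <- predictOutcome(t1, fvMiss)
  p2 <- predictOutcome(t1, fvMiss)
  expect_identical(meanScore(p1), meanScore(p2))
  expect_true(predictionPath(p1)$imputed[1])
  expect_identical(predictionPath(p1)$direction[1],
                   if (t1@root$missing == "left") "le" else "gt")
  # mw_mono is mandatory.
  expect_error(predictOutcome(t1, featureVector(l_dis = 5)), "mw_mono")
})

test_that("leaf histograms and mean reflect mixed outcomes", {
  # Force a leaf with outcomes {0, 0, 6}: single feature, one clean split.
  co <- data.frame(l_dis = c(5, 8, 11, 80, 85, 90),
                   score = c(0, 0, 6, 5, 5, 5))
  co$mw_mono <- 40000
  tree <- trainTree(co, minLeaf = 3L, maxDepth = 1L, features = "l_dis")
  pred <- predictOutcome(tree, featureVector(mw_mono = 40000, l_dis = 6))
  expect_equal(meanScore(pred), 2)
  expect_equal(unname(pred@trainHist[c("0", "6")]), c(2, 1))
  expect_identical(pred@leafN, 3L)
  # Single-leaf tree: empty path, global mean.
  lone <- trainTree(co[1:3, ], minLeaf = 5L)
  pl <- predictOutcome(lone, featureVector(mw_mono = 40000))
  expect_identical(nrow(predictionPath(pl)), 0L)
  expect_equal(meanScore(pl), 2)
})

test_that("interpretation bands and suggestions follow the decision path", {
  expect_match(interpretScore(0.4), "not likely")
  expect_match(interpretScore(4.9), "2.8")
  co <- makePlantedCohort(n = 60, sigma = 0, seed = 5)
  tree <- trainTree(co)
  # Disordered sample: unfavorable l_dis split yields truncation advice.
  bad <- predictOutcome(tree, featureVector(mw_mono = 40000, l_dis = 120))
  expect_false(predictionPath(bad)$favorable[1])
  sug <- crystallizationSuggestions(bad)
  expect_true(any(grepl("disorder", sug, ignore.case = TRUE)))
  # Favorable path, no crystals yet: screening resources only.
  good <- predictOutcome(tree, featureVector(mw_mono = 40000, l_dis = 5))
  expect_gte(meanScore(good), 4.5)
  sugTop <- crystallizationSuggestions(good, noCrystalsYet = TRUE)
  expect_length(sugTop, 1)
  expect_match(sugTop, "screen")
  # Favorable path, crystals in hand: nothing to suggest.
  expect_length(crystallizationSuggestions(good), 0)
})

test_that("tree JSON definitions round-trip and predict identically", {
  d <- withr::local_tempdir()
  co <- makePlantedCohort(n = 60, sigma = 0.5, seed = 7)
  tree <- attachTestCohort(trainTree(co),
                           makePlantedCohort(n = 30, sigma = 0.5, seed = 8))
  f <- file.path(d, "tree.json")
  writeTreeJson(tree, f)
  back <- readTreeJson(f)
  fv <- featureVector(mw_mono = 40000, l_dis = 10, p_maj = 0.8)
  p1 <- predictOutcome(tree, fv)
  p2 <- predictOutcome(back, fv)
  expect_equal(meanScore(p1), meanScore(p2))
  expect_equal(predictionPath(p1), predictionPath(p2))
  expect_identical(p1@testHist, p2@testHist)
  expect_gt(sum(p1@testHist), 0)
  expect_error(readTreeJson(withr::local_tempfile(lines = "{}",
                                                  fileext = ".json")),
               "tree definition")
})

test_that("split choice agrees with an independent CART implementation", {
  skip_if_not_installed("rpart")
  set.seed(21)
  co <- makePlantedCohort(n = 80, threshold = 40, sigma = 0.5, seed = 12)
  tree <- trainTree(co, minLeaf = 10L, maxDepth = 1L, features = "l_dis")
  rp <- rpart::rpart(score ~ l_dis, data = co, method = "anova",
                     control = rpart::rpart.control(minbucket = 10,
                                                    maxdepth = 1, cp = 0,
                                                    minsplit = 2, xval = 0))
  rpThr <- rp$splits[1, "index"]
  expect_equal(tree@root$threshold, rpThr, tolerance = 1e-9)
})
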