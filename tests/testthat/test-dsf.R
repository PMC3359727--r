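# DSF: parsing dialects, truncation, Boltzmann fitting, r_dsf.

test_that("DSF parser reads comma and tab dialects with and without headers", {
  f <- tempfile(fileext = ".csv")
  temp <- seq(25, 95, by = 1)
  writeLines(c("Temp,A1", paste(temp, 100 + temp, sep = ",")), f)
  curves <- readDsfCsv(f)
  expect_length(curves, 1)
  expect_identical(curves[[1]]@wellLabel, "A1")
  expect_equal(curves[[1]]@temperature[1], 25 + 273.15)  # Celsius converted

  # 97-column tab-delimited plate file without a header: positional labels.
  plate <- tempfile()
  mat <- cbind(temp, matrix(rnorm(length(temp) * 96, 1000, 10),
                            ncol = 96))
  writeLines(apply(mat, 1, paste, collapse = "\t"), plate)
  curves <- readDsfCsv(plate)
  expect_length(curves, 96)
  expect_identical(curves[[1]]@wellLabel, "A1")
  expect_identical(curves[[13]]@wellLabel, "B1")
})

test_that("DSF parser rejects non-monotone temperature and ragged rows", {
  f <- tempfile()
  writeLines(c("Temp,A1", paste(c(25:40, 39, 41:60), 1:37, sep = ",")), f)
  expect_error(readDsfCsv(f), "strictly increasing")
  g <- tempfile()
  rows <- paste(25:44, 1:20, sep = ",")
  rows[7] <- "31,5,99"
  writeLines(c("Temp,A1", rows), g)
  expect_error(readDsfCsv(g), "line 8")
})

test_that("curve truncation stops at the smoothed post-transition maximum", {
  d <- withr::local_tempdir()
  g <- synthDsfCurve(d, seed = 2, noise = 0.005, decaySlope = 40)
  cv <- readDsfCsv(g$csv)[[1]]
  region <- truncateCurve(cv)
  onsetIdx <- which.min(abs(cv@temperature - g$record$decay_onset))
  expect_lte(abs(region[2] - onsetIdx), 2)
  # Monotone curve: full range.
  mono <- makeDsfCurve(noise = 0)
  expect_identical(truncateCurve(mono),
                   c(1L, length(mono@temperature)))
  # Flat curve: argmax ties break to the latest index, full range kept.
  flat <- dsfCurve(seq(293, 363, 0.5), rep(500, 141))
  expect_identical(truncateCurve(flat)[2], 141L)
})

test_that("noiseless Boltzmann fits recover parameters and closed forms", {
  cv <- makeDsfCurve(baseline = 200, tm = 323, s = 1.5, delta_f = 1000)
  fit <- fitBoltzmann(cv, 1)
  tr <- transitions(fit)
  expect_equal(tr$tm, 323, tolerance = 0.01 / 323)
  expect_equal(tr$s, 1.5, tolerance = 1e-4)
  expect_equal(tr$delta_f, 1000, tolerance = 1e-4)
  # Closed forms: max slope dF/(4s) and FWHM of dF/dT.
  expect_equal(tr$max_slope, 1000 / 6, tolerance = 1e-4)
  expect_equal(tr$fwhm, 5.288, tolerance = 1e-3)
  # Predictor values from the generating model.
  expect_equal(fit@fTm, 700, tolerance = 1e-4)
  expect_equal(fit@f30, 200, tolerance = 1e-3)
  expect_equal(rDsf(fit), 0.286, tolerance = 1e-2)
  # Refitting the model's own output is numerically exact.
  expect_lte(fit@rss, 1e-12 * sum(cv@fluorescence^2))
})

test_that("fwhm/s identity and fluorescence-rescale invariance hold on
           noisy fits", {
  for (seed in 1:6) {
    cv <- makeDsfCurve(noise = 0.01, seed = seed)
    fit <- fitBoltzmann(cv, 1)
    tr <- transitions(fit)
    expect_equal(tr$fwhm / tr$s, 2 * log(3 + 2 * sqrt(2)),
                 tolerance = 1e-9)
    expect_lt(abs(tr$tm - 323), 0.5)
    # r_dsf is invariant under uniform rescaling of the fluorescence axis.
    cv2 <- dsfCurve(cv@temperature, cv@fluorescence * 7.5)
    expect_equal(rDsf(fitBoltzmann(cv2, 1)), rDsf(fit), tolerance = 1e-6)
  }
})

test_that("transition-count selection finds the generative count", {
  one <- makeDsfCurve()
  expect_identical(selectTransitionCount(one), 1L)
  two <- makeDsfCurve(tm = c(318, 333), s = c(1.5, 1.5),
                      delta_f = c(800, 800), noise = 0.005, seed = 3)
  expect_identical(selectTransitionCount(two), 2L)
  set.seed(9)
  flatNoise <- dsfCurve(seq(293, 363, 0.5), rnorm(141, 1000, 5))
  expect_warning(kN <- selectTransitionCount(flatNoise), "no clear")
  expect_identical(kN, 1L)
})

test_that("over-parameterized fits are rejected and the major transition is
           overridable", {
  short <- dsfCurve(seq(300, 306, 0.5), seq(1, 13) * 10)
  expect_error(fitBoltzmann(short, 3), "too short")
  two <- makeDsfCurve(tm = c(318, 333), s = c(1.5, 3),
                      delta_f = c(800, 800))
  fit <- fitBoltzmann(two, 2)
  expect_identical(majorIndex(fit), 1L)    # steeper transition wins
  majorIndex(fit) <- 2L
  expect_equal(fit@fTm, dsfModel(fit, transitions(fit)$tm[2]))
  expect_equal(rDsf(fit), fit@f30 / fit@fTm)
})
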