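# SEC: fraction conversion, peak seeding, Gaussian fitting, purity, r_sec.

test_that("time-to-fraction conversion follows half-open 1-based intervals", {
  d <- withr::local_tempdir()
  g <- synthSecChromatogram(d, flowRate = 1, fractionSize = 2,
                            collectionStart = 10)
  chrom <- readSecAscii(g$curve, g$doc)
  fracAt <- function(t) {
    fractionIndex(1 + (t - 10) * 1 / 2)
  }
  expect_identical(fracAt(13), 2)     # 3 mL into collection
  expect_identical(fracAt(14), 3)     # 4 mL boundary opens fraction 3
  expect_identical(fracAt(9), 0)      # pre-collection
  expect_identical(fractionIndex(chrom)[1], 1)
})

test_that("missing run-log metadata is rejected by key name", {
  d <- withr::local_tempdir()
  g <- synthSecChromatogram(d)
  doc2 <- file.path(d, "broken_doc.asc")
  lines <- readLines(g$doc)
  writeLines(lines[!grepl("Fraction size", lines)], doc2)
  expect_error(readSecAscii(g$curve, doc2), "fraction size")
})

test_that("initial peak estimates find generative centers and ignore noise", {
  ch <- makeSecChrom(height = c(100, 60), center = c(20, 30),
                     width = c(2, 2), noise = 0.01, seed = 4)
  est <- initialPeakEstimates(ch)
  expect_gte(nrow(est), 2)
  expect_lt(min(abs(est$center - 20)), 1)
  expect_lt(min(abs(est$center - 30)), 1)
  # Flat baseline noise only: nothing above the noise floor.
  set.seed(5)
  flat <- secChromatogram(seq(1, 30, length.out = 200),
                          rnorm(200, 5, 0.5))
  expect_identical(nrow(initialPeakEstimates(flat)), 0L)
})

test_that("Gaussian fits recover noiseless and noisy mixtures", {
  ch <- makeSecChrom(height = 100, center = 20, width = 2)
  fit <- fitGaussians(ch, 1)
  comp <- components(fit)
  expect_equal(comp$height, 100, tolerance = 1e-6)
  expect_equal(comp$center, 20, tolerance = 1e-6)
  expect_equal(comp$width, 2, tolerance = 1e-6)
  expect_error(fitGaussians(secChromatogram(1:12, c(1:6, 6:1)), 5),
               "too few points")
  # Mixture RSS is nonincreasing in k on the same trace.
  noisy <- makeSecChrom(height = c(100, 50), center = c(20, 30),
                        width = c(2, 2), noise = 0.01, seed = 6)
  rss <- vapply(1:3, function(k) fitGaussians(noisy, k)@rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-6 * rss[1]))
})

test_that("pool purity matches a numeric-integration oracle", {
  ch <- makeSecChrom(height = c(100, 50), center = c(20, 30),
                     width = c(2, 2))
  fit <- analyzeSec(ch, k = 2, pool = c(16, 24))
  # Oracle: numeric integration of each generative component over the pool
  # interval [16, 25) in continuous fraction coordinates.
  gint <- function(h, c, w) {
    integrate(function(x) h * exp(-(x - c)^2 / (2 * w^2)), 16, 25,
              rel.tol = 1e-10)$value
  }
  main <- gint(100, 20, 2)
  other <- gint(50, 30, 2)
  expect_equal(purityPool(fit), 100 * main / (main + other),
               tolerance = 0.001 / 100)
  # Single-component fit: purity is 100 wherever the pool sits.
  lone <- analyzeSec(makeSecChrom(), k = 1, pool = c(16, 24))
  expect_equal(purityPool(lone), 100)
  # Pool centered on the minor component reports the minor component.
  gint2 <- function(h, c, w) {
    integrate(function(x) h * exp(-(x - c)^2 / (2 * w^2)), 28, 33,
              rel.tol = 1e-10)$value
  }
  expect_equal(poolPurity(fit, c(28, 32)),
               100 * gint2(50, 30, 2) /
                 (gint2(50, 30, 2) + gint2(100, 20, 2)),
               tolerance = 1e-4)
})

test_that("single-Gaussian residual matches direct RSS/TSS evaluation", {
  # Perfect single Gaussian: residual vanishes.
  expect_lte(singleGaussianResidual(makeSecChrom()), 1e-6)
  # Two equal Gaussians 10 fractions apart: substantially nonzero and equal
  # to an independently optimized single-Gaussian RSS over TSS.
  ch <- makeSecChrom(height = c(80, 80), center = c(15, 25),
                     width = c(2, 2))
  r <- singleGaussianResidual(ch)
  expect_gt(r, 0.05)
  obj <- function(p) {
    sum((ch@absorbance -
           p[1] * exp(-(ch@fraction - p[2])^2 / (2 * p[3]^2)))^2)
  }
  oracle <- optim(c(80, 20, 5), obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-14))$value
  tss <- sum((ch@absorbance - mean(ch@absorbance))^2)
  expect_equal(r, oracle / tss, tolerance = 1e-3)
  # With 1% noise the residual is close to the noise variance fraction.
  noisy <- makeSecChrom(noise = 0.01, seed = 8)
  truthRss <- sum((noisy@absorbance - makeSecChrom()@absorbance)^2)
  tssN <- sum((noisy@absorbance - mean(noisy@absorbance))^2)
  expect_equal(singleGaussianResidual(noisy), truthRss / tssN,
               tolerance = 0.3)
})

test_that("r_sec is scale invariant and degenerate traces report missing", {
  ch <- makeSecChrom(height = c(80, 80), center = c(15, 25),
                     width = c(2, 2))
  scaled <- secChromatogram(ch@fraction, ch@absorbance * 12.5)
  expect_equal(singleGaussianResidual(scaled), singleGaussianResidual(ch),
               tolerance = 1e-6)
  flat <- secChromatogram(seq(1, 20, length.out = 50), rep(3, 50))
  expect_true(is.na(singleGaussianResidual(flat)))
  # Zero mixture mass in the pool: purity undefined.
  fit <- analyzeSec(makeSecChrom(), k = 1)
  expect_true(is.na(poolPurity(fit, c(2000, 2010))))
})
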