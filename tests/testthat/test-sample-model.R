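# Sample container: aggregation by mean, feature assembly, XML round trips.

manualDsf <- function(tm, r_dsf = 0.3) {
  experimentSummary("dsf", c(tm = tm, r_dsf = r_dsf), provenance = "manual")
}

test_that("aggregation over selected results is the arithmetic mean", {
  res <- list(manualDsf(50, 0.2), manualDsf(54, 0.4))
  agg <- aggregateSelected(res, c(1L, 2L))
  expect_equal(summaryValues(agg)[["tm"]], 52)
  expect_equal(summaryValues(agg)[["r_dsf"]], 0.3)
  # One selected result: identity.
  one <- aggregateSelected(res, 2L)
  expect_identical(summaryValues(one), summaryValues(res[[2]]))
  # Empty selection: a missing marker, never zero.
  expect_null(aggregateSelected(res, integer(0)))
  # Permutation invariance.
  res3 <- list(manualDsf(48), manualDsf(51), manualDsf(57))
  a1 <- aggregateSelected(res3, c(1L, 2L, 3L))
  a2 <- aggregateSelected(res3, c(3L, 1L, 2L))
  expect_equal(summaryValues(a1), summaryValues(a2))
  # Mixed tags and bad indices are rejected.
  expect_error(aggregateSelected(list(manualDsf(50),
                                      experimentSummary("sec",
                                                        c(r_sec = 0.1),
                                                        "manual")),
                                 c(1L, 2L)), "mixed")
  expect_error(aggregateSelected(res, c(1L, 5L)), "out of range")
})

test_that("feature assembly takes sequence maxima and selected-result
           means, flagging missing experiments", {
  s1 <- sequenceRecord(strrep("A", 267), disorderCalls = c(rep(TRUE, 12),
                                                           rep(FALSE, 255)))
  s2 <- sequenceRecord(strrep("A", 445), disorderCalls = c(rep(TRUE, 25),
                                                           rep(FALSE, 420)))
  smp <- proteinSample("s", sequences = list(s1, s2))
  fv <- featureValues(assembleFeatureVector(smp))
  # Maximum MW and maximum disorder stretch over the sample's sequences.
  expect_equal(fv[["mw_mono"]], max(monomerMW(s1), monomerMW(s2)))
  expect_equal(fv[["l_dis"]], 25)
  expect_true(all(missingMask(assembleFeatureVector(smp))[
    c("r_dsf", "yield", "r_sec", "p_maj")]))

  smp <- addResult(smp, manualDsf(50, 0.25))
  smp <- addResult(smp, manualDsf(54, 0.35))
  smp <- addResult(smp, experimentSummary("yield", c(yield = 4), "manual"))
  smp <- addResult(smp, experimentSummary("sec", c(r_sec = 0.12), "manual"))
  fv2 <- featureValues(assembleFeatureVector(smp))
  expect_equal(fv2[["r_dsf"]], 0.3)     # mean of both selected results
  expect_equal(fv2[["yield"]], 4)
  expect_equal(fv2[["r_sec"]], 0.12)
  expect_true(is.na(fv2[["p_maj"]]))    # sample lacks DLS
  # Deselecting one DSF result changes the aggregate deterministically.
  smp <- selectResults(smp, "dsf", 1L)
  expect_equal(featureValues(assembleFeatureVector(smp))[["r_dsf"]], 0.25)
  # Assembly is deterministic.
  expect_identical(featureValues(assembleFeatureVector(smp)),
                   featureValues(assembleFeatureVector(smp)))
  # No sequence: rejection (monomer MW is mandatory).
  expect_error(assembleFeatureVector(proteinSample("empty")), "sequence")
})

test_that("standardized XML round-trips every payload type", {
  d <- withr::local_tempdir()
  roundtrip <- function(summary) {
    f <- file.path(d, paste0(typeTag(summary), ".xml"))
    writeStandardXml(summary, f)
    readStandardXml(f)
  }
  # DSF fit with two transitions, curve attached.
  cv <- makeDsfCurve(tm = c(318, 333), s = c(1.5, 2), delta_f = c(800, 600),
                     noise = 0.01, seed = 2)
  fit <- fitBoltzmann(cv, 2)
  back <- roundtrip(summarizeResult(fit))
  expect_equal(summaryValues(back), summaryValues(summarizeResult(fit)),
               tolerance = 1e-9)
  expect_equal(back@payload@transitions, fit@transitions, tolerance = 1e-9)
  expect_equal(back@payload@rDsf, fit@rDsf, tolerance = 1e-12)
  expect_equal(back@payload@curve@temperature, cv@temperature)
  expect_identical(back@payload@fitRegion, fit@fitRegion)
  # SEC fit.
  sfit <- analyzeSec(makeSecChrom(height = c(100, 50), center = c(20, 30),
                                  width = c(2, 2)), k = 2, pool = c(16, 24))
  sback <- roundtrip(summarizeResult(sfit))
  expect_equal(sback@payload@components, sfit@components, tolerance = 1e-9)
  expect_equal(sback@payload@purityPool, sfit@purityPool, tolerance = 1e-12)
  # DLS with histogram.
  dl <- synthDlsExport(d)
  dres <- readDlsExport(dl$path, monomerMW = 44000)
  dback <- roundtrip(summarizeResult(dres))
  expect_equal(dback@payload@peaks, dres@peaks, tolerance = 1e-12)
  expect_equal(dback@payload@pMaj, dres@pMaj, tolerance = 1e-12)
  expect_equal(dback@payload@histogram, dres@histogram, tolerance = 1e-12)
  # Yield, Lp, sequence.
  yback <- roundtrip(summarizeResult(yieldResult(massMg = 5,
                                                 cultureL = 0.5)))
  expect_equal(yback@payload@mgPerL, 10)
  lback <- roundtrip(summarizeResult(lpStability(c(5, 3),
                                                 c("trypsin", "GluC"))))
  expect_equal(lback@payload@stability, 4)
  expect_identical(lback@payload@perProtease$protease,
                   c("trypsin", "GluC"))
  rec <- sequenceRecord("MKTAYIAKQR", disorderCalls = rep(c(TRUE, FALSE), 5))
  qback <- roundtrip(summarizeResult(rec))
  expect_identical(qback@payload@residues, "MKTAYIAKQR")
  expect_identical(qback@payload@disorderCalls, rep(c(TRUE, FALSE), 5))
})

test_that("manual summaries serialize without payload and schema
           violations are named", {
  d <- withr::local_tempdir()
  f <- file.path(d, "manual.xml")
  writeStandardXml(manualDsf(52.5, 0.31), f)
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, ".//fit"), 0)
  back <- readStandardXml(f)
  expect_identical(back@provenance, "manual")
  expect_null(back@payload)
  expect_equal(summaryValues(back)[["r_dsf"]], 0.31)
  # Unknown experiment tag.
  badTag <- file.path(d, "badtag.xml")
  writeLines(c("<protchar_result type='nmr' version='1.0'>",
               "<analysis><value name='x'>1</value></analysis>",
               "</protchar_result>"), badTag)
  expect_error(readStandardXml(badTag), "unknown type 'nmr'")
  # Summary value outside the tag's schema.
  badVal <- file.path(d, "badval.xml")
  writeLines(c("<protchar_result type='dsf' version='1.0'>",
               "<analysis><value name='bogus'>1</value></analysis>",
               "</protchar_result>"), badVal)
  expect_error(readStandardXml(badVal), "bogus")
})

test_that("project manifests round-trip through JSON", {
  d <- withr::local_tempdir()
  manifest <- list(name = "kinases", description = "pilot set",
                   samples = list(list(name = "k1", description = "",
                                       fasta = "k1.fasta",
                                       results = list("dsf_A1.xml"))))
  p <- file.path(d, "project.json")
  writeProjectManifest(manifest, p)
  expect_equal(readProjectManifest(p), manifest)
})
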