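test_that("cohort generation is bit-identical for identical spec and seed", {
  spec <- cohortSpec(nSubjectsPerGroup = 1, channels = c("C3", "C4", "CP4"),
                     nTrials = 4, epochWindow = c(-1, 1.5), seed = 11,
                     plantedEdges = plantedEdge("C3", "C4", "beta", pi / 2,
                                               0.7, "post"),
                     erdEffects = erdEffect("CP4", "alpha", 0.6))
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(lapply(a, function(s) epochData(subjectEpochs(s))),
                   lapply(b, function(s) epochData(subjectEpochs(s))))
  expect_identical(vapply(a, ulFMA, 0), vapply(b, ulFMA, 0))
  ## a different seed changes the realization
  spec2 <- cohortSpec(nSubjectsPerGroup = 1, channels = c("C3", "C4", "CP4"),
                      nTrials = 4, epochWindow = c(-1, 1.5), seed = 12)
  expect_false(identical(epochData(subjectEpochs(generateCohort(spec2)[[1]])),
                         epochData(subjectEpochs(a[[1]]))))
})

test_that("invalid specs are rejected", {
  expect_error(cohortSpec(bands = data.frame(name = "bad", low = 30,
                                             high = 20)),
               "low < high")
  expect_error(cohortSpec(bands = data.frame(name = "bad", low = 10,
                                             high = 200)),
               "fs/2")
  expect_error(
    cohortSpec(channels = c("C3", "C4"),
               plantedEdges = plantedEdge("C3", "C4", "beta", pi / 2, 1.5)),
    "strength")
  expect_error(
    cohortSpec(channels = c("C3", "C4"),
               erdEffects = erdEffect("C3", "beta", -0.5)),
    "ratio")
  expect_error(
    cohortSpec(channels = c("C3", "C4"),
               plantedEdges = plantedEdge("C3", "Cz", "beta", 1, 0.5)),
    "montage")
})

test_that("null spec yields near-zero iCOH and ERD everywhere", {
  spec <- cohortSpec(nSubjectsPerGroup = 1,
                     channels = c("C3", "C4", "CP3", "CP4", "FC3", "FC4"),
                     nTrials = 100, epochWindow = c(-1, 1.5), seed = 21)
  e <- subjectEpochs(generateCohort(spec)[[1]])
  ic <- icohMatrices(e)
  ## estimation noise at 100 trials: per-pair band SE is roughly
  ## 1/sqrt(2 * trials * bins); the bounds sit at ~4 SE of the alpha band
  for (w in c("pre", "post")) for (b in c("alpha", "beta")) {
    expect_lt(max(abs(ic[[w]][[b]])), 0.12)
    expect_lt(mean(abs(ic[[w]][[b]])), 0.05)
  }
  em <- erd(e, c(13, 30))
  expect_lt(max(abs(em$erd)), 10)
})

test_that("planted ERD effect reproduces the requested power ratio", {
  spec <- cohortSpec(nSubjectsPerGroup = 1, channels = c("C3", "C4"),
                     nTrials = 40, epochWindow = c(-1, 1.5), seed = 4,
                     erdEffects = erdEffect("C4", "beta", 0.5),
                     subjectSD = 0, backgroundSD = 0.05,
                     commonSourceStrength = 0)
  e <- subjectEpochs(generateCohort(spec)[[1]])
  em <- erd(e, c(13, 30))
  ## post/pre power ratio ~ 0.5 on the planted channel -> ERD ~ -50%
  expect_lt(abs(em$erd[em$channel == "C4"] - (-50)), 5)
  expect_lt(abs(em$erd[em$channel == "C3"]), 10)
})

test_that("band power scales quadratically with source amplitude", {
  mk <- function(A) {
    spec <- cohortSpec(nSubjectsPerGroup = 1, channels = c("C3", "C4"),
                       nTrials = 20, epochWindow = c(-1, 1.5), seed = 31,
                       erdEffects = erdEffect("C4", "beta", 1),
                       subjectSD = 0, backgroundSD = 0.01,
                       commonSourceStrength = 0, sourceAmplitude = A)
    e <- subjectEpochs(generateCohort(spec)[[1]])
    em <- erd(e, c(13, 30))
    em$pre[em$channel == "C4"]
  }
  p1 <- mk(1); p2 <- mk(2)
  expect_lt(abs(p2 / p1 - 4), 0.2)
})

test_that("planted truth matches the outcome model and generated scores", {
  spec <- cohortSpec(nSubjectsPerGroup = 2, channels = c("C3", "C4", "CP4"),
                     nTrials = 2, epochWindow = c(-1, 1.5), seed = 41,
                     erdEffects = erdEffect("C4", "beta", 0.5),
                     outcomeIntercept = 20,
                     outcomeCoefficients = c("erd:C4:beta" = 40),
                     outcomeNoiseSD = 0)
  tr <- plantedTruth(spec)
  out <- attr(tr, "outcome")
  v <- tr$value[match(out$subject, tr$subject)]
  expect_equal(out$ulFMA_noiseless, 20 + 40 * v)
  ## zero noise: realized score equals the noise-free score (within [0,66])
  expect_equal(out$ulFMA, pmin(66, pmax(0, out$ulFMA_noiseless)))
  ## and the generated cohort carries exactly these scores
  co <- generateCohort(spec)
  expect_equal(vapply(co, ulFMA, 0),
               out$ulFMA[match(vapply(co, subjectId, ""), out$subject)])
})

test_that("empty planted list gives an empty truth table", {
  spec <- cohortSpec(nSubjectsPerGroup = 2, channels = c("C3", "C4"),
                     nTrials = 2, epochWindow = c(-1, 1.5), seed = 5)
  tr <- plantedTruth(spec)
  expect_equal(nrow(tr), 0)
  expect_equal(nrow(attr(tr, "outcome")), 4)
})

test_that("group-restricted plants only affect that group", {
  spec <- cohortSpec(nSubjectsPerGroup = 2, channels = c("C3", "C4"),
                     nTrials = 2, epochWindow = c(-1, 1.5), seed = 6,
                     plantedEdges = plantedEdge("C3", "C4", "beta", pi / 2,
                                               0.8, group = "stroke"))
  tr <- plantedTruth(spec)
  expect_true(all(tr$value[tr$group == "stroke"] > 0))
  expect_true(all(tr$value[tr$group == "control"] == 0))
})

test_that("cohort text round-trip preserves data and metadata", {
  spec <- cohortSpec(nSubjectsPerGroup = 1, channels = c("C3", "C4"),
                     nTrials = 3, epochWindow = c(-1, 1.5), seed = 7)
  co <- generateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_equal(subjectId(back[[1]]), subjectId(co[[1]]))
  expect_equal(ulFMA(back[[1]]), ulFMA(co[[1]]))
  expect_equal(epochData(subjectEpochs(back[[1]])),
               epochData(subjectEpochs(co[[1]])), tolerance = 1e-6,
               ignore_attr = TRUE)
})
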