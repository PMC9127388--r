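test_that("the default cohort has 305 valid baseline/follow-up pairs", {
  pairs <- generateCohort(cohortConfig(seed = 1))
  expect_length(pairs, 305L)
  tr <- cohortTruth(pairs)
  expect_equal(nrow(tr), 305L)
  expect_equal(length(unique(tr$patient_id)), 7L)
  # nesting and orientation hold for every contour (validity ran at
  # construction; spot-check the invariants directly on a few pairs)
  for (pr in pairs[c(1, 150, 305)]) {
    expect_true(all(pointsInPolygon(lumenContour(pr$baseline),
                                    eemContour(pr$baseline))))
    expect_true(isCCW(lumenContour(pr$followup)))
    expect_identical(eemContour(pr$followup), eemContour(pr$baseline))
  }
  # labels split roughly like the target cohort (160/145)
  expect_gt(min(table(tr$label)), 100)
})

test_that("generation is bit-for-bit reproducible under a fixed seed", {
  a <- generateCohort(tinyCohort(seed = 99))
  b <- generateCohort(tinyCohort(seed = 99))
  expect_identical(cohortTruth(a), cohortTruth(b))
  for (i in seq_along(a)) {
    expect_identical(lumenContour(a[[i]]$baseline), lumenContour(b[[i]]$baseline))
    expect_identical(lumenContour(a[[i]]$followup), lumenContour(b[[i]]$followup))
  }
  c <- generateCohort(tinyCohort(seed = 100))
  expect_false(identical(cohortTruth(a)$dla, cohortTruth(c)$dla))
})

test_that("no-signal no-noise configuration yields exactly zero DLA", {
  cfg <- tinyCohort(seed = 12, gamma0 = 0, gammaFatigue = 0, gammaPb = 0,
                    sigmaPatient = 0, sigmaNoise = 0)
  tr <- cohortTruth(generateCohort(cfg))
  expect_identical(tr$dla, rep(0, nrow(tr)))
  expect_identical(tr$label, rep(0L, nrow(tr)))
})

test_that("with only the fatigue term active, DLA is a deterministic linear map", {
  cfg <- tinyCohort(seed = 12, nPat = 3L, nSl = 10L, gamma0 = 0,
                    gammaFatigue = 0.05, gammaPb = 0,
                    sigmaPatient = 0, sigmaNoise = 0)
  tr <- cohortTruth(generateCohort(cfg))
  expect_equal(cor(tr$surrogate_amplitude, tr$dla), 1, tolerance = 1e-12)
  expect_equal(tr$dla, 0.05 * tr$surrogate_amplitude, tolerance = 1e-12)
})

test_that("the hoop-stress amplitude surrogate equals dP r / t", {
  g <- ringGeometry(1.5, 2.0, pressureMin = 10.67, pressureMax = 16.0)
  expect_equal(surrogateStressAmplitude(g), 5.33 * 1.5 / 0.5,
               tolerance = 1e-3)  # 15.99 kPa
  g0 <- ringGeometry(1.5, 2.0, pressureMin = 10, pressureMax = 10 + 1e-12)
  expect_equal(surrogateStressAmplitude(g0), 0, tolerance = 1e-9)
  g1 <- ringGeometry(1, 2, pressureMin = 1, pressureMax = 2)
  expect_equal(surrogateStressAmplitude(g1), 1, tolerance = 2e-3)
})

test_that("patient intercept dispersion converges to sigmaPatient", {
  cfg <- cohortConfig(nPatients = 200L, slicesPerPatient = c(2L, 2L),
                      totalSlices = NULL, sigmaPatient = 0.25, seed = 31)
  tr <- cohortTruth(generateCohort(cfg))
  b <- tapply(tr$b_patient, tr$patient_id, unique)
  se <- 0.25 / sqrt(2 * (200 - 1))
  expect_lt(abs(sd(b) - 0.25), 3 * se)
})

test_that("the narrowing fraction is monotone non-decreasing in gamma0", {
  frac <- vapply(c(0.5, 1.9, 3.5), function(g0) {
    tr <- cohortTruth(generateCohort(tinyCohort(seed = 4, nPat = 4L,
                                                nSl = 20L, gamma0 = g0)))
    mean(tr$label)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("contour files round-trip through JSON", {
  pairs <- generateCohort(tinyCohort(seed = 8, nPat = 1L, nSl = 2L,
                                     pLipid = 1, pCalcium = 1))
  dir <- tempfile("contours")
  writeContours(pairs, dir)
  expect_length(list.files(dir, pattern = "json$"), 4L)
  back <- readContours(dir)
  expect_length(back, 2L)
  i <- match(sliceId(pairs[[1]]$baseline),
             vapply(back, function(p) sliceId(p$baseline), ""))
  expect_equal(lumenContour(back[[i]]$baseline),
               lumenContour(pairs[[1]]$baseline), tolerance = 1e-12)
  expect_equal(length(plaqueComponents(back[[i]]$baseline)), 2L)
  expect_equal(pressureRange(back[[i]]$followup),
               pressureRange(pairs[[1]]$followup))
})
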