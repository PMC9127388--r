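mesh6 <- buildMesh(ringGeometry(1, 1.4), targetEdgeLength = 0.4)

test_that("luminal statistics reduce correctly on prescribed fields", {
  n <- nrow(mesh6@nodes)
  solU <- fieldSolution(mesh6, stress = rep(4.5, n))
  expect_equal(unname(luminalStats(solU)$stress), c(4.5, 4.5))
  v <- rep(0, n)
  li <- mesh6@lumenNodes
  v[li] <- rep_len(c(1, 2, 3), length(li))
  solV <- fieldSolution(mesh6, stress = v)
  expect_equal(unname(luminalStats(solV)$stress), c(3, 2))
  bad <- solV; bad@mesh@lumenNodes <- integer()
  expect_error(luminalStats(bad), "empty")
})

test_that("fatigue amplitudes are the exact max-minus-min differences", {
  n <- nrow(mesh6@nodes)
  lo <- fieldSolution(mesh6, stress = rep(8, n), strain = rep(0.02, n))
  hi <- fieldSolution(mesh6, stress = rep(12, n), strain = rep(0.05, n))
  expect_equal(unname(fatigueAmplitudes(lo, hi)), c(4, 4, 0.03, 0.03))
  # a luminal hot spot moves only the max amplitude
  hi2 <- hi; hi2@stress[mesh6@lumenNodes[1]] <- 18
  amp <- fatigueAmplitudes(lo, hi2)
  loS <- luminalStats(lo); hiS <- luminalStats(hi2)
  expect_identical(unname(amp["max_stress_amplitude"]),
                   unname(hiS$stress["max"] - loS$stress["max"]))
  expect_identical(unname(amp["avg_stress_amplitude"]),
                   unname(hiS$stress["avg"] - loS$stress["avg"]))
  expect_equal(unname(amp["max_stress_amplitude"]), 10)
  expect_equal(unname(fatigueAmplitudes(lo, lo)), rep(0, 4))
  other <- buildMesh(ringGeometry(1, 1.5), targetEdgeLength = 0.4)
  expect_error(fatigueAmplitudes(lo, fieldSolution(other,
    stress = rep(1, nrow(other@nodes)))), "same mesh")
})

test_that("morphology implements plaque burden and area amplitudes", {
  m <- morphology(list(lumenArea = 6, wallArea = 6),
                  list(lumenArea = 6.5, wallArea = 6.1))
  expect_equal(unname(m["pb_at_pmin"]), 50)
  expect_equal(unname(m["wall_area_at_pmin"]), 6)
  m2 <- morphology(list(lumenArea = 6.8, wallArea = 6.0),
                   list(lumenArea = 7.2, wallArea = 6.1))
  expect_equal(unname(m2["lumen_area_amplitude"]), 0.4)
  expect_equal(unname(m2["wall_area_amplitude"]), 0.1)
  expect_error(morphology(list(lumenArea = -1, wallArea = 6),
                          list(lumenArea = 1, wallArea = 6)), "area")
})

test_that("the stenosis outcome follows the sign convention of DLA", {
  expect_equal(stenosisOutcome(8, 6.5), list(dla = 1.5, label = 1L))
  expect_equal(stenosisOutcome(6.5, 8), list(dla = -1.5, label = 0L))
  # boundary: zero DLA is non-progressive
  expect_equal(stenosisOutcome(7, 7), list(dla = 0, label = 0L))
  expect_error(stenosisOutcome(0, 7), "positive")
})

test_that("feature rows expose exactly the 19 documented factors", {
  expect_length(featureNames(), 19L)
  pairs <- generateCohort(tinyCohort(seed = 2, nPat = 1L, nSl = 2L))
  row <- sliceFeatures(pairs[[1]], surrogate = TRUE)
  expect_identical(names(row),
                   c("patient_id", "slice_id", featureNames(), "dla", "label"))
  # amplitude identities hold exactly in the assembled row
  expect_identical(row$max_stress_amplitude,
                   row$max_stress_at_pmax - row$max_stress_at_pmin)
  expect_identical(row$lumen_area_amplitude,
                   row$lumen_area_at_pmax - row$lumen_area_at_pmin)
  expect_true(row$pb_at_pmin > 0 && row$pb_at_pmin < 100)
})

test_that("FE and surrogate feature rows agree on morphology and signs", {
  pairs <- generateCohort(tinyCohort(seed = 6, nPat = 1L, nSl = 2L))
  fe <- sliceFeatures(pairs[[1]], surrogate = FALSE,
                      config = fastSolver(5L), targetEdgeLength = 0.18)
  su <- sliceFeatures(pairs[[1]], surrogate = TRUE)
  expect_identical(fe$dla, su$dla)
  # imaged-at-pmin lumen areas agree within the shrink tolerance
  expect_equal(fe$lumen_area_at_pmin, su$lumen_area_at_pmin,
               tolerance = 0.02)
  # the uniform circumferential shrink matches the lumen area only; the
  # incompressible wall ring keeps the shrunken (s^2-scaled) area, so
  # the FE plaque burden sits below the image-derived value
  expect_equal(fe$pb_at_pmin, su$pb_at_pmin, tolerance = 0.25)
  expect_lt(fe$pb_at_pmin, su$pb_at_pmin)
  expect_true(fe$avg_stress_amplitude > 0 && fe$avg_strain_amplitude > 0)
  expect_gt(fe$lumen_area_amplitude, 0)
})

test_that("stress amplitude correlates positively with DLA on a fatigue-driven cohort", {
  pairs <- generateCohort(cohortConfig(nPatients = 3L,
                                       slicesPerPatient = c(25L, 25L),
                                       totalSlices = NULL, seed = 14))
  feats <- computeCohortFeatures(pairs, surrogate = TRUE)
  expect_gt(cor(feats$avg_stress_amplitude, feats$dla), 0)
  expect_lt(cor(feats$pb_at_pmin, feats$dla), 0)
})
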