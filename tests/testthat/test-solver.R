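# Cylinder benchmarks: thin-wall ring (t/r = 0.1) where the Laplace
# hoop stress P r / t is the analytic reference.

mats <- vesselMaterials()

test_that("zero pressure produces zero displacement and zero stress", {
  m <- buildMesh(thinRing(), targetEdgeLength = 0.12)
  sol <- solveInflation(m, mats, 0, fastSolver(2L))
  expect_equal(max(abs(sol@displacement)), 0)
  expect_lt(max(abs(nodalStress(sol))), 1e-10)
  expect_lt(max(abs(nodalStrain(sol))), 1e-10)
})

test_that("luminal hoop stress matches the Laplace thin-wall value", {
  m <- buildMesh(thinRing(), targetEdgeLength = 0.1)
  p <- 0.3  # small load: reference-configuration Laplace applies
  sol <- solveInflation(m, mats, p, fastSolver(4L, lambdaZ = 1))
  ls <- luminalStats(sol)
  expect_lt(abs(ls$stress["avg"] - p * 1.5 / 0.15) / (p * 1.5 / 0.15), 0.10)
  # axisymmetry: max ~ average on the lumen
  expect_lt(ls$stress["max"] / ls$stress["avg"] - 1, 0.02)
  # at a finite load the deformed-configuration Laplace value applies
  p2 <- 1
  sol2 <- solveInflation(m, mats, p2, fastSolver(5L, lambdaZ = 1))
  rDef <- sqrt(lumenArea(sol2) / pi)
  tDef <- sqrt((lumenArea(sol2) + wallArea(sol2)) / pi) - rDef
  lap <- p2 * rDef / tDef
  expect_lt(abs(luminalStats(sol2)$stress["avg"] - lap) / lap, 0.10)
})

test_that("the response is linear at small loads", {
  m <- buildMesh(thinRing(), targetEdgeLength = 0.12)
  s1 <- solveInflation(m, mats, 0.05, fastSolver(2L, lambdaZ = 1))
  s2 <- solveInflation(m, mats, 0.10, fastSolver(2L, lambdaZ = 1))
  ratio <- max(nodalStress(s2)) / max(nodalStress(s1))
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("inflation is monotone and equal pressures give identical pairs", {
  m <- buildMesh(ringGeometry(1.5, 2.2), targetEdgeLength = 0.18)
  pr <- solvePair(m, mats, 10.67, 16.0, fastSolver(5L))
  expect_gt(lumenArea(pr$max), lumenArea(pr$min))
  same <- solvePair(m, mats, 10.67, 10.67, fastSolver(5L))
  expect_identical(same$min, same$max)
  expect_equal(unname(fatigueAmplitudes(same$min, same$max)), rep(0, 4))
})

test_that("a cycle amplitude tracks dP on a stiff thin ring", {
  # stiffness-scaled wall keeps strains small so the small-strain
  # Laplace amplitude dP r / t is the oracle for dP = 5.33 kPa
  sm <- scaledMaterials(100)
  m <- buildMesh(thinRing(), targetEdgeLength = 0.12)
  pr <- solvePair(m, sm, 10.67, 16.0, fastSolver(5L, lambdaZ = 1))
  amp <- fatigueAmplitudes(pr$min, pr$max)
  lap <- 5.33 * 1.5 / 0.15
  expect_lt(abs(amp["avg_stress_amplitude"] - lap) / lap, 0.10)
  # larger dP gives strictly larger amplitudes
  pr2 <- solvePair(m, sm, 10.67, 18.0, fastSolver(5L, lambdaZ = 1))
  amp2 <- fatigueAmplitudes(pr2$min, pr2$max)
  expect_true(all(amp2 > amp))
})

test_that("luminal stress is mesh-converged within 5% under edge halving", {
  coarse <- buildMesh(thinRing(), targetEdgeLength = 0.2)
  fine <- buildMesh(thinRing(), targetEdgeLength = 0.1)
  a <- max(nodalStress(solveInflation(coarse, mats, 0.5, fastSolver(3L, lambdaZ = 1))))
  b <- max(nodalStress(solveInflation(fine, mats, 0.5, fastSolver(3L, lambdaZ = 1))))
  expect_lt(abs(a - b) / b, 0.05)
})

test_that("the follower load satisfies the discrete virtual-work identity", {
  # for a closed pressurized loop, integral of x . p n ds = 2 p A
  m <- buildMesh(ringGeometry(1.5, 2.2), targetEdgeLength = 0.18)
  sol <- solveInflation(m, mats, 12, fastSolver(5L))
  u <- as.numeric(t(sol@displacement))
  x <- as.numeric(t(sol@mesh@nodes)) + u
  f <- plaqueFatigue:::pressureLoadCpp(m@nodes, m@lumenEdges, u, 12)$force
  expect_lt(abs(sum(f * x) / 2 - 12 * lumenArea(sol)) / (12 * lumenArea(sol)),
            0.01)
})

test_that("rotating the mesh rotates the solution (objectivity)", {
  g <- ringGeometry(1.5, 1.9)
  m <- buildMesh(g, targetEdgeLength = 0.18)
  a <- 0.7
  Q <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  mR <- m
  mR@nodes <- m@nodes %*% t(Q)
  s <- solveInflation(m, mats, 2, fastSolver(3L))
  sR <- solveInflation(mR, mats, 2, fastSolver(3L))
  expect_equal(nodalStress(sR), nodalStress(s),
               tolerance = 1e-6)
  expect_equal(lumenArea(sR), lumenArea(s), tolerance = 1e-8)
})

test_that("solver failures carry diagnostic messages", {
  m <- buildMesh(thinRing(), targetEdgeLength = 0.25)
  # absurd load: even adaptive substepping gives up
  expect_error(solveInflation(m, vesselMaterials(), 5000,
                              solverConfig(1L, maxNewtonIter = 3L)),
               "load stepping|Newton")
})
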