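# Shared fixtures: small meshes and solver settings sized for test
# runtime; scientific checks use these unless a test needs the
# benchmark resolution.

fastSolver <- function(nInc = 5L, lambdaZ = 1) {
  solverConfig(nLoadIncrements = nInc, axialStretch = lambdaZ)
}

# thin-wall cylinder benchmark, t/r = 0.1
thinRing <- function(n = 64L) ringGeometry(1.5, 1.65, n = n)

# stiffness-scaled materials: same parameter shape, small strains at a
# given load (near-rigid oracle regimes)
scaledMaterials <- function(factor) {
  m <- vesselMaterials()
  lapply(m, function(p) materialParams(
    c1 = p@c1 * factor, c2 = p@c2 * factor, D1 = p@D1 * factor, D2 = p@D2,
    K1 = p@K1 * factor, K2 = p@K2, kappaVol = p@kappaVol * factor,
    anisotropic = p@anisotropic))
}

# minimal FESolution carrying prescribed nodal fields on a given mesh
fieldSolution <- function(mesh, stress, strain = stress, pressure = 1,
                          lumenArea = 1, wallArea = 1) {
  new("FESolution", mesh = mesh,
      displacement = matrix(0, nrow(mesh@nodes), 2),
      stress = stress, strain = strain, pressure = pressure,
      lumenArea = lumenArea, wallArea = wallArea, converged = TRUE,
      iterations = 0L)
}

tinyCohort <- function(seed = 3, nPat = 2L, nSl = 4L, ...) {
  cohortConfig(nPatients = nPat, slicesPerPatient = c(nSl, nSl),
               totalSlices = NULL, seed = seed, ...)
}
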