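#' Solver configuration
#'
#' @param nLoadIncrements number of pressure increments (>= 1).
#' @param newtonTol relative residual tolerance for Newton convergence.
#' @param maxNewtonIter maximum Newton iterations per increment.
#' @param axialStretch fixed axial stretch lambda_z; the default
#'   1/(1 - 0.05) applies the 5 percent axial shrinkage of in vivo
#'   coronary models as a pre-stretch.
#' @return validated list of solver settings.
#' @export
solverConfig <- function(nLoadIncrements = 10L, newtonTol = 1e-8,
                         maxNewtonIter = 30L, axialStretch = 1 / 0.95) {
  stopifnot(nLoadIncrements >= 1, newtonTol > 0, maxNewtonIter >= 1,
            axialStretch > 0)
  structure(list(nLoadIncrements = as.integer(nLoadIncrements),
                 newtonTol = newtonTol,
                 maxNewtonIter = as.integer(maxNewtonIter),
                 axialStretch = axialStretch), class = "solverConfig")
}

materialMatrix <- function(materials) {
  stopifnot(all(c("wall", "lipid", "calcium") %in% names(materials)))
  do.call(rbind, lapply(materials[c("wall", "lipid", "calcium")], paramVector))
}

# Rigid-body constraint rows: zero net translation and zero net rotation
# about the node-set centroid.
rigidBodyConstraints <- function(nodes) {
  nn <- nrow(nodes)
  ctr <- colMeans(nodes)
  X <- nodes[, 1] - ctr[1]; Y <- nodes[, 2] - ctr[2]
  ix <- seq(1, 2 * nn, by = 2); iy <- ix + 1
  Matrix::sparseMatrix(
    i = c(rep(1L, nn), rep(2L, nn), rep(3L, nn), rep(3L, nn)),
    j = c(ix, iy, ix, iy),
    x = c(rep(1, nn), rep(1, nn), -Y, X),
    dims = c(3L, 2L * nn))
}

deformedLumenPolygon <- function(mesh, u) {
  idx <- mesh@lumenEdges[, 1]
  mesh@nodes[idx, , drop = FALSE] + u[idx, , drop = FALSE]
}

deformedOuterPolygon <- function(mesh, u) {
  nCirc <- nrow(mesh@lumenEdges)
  idx <- mesh@outerNodes[seq_len(nCirc)]
  mesh@nodes[idx, , drop = FALSE] + u[idx, , drop = FALSE]
}

#' Solve static inflation of a meshed slice
#'
#' Incremental Newton-Raphson solution of finite-strain equilibrium
#' under follower luminal pressure (the load acts on the deformed lumen
#' edge normals), traction-free outer boundary, and generalized plane
#' strain with the configured axial stretch. Rigid-body modes are
#' removed by Lagrange-multiplier constraints on net translation and
#' rotation. The element tangent is a forward-difference linearization
#' of the analytic element residual.
#'
#' @param mesh a [VesselMesh-class].
#' @param materials named list of [MaterialParams-class] for `wall`,
#'   `lipid`, `calcium` (see [vesselMaterials()]).
#' @param pressure luminal pressure (kPa), >= 0.
#' @param config a [solverConfig()].
#' @param state optional warm-start: a previous [FESolution-class] on
#'   the same mesh whose pressure becomes the starting load level.
#' @return An [FESolution-class] with nodal maximum principal Cauchy
#'   stress (kPa) and Green-Lagrange strain recovered by area-weighted
#'   averaging of element quadrature values.
#' @examples
#' \donttest{
#' m <- buildMesh(ringGeometry(1.5, 1.65), targetEdgeLength = 0.3)
#' sol <- solveInflation(m, vesselMaterials(), 2, solverConfig(4))
#' sol
#' }
#' @export
solveInflation <- function(mesh, materials, pressure,
                           config = solverConfig(), state = NULL) {
  stopifnot(pressure >= 0)
  nn <- nrow(mesh@nodes); ndof <- 2L * nn
  pars <- materialMatrix(materials)
  tissueIdx <- match(mesh@tissue, c("wall", "lipid", "calcium")) - 1L
  fibers <- elementFibers(mesh)
  Cmat <- rigidBodyConstraints(mesh@nodes)
  lz <- config$axialStretch

  u <- numeric(ndof); p0 <- 0; totalIter <- 0L
  if (!is.null(state)) {
    stopifnot(is(state, "FESolution"), nrow(state@mesh@nodes) == nn)
    u <- as.numeric(t(state@displacement)); p0 <- state@pressure
  }
  lambda <- numeric(3)
  trace <- list()

  # residual norm at a trial state; Inf flags an inverted element so the
  # line search backtracks instead of aborting
  resNorm <- function(uT, lambdaT, pk) {
    r <- tryCatch(
      feAssembleCpp(mesh@nodes, mesh@elements, tissueIdx, pars, fibers,
                    uT, lz, FALSE)$residual,
      error = function(e) NULL)
    if (is.null(r)) return(Inf)
    f <- pressureLoadCpp(mesh@nodes, mesh@lumenEdges, uT, pk)$force
    Gu <- r - f + as.numeric(Matrix::crossprod(Cmat, lambdaT))
    out <- sqrt(sum(Gu^2) + sum(as.numeric(Cmat %*% uT)^2))
    if (is.finite(out)) out else Inf
  }

  zero33 <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(3, 3))

  # Newton with line search at one load level, from a given state;
  # returns NULL when the level is out of reach (caller halves the step)
  newtonAt <- function(u, lambda, pk, tolK) {
    needTangent <- TRUE
    A <- NULL
    for (iter in seq_len(config$maxNewtonIter)) {
      asm <- feAssembleCpp(mesh@nodes, mesh@elements, tissueIdx, pars,
                           fibers, u, lz, needTangent)
      ext <- pressureLoadCpp(mesh@nodes, mesh@lumenEdges, u, pk)
      Gu <- asm$residual - ext$force + as.numeric(Matrix::crossprod(Cmat, lambda))
      Gc <- as.numeric(Cmat %*% u)
      ref <- max(sqrt(sum(ext$force^2)), 1)
      res <- sqrt(sum(Gu^2) + sum(Gc^2))
      totalIter <<- totalIter + 1L
      trace[[length(trace) + 1L]] <<- c(pressure = pk, iter = iter,
                                        residual = res)
      if (res < tolK * ref)
        return(list(u = u, lambda = lambda))
      if (needTangent) {
        K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$v,
                                  dims = c(ndof, ndof))
        if (length(ext$i))
          K <- K - Matrix::sparseMatrix(i = ext$i, j = ext$j, x = ext$v,
                                        dims = c(ndof, ndof))
        # keep the same object across iterations: Matrix caches the
        # sparse LU inside it, so modified-Newton steps reuse the factor
        A <- rbind(cbind(K, Matrix::t(Cmat)), cbind(Cmat, zero33))
      }
      dz <- as.numeric(Matrix::solve(A, -c(Gu, Gc)))
      du <- dz[seq_len(ndof)]; dl <- dz[ndof + 1:3]
      # line search: the exponential (fibre) stiffening and the
      # volumetric penalty make full Newton steps overshoot on soft
      # thin-walled sections; evaluate a geometric ladder of step
      # fractions and take the best
      best <- Inf; bestA <- NA_real_
      for (a in 2^-(0:12)) {
        rA <- resNorm(u + a * du, lambda + a * dl, pk)
        if (rA < best) { best <- rA; bestA <- a }
        if (best < 0.5 * res) break  # good enough, stop probing
      }
      if (!is.finite(best) || best >= res) {
        if (!needTangent) { needTangent <- TRUE; next }  # stale tangent
        return(NULL)
      }
      u <- u + bestA * du
      lambda <- lambda + bestA * dl
      # refresh the tangent only when the modified-Newton step degrades
      needTangent <- bestA < 0.49 || best > 0.6 * res
    }
    NULL
  }

  # incremental loading with adaptive substepping: increments that the
  # Newton loop cannot reach are bisected (soft slices with large
  # strains per increment need the finer staging)
  if (pressure != p0) {
    step0 <- (pressure - p0) / config$nLoadIncrements
    step <- step0
    pCur <- p0
    minStep <- step0 / 64
    while (pCur < pressure - 1e-12) {
      pk <- min(pCur + step, pressure)
      # intermediate levels only stage the load path; they are solved to
      # a loose tolerance, the target pressure to the configured one
      tolK <- if (pk == pressure) config$newtonTol else
        max(config$newtonTol, 1e-4)
      stateK <- newtonAt(u, lambda, pk, tolK)
      if (is.null(stateK)) {
        step <- step / 2
        if (step < minStep)
          stop(sprintf(
            "load stepping failed near %.3f kPa even at 1/64 of the configured increment (see iteration trace)",
            pk))
        next
      }
      u <- stateK$u; lambda <- stateK$lambda
      pCur <- pk
      step <- min(step * 1.5, step0)
    }
  } else {
    stateK <- newtonAt(u, lambda, pressure, config$newtonTol)
    if (is.null(stateK))
      stop(sprintf("Newton did not converge at pressure %.3f kPa", pressure))
    u <- stateK$u; lambda <- stateK$lambda
  }

  rec <- recoverFieldsCpp(mesh@nodes, mesh@elements, tissueIdx, pars,
                          fibers, u, lz)
  fld <- nodalRecovery(mesh, rec)
  U <- matrix(u, nn, 2, byrow = TRUE)
  lp <- deformedLumenPolygon(mesh, U)
  op <- deformedOuterPolygon(mesh, U)
  la <- polygonArea(lp)
  new("FESolution", mesh = mesh, displacement = U,
      stress = fld$stress, strain = fld$strain, pressure = pressure,
      lumenArea = la, wallArea = polygonArea(op) - la,
      converged = TRUE, iterations = totalIter)
}

# Area-weighted nodal averaging of element quadrature means.
nodalRecovery <- function(mesh, rec) {
  nn <- nrow(mesh@nodes)
  ids <- as.vector(mesh@elements)
  w <- rep(rec$area, 6L)
  agg <- rowsum(cbind(w * rep(rec$stressMax, 6L),
                      w * rep(rec$strainMax, 6L), w), ids)
  out_s <- numeric(nn); out_e <- numeric(nn)
  at <- as.integer(rownames(agg))
  out_s[at] <- agg[, 1] / agg[, 3]
  out_e[at] <- agg[, 2] / agg[, 3]
  list(stress = out_s, strain = out_e)
}

#' Solve both ends of the cardiac pressure cycle
#'
#' Solves the same mesh at the diastolic (`pressureMin`) and systolic
#' (`pressureMax`) pressures; the systolic solve warm-starts from the
#' diastolic state.
#'
#' @inheritParams solveInflation
#' @param pressureMin,pressureMax the cycle pressure range (kPa),
#'   `pressureMax >= pressureMin`.
#' @return list with elements `min` and `max`, both [FESolution-class]
#'   on the same mesh.
#' @export
solvePair <- function(mesh, materials, pressureMin, pressureMax,
                      config = solverConfig()) {
  stopifnot(pressureMax >= pressureMin)
  solMin <- solveInflation(mesh, materials, pressureMin, config)
  solMax <- if (pressureMax == pressureMin) solMin else
    solveInflation(mesh, materials, pressureMax, config, state = solMin)
  list(min = solMin, max = solMax)
}

#' Export solution fields as CSV
#'
#' One row per node: reference coordinates, displacements, maximum
#' principal Cauchy stress (kPa) and Green-Lagrange strain.
#'
#' @param solution an [FESolution-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFieldsCsv <- function(solution, file) {
  df <- data.frame(x = solution@mesh@nodes[, 1], y = solution@mesh@nodes[, 2],
                   ux = solution@displacement[, 1],
                   uy = solution@displacement[, 2],
                   stress_max_principal = solution@stress,
                   strain_max_principal = solution@strain)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
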