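#' The 19 baseline predictor names
#'
#' Twelve biomechanical factors (maximum/average principal stress and
#' strain at minimum and maximum pressure, plus the four cardiac-cycle
#' amplitudes) and seven morphological factors (plaque burden at minimum
#' pressure, lumen/wall areas at both pressures, and their amplitudes).
#' Column order is fixed; this is the contract between the mechanics and
#' statistics stages.
#'
#' @return character vector of length 19.
#' @export
featureNames <- function() {
  c("max_stress_at_pmin", "avg_stress_at_pmin",
    "max_stress_at_pmax", "avg_stress_at_pmax",
    "max_strain_at_pmin", "avg_strain_at_pmin",
    "max_strain_at_pmax", "avg_strain_at_pmax",
    "max_stress_amplitude", "avg_stress_amplitude",
    "max_strain_amplitude", "avg_strain_amplitude",
    "pb_at_pmin",
    "lumen_area_at_pmin", "lumen_area_at_pmax",
    "wall_area_at_pmin", "wall_area_at_pmax",
    "lumen_area_amplitude", "wall_area_amplitude")
}

#' Luminal stress/strain statistics
#'
#' Plaque rupture initiates at the luminal surface, so the per-slice
#' stress/strain summaries are taken over the lumen boundary nodes:
#' the maximum and the (node-based) arithmetic mean of the nodal maximum
#' principal stress and strain.
#'
#' @param solution an [FESolution-class].
#' @return list with `stress = c(max, avg)` (kPa) and
#'   `strain = c(max, avg)`.
#' @export
luminalStats <- function(solution) {
  idx <- solution@mesh@lumenNodes
  if (!length(idx)) stop("empty lumen boundary node set")
  list(stress = c(max = max(solution@stress[idx]),
                  avg = mean(solution@stress[idx])),
       strain = c(max = max(solution@strain[idx]),
                  avg = mean(solution@strain[idx])))
}

#' Fatigue amplitudes over one cardiac cycle
#'
#' The four fatigue measurements: maximum/average stress and strain
#' variation between the diastolic and systolic solutions, i.e. the
#' luminal statistic at maximum pressure minus the same statistic at
#' minimum pressure.
#'
#' @param solMin,solMax [FESolution-class] objects on the same mesh at
#'   the two cycle pressures.
#' @return named numeric: `max_stress_amplitude`, `avg_stress_amplitude`
#'   (kPa), `max_strain_amplitude`, `avg_strain_amplitude`.
#' @export
fatigueAmplitudes <- function(solMin, solMax) {
  if (!identical(dim(solMin@mesh@nodes), dim(solMax@mesh@nodes)) ||
      !isTRUE(all.equal(solMin@mesh@nodes, solMax@mesh@nodes)))
    stop("solutions are not on the same mesh")
  lo <- luminalStats(solMin); hi <- luminalStats(solMax)
  c(max_stress_amplitude = unname(hi$stress["max"] - lo$stress["max"]),
    avg_stress_amplitude = unname(hi$stress["avg"] - lo$stress["avg"]),
    max_strain_amplitude = unname(hi$strain["max"] - lo$strain["max"]),
    avg_strain_amplitude = unname(hi$strain["avg"] - lo$strain["avg"]))
}

#' Morphological factors from the deformed configurations
#'
#' Areas are computed by the shoelace formula on the deformed boundary
#' loops. Plaque (wall ring) area is the EEM area minus the lumen area;
#' plaque burden `PB = plaque area / EEM area * 100` is evaluated at
#' minimum pressure.
#'
#' @param atMin,atMax lists `list(lumenArea, wallArea)` (mm^2) for the
#'   two pressures, or [FESolution-class] objects.
#' @return named numeric: `pb_at_pmin` (percent), lumen/wall areas at
#'   both pressures and the two area amplitudes (mm^2).
#' @export
morphology <- function(atMin, atMax) {
  getA <- function(x)
    if (is(x, "FESolution")) c(lumen = x@lumenArea, wall = x@wallArea)
    else c(lumen = x$lumenArea, wall = x$wallArea)
  lo <- getA(atMin); hi <- getA(atMax)
  if (any(c(lo, hi) <= 0)) stop("non-positive deformed area")
  eem <- lo["lumen"] + lo["wall"]
  c(pb_at_pmin = unname(100 * lo["wall"] / eem),
    lumen_area_at_pmin = unname(lo["lumen"]),
    lumen_area_at_pmax = unname(hi["lumen"]),
    wall_area_at_pmin = unname(lo["wall"]),
    wall_area_at_pmax = unname(hi["wall"]),
    lumen_area_amplitude = unname(hi["lumen"] - lo["lumen"]),
    wall_area_amplitude = unname(hi["wall"] - lo["wall"]))
}

#' Stenosis progression outcome
#'
#' Delta lumen area `DLA = baseline lumen area - follow-up lumen area`
#' (both imaged, i.e. at minimum pressure); the binary label is 1 for
#' positive DLA (progressive narrowing) and 0 for non-positive DLA.
#'
#' @param baselineArea,followupArea imaged lumen areas (mm^2), > 0.
#' @return list with `dla` (mm^2) and `label` (integer 0/1).
#' @examples
#' stenosisOutcome(8, 6.5)  # dla 1.5, label 1
#' @export
stenosisOutcome <- function(baselineArea, followupArea) {
  if (baselineArea <= 0 || followupArea <= 0)
    stop("lumen areas must be positive")
  dla <- baselineArea - followupArea
  list(dla = dla, label = as.integer(dla > 0))
}

# Closed-form screening surrogate for the per-slice biomechanics:
# Laplace hoop stress sigma = p r / t (mean thickness for the average,
# minimum thickness for the maximum) and strain = sigma / E_eff. Keeps
# the orderings and signs of the FE quantities at negligible cost.
surrogateSliceStats <- function(geometry, eEff = 150) {
  ctr <- polygonCentroid(geometry@lumen)
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  rl <- vapply(th, function(t) rayPolygonDistance(geometry@lumen, ctr, t), 0)
  re <- vapply(th, function(t) rayPolygonDistance(geometry@eem, ctr, t), 0)
  tMean <- mean(re - rl); tMin <- min(re - rl)
  if (tMin <= 0) stop("non-positive wall thickness")
  rEq <- sqrt(lumenArea(geometry) / pi)
  aL <- lumenArea(geometry); aW <- wallArea(geometry)
  # the imaged geometry corresponds to the diastolic state, so areas
  # respond to the pressure *excess* over pressureMin, while stresses
  # follow the absolute pressure
  p0 <- geometry@pressureMin
  perSlice <- function(p) {
    sAvg <- p * rEq / tMean; sMax <- p * rEq / tMin
    # lumen gains what the wall compliance allows; the nearly
    # incompressible ring area shrinks only by the small volumetric
    # strain ~ p / kappa
    dA <- aL * ((p - p0) * rEq / tMean) / eEff * 0.5
    list(lumenArea = aL + dA, wallArea = aW * (1 - (p - p0) / 2000),
         stress = c(max = sMax, avg = sAvg),
         strain = c(max = sMax / eEff, avg = sAvg / eEff))
  }
  list(min = perSlice(geometry@pressureMin),
       max = perSlice(geometry@pressureMax))
}

#' Compute the per-slice feature row
#'
#' Assembles the 19 baseline factors plus DLA and label for one
#' baseline/follow-up pair. In finite-element mode the baseline slice is
#' shrunk to its stress-free reference, meshed and solved at both cycle
#' pressures; in surrogate mode closed-form Laplace statistics replace
#' the solve (fast screening, identical table layout).
#'
#' @param pair `list(baseline =, followup =)` of
#'   [VesselGeometry-class].
#' @param materials tissue materials, see [vesselMaterials()].
#' @param surrogate logical; use the closed-form screening statistics.
#' @param config a [solverConfig()].
#' @param targetEdgeLength FE mesh resolution (mm).
#' @param shrinkTolerance relative lumen-area tolerance of the
#'   circumferential shrink search.
#' @return one-row data.frame: ids, the 19 factors, `dla`, `label`.
#' @export
sliceFeatures <- function(pair, materials = vesselMaterials(),
                          surrogate = FALSE, config = solverConfig(),
                          targetEdgeLength = 0.12, shrinkTolerance = 0.01) {
  g <- pair$baseline
  if (surrogate) {
    st <- surrogateSliceStats(g)
    lo <- st$min; hi <- st$max
    biomech <- c(
      max_stress_at_pmin = unname(lo$stress["max"]),
      avg_stress_at_pmin = unname(lo$stress["avg"]),
      max_stress_at_pmax = unname(hi$stress["max"]),
      avg_stress_at_pmax = unname(hi$stress["avg"]),
      max_strain_at_pmin = unname(lo$strain["max"]),
      avg_strain_at_pmin = unname(lo$strain["avg"]),
      max_strain_at_pmax = unname(hi$strain["max"]),
      avg_strain_at_pmax = unname(hi$strain["avg"]),
      max_stress_amplitude = unname(hi$stress["max"] - lo$stress["max"]),
      avg_stress_amplitude = unname(hi$stress["avg"] - lo$stress["avg"]),
      max_strain_amplitude = unname(hi$strain["max"] - lo$strain["max"]),
      avg_strain_amplitude = unname(hi$strain["avg"] - lo$strain["avg"]))
    morph <- morphology(lo, hi)
  } else {
    ref <- findCircumferentialShrink(g, materials, shrinkTolerance, config,
                                     targetEdgeLength)
    mesh <- attr(ref, "mesh")
    solMin <- attr(ref, "solutionMin")
    solMax <- solveInflation(mesh, materials, g@pressureMax, config,
                             state = solMin)
    sols <- list(min = solMin, max = solMax)
    loS <- luminalStats(sols$min); hiS <- luminalStats(sols$max)
    biomech <- c(
      max_stress_at_pmin = unname(loS$stress["max"]),
      avg_stress_at_pmin = unname(loS$stress["avg"]),
      max_stress_at_pmax = unname(hiS$stress["max"]),
      avg_stress_at_pmax = unname(hiS$stress["avg"]),
      max_strain_at_pmin = unname(loS$strain["max"]),
      avg_strain_at_pmin = unname(loS$strain["avg"]),
      max_strain_at_pmax = unname(hiS$strain["max"]),
      avg_strain_at_pmax = unname(hiS$strain["avg"]),
      fatigueAmplitudes(sols$min, sols$max))
    morph <- morphology(sols$min, sols$max)
  }
  out <- stenosisOutcome(lumenArea(pair$baseline), lumenArea(pair$followup))
  df <- data.frame(patient_id = g@patientId, slice_id = g@sliceId,
                   t(biomech), t(morph))
  df$dla <- out$dla
  df$label <- out$label
  df[, c("patient_id", "slice_id", featureNames(), "dla", "label")]
}

#' Build the cohort feature table
#'
#' Applies [sliceFeatures()] to every pair; the result (one row per
#' baseline slice: ids, 19 factors, DLA, label) is the input to the
#' correlation screen and the random-forest classifier.
#'
#' @param pairs output of [generateCohort()] or [readContours()].
#' @inheritParams sliceFeatures
#' @param progress print a line every 25 slices in FE mode.
#' @return data.frame with `2 + 19 + 2` columns.
#' @export
computeCohortFeatures <- function(pairs, materials = vesselMaterials(),
                                  surrogate = FALSE,
                                  config = solverConfig(),
                                  targetEdgeLength = 0.12,
                                  shrinkTolerance = 0.01,
                                  progress = FALSE) {
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    rows[[i]] <- sliceFeatures(pairs[[i]], materials, surrogate, config,
                               targetEdgeLength, shrinkTolerance)
    if (progress && i %% 25L == 0L)
      message(sprintf("  ... %d / %d slices", i, length(pairs)))
  }
  do.call(rbind, rows)
}
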