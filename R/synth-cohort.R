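#' Configure a synthetic IVUS-like cohort
#'
#' Defines the generative conditions for baseline/follow-up slice-pair
#' cohorts: an eccentric-walled vessel population with optional
#' lipid/calcium inclusions, patient-level pulsating pressures, and a
#' linear generative rule linking the follow-up lumen-area change (DLA)
#' positively to the hoop-stress amplitude and negatively to plaque
#' burden, with a patient random intercept. Defaults emulate a
#' seven-patient, 305-slice-pair coronary cohort with roughly balanced
#' narrowing/non-narrowing classes; see the methods vignette for the
#' rationale behind each value.
#'
#' @param nPatients number of patients.
#' @param slicesPerPatient integer range (min, max) of slices drawn per
#'   patient.
#' @param totalSlices optional exact total pair count; after drawing,
#'   per-patient counts are adjusted cyclically to match. `NULL` skips
#'   the adjustment.
#' @param lumenRadius,wallThickness `c(mean, sd)` of the lumen base
#'   radius and mean wall thickness (mm).
#' @param eccentricity maximum relative cos(theta) modulation of the
#'   lumen radius, in [0, 1); per-slice values are drawn uniformly from
#'   `[0, eccentricity]`.
#' @param pLipid,pCalcium per-slice inclusion probabilities.
#' @param pressureMin,pressureMax `c(mean, sd)` of the per-patient
#'   diastolic/systolic luminal pressures (kPa); defaults centre on
#'   80/120 mmHg.
#' @param gamma0,gammaFatigue,gammaPb generative DLA coefficients
#'   (mm^2; mm^2/kPa; mm^2 per percent plaque burden). The DLA of a pair
#'   is `gamma0 + gammaFatigue * A + gammaPb * PB + b_patient + eps`
#'   with `A` the closed-form hoop-stress amplitude surrogate.
#' @param sigmaPatient,sigmaNoise SDs of the patient random intercept
#'   and residual (mm^2).
#' @param seed integer master seed; per-patient sub-streams are derived
#'   deterministically from it.
#' @return validated config list (class `"cohortConfig"`).
#' @examples
#' cfg <- cohortConfig(nPatients = 2, slicesPerPatient = c(4, 6),
#'                     totalSlices = NULL)
#' pairs <- generateCohort(cfg)
#' length(pairs)
#' @export
cohortConfig <- function(nPatients = 7L,
                         slicesPerPatient = c(40L, 50L),
                         totalSlices = 305L,
                         lumenRadius = c(mean = 1.5, sd = 0.25),
                         wallThickness = c(mean = 0.7, sd = 0.12),
                         eccentricity = 0.25,
                         pLipid = 0.4, pCalcium = 0.2,
                         pressureMin = c(mean = 10.67, sd = 0.8),
                         pressureMax = c(mean = 16.0, sd = 1.0),
                         gamma0 = 1.90, gammaFatigue = 0.06,
                         gammaPb = -0.05,
                         sigmaPatient = 0.25, sigmaNoise = 0.45,
                         seed = 1L) {
  stopifnot(nPatients >= 1, length(slicesPerPatient) == 2,
            slicesPerPatient[1] >= 1,
            slicesPerPatient[2] >= slicesPerPatient[1],
            lumenRadius[1] > 0, lumenRadius[2] >= 0,
            wallThickness[1] > 0, wallThickness[2] >= 0,
            eccentricity >= 0, eccentricity < 1,
            pLipid >= 0, pLipid <= 1, pCalcium >= 0, pCalcium <= 1,
            pressureMin[1] > 0, pressureMax[1] > pressureMin[1],
            sigmaPatient >= 0, sigmaNoise >= 0)
  structure(list(nPatients = as.integer(nPatients),
                 slicesPerPatient = as.integer(slicesPerPatient),
                 totalSlices = if (is.null(totalSlices)) NULL else as.integer(totalSlices),
                 lumenRadius = lumenRadius, wallThickness = wallThickness,
                 eccentricity = eccentricity, pLipid = pLipid,
                 pCalcium = pCalcium, pressureMin = pressureMin,
                 pressureMax = pressureMax, gamma0 = gamma0,
                 gammaFatigue = gammaFatigue, gammaPb = gammaPb,
                 sigmaPatient = sigmaPatient, sigmaNoise = sigmaNoise,
                 seed = as.integer(seed)), class = "cohortConfig")
}

# annular sector polygon between radius functions of the lumen-centred
# angular grid; CCW = outer arc forward, inner arc backward
sectorPolygon <- function(centre, thetaMid, span, rIn, rOut, nArc = 12L) {
  th <- seq(thetaMid - span / 2, thetaMid + span / 2, length.out = nArc)
  outer <- cbind(centre[1] + rOut(th) * cos(th), centre[2] + rOut(th) * sin(th))
  thr <- rev(th)
  inner <- cbind(centre[1] + rIn(thr) * cos(thr), centre[2] + rIn(thr) * sin(thr))
  rbind(outer, inner)
}

truncNorm <- function(n, mean, sd, lower) pmax(stats::rnorm(n, mean, sd), lower)

# one baseline slice geometry; NULL if the draw violates the geometric
# invariants (caller resamples)
drawSliceGeometry <- function(cfg, pid, sid, pmin, pmax) {
  nV <- 64L
  th <- seq(0, 2 * pi, length.out = nV + 1L)[-(nV + 1L)]
  rb <- truncNorm(1, cfg$lumenRadius[1], cfg$lumenRadius[2], 0.6)
  ecc <- stats::runif(1, 0, cfg$eccentricity)
  phi <- stats::runif(1, 0, 2 * pi)
  a2 <- stats::rnorm(1, 0, 0.02); phi2 <- stats::runif(1, 0, 2 * pi)
  a3 <- stats::rnorm(1, 0, 0.015); phi3 <- stats::runif(1, 0, 2 * pi)
  rLum <- function(t) rb * (1 + ecc * cos(t - phi) + a2 * cos(2 * t - phi2) +
                              a3 * cos(3 * t - phi3))
  tb <- truncNorm(1, cfg$wallThickness[1], cfg$wallThickness[2], 0.3)
  wEcc <- stats::runif(1, 0, 0.3); phiW <- stats::runif(1, 0, 2 * pi)
  tWall <- function(t) tb * (1 + wEcc * cos(t - phiW))
  rEem <- function(t) rLum(t) + tWall(t)
  if (any(rLum(th) <= 0.2) || any(tWall(th) <= 0.1)) return(NULL)

  centre <- c(0, 0)
  lumen <- cbind(rLum(th) * cos(th), rLum(th) * sin(th))
  eem <- cbind(rEem(th) * cos(th), rEem(th) * sin(th))

  components <- list()
  hasLipid <- stats::runif(1) < cfg$pLipid
  hasCalc <- stats::runif(1) < cfg$pCalcium
  thetaL <- stats::runif(1, 0, 2 * pi)
  if (hasLipid) {
    span <- stats::runif(1, 40, 120) * pi / 180
    components <- c(components, list(list(
      tissue = "lipid",
      polygon = sectorPolygon(centre, thetaL, span,
                              function(t) rLum(t) + 0.15 * tWall(t),
                              function(t) rLum(t) + 0.75 * tWall(t)))))
  }
  if (hasCalc) {
    span <- stats::runif(1, 30, 80) * pi / 180
    thetaC <- thetaL + pi + stats::runif(1, -0.3, 0.3)  # away from lipid
    components <- c(components, list(list(
      tissue = "calcium",
      polygon = sectorPolygon(centre, thetaC, span,
                              function(t) rLum(t) + 0.45 * tWall(t),
                              function(t) rLum(t) + 0.60 * tWall(t)))))
  }
  g <- try(vesselGeometry(lumen, eem, components, pressureMin = pmin,
                          pressureMax = pmax, patientId = pid, sliceId = sid,
                          timepoint = "baseline"), silent = TRUE)
  if (inherits(g, "try-error")) NULL else g
}

#' Thin-wall hoop-stress amplitude surrogate
#'
#' Laplace estimate of the cyclic hoop-stress amplitude,
#' `dP * r / t`, with `r = sqrt(lumen area / pi)` the equivalent lumen
#' radius and `t` the mean radial wall thickness about the lumen
#' centroid. Used as a fast stand-in for the finite-element amplitude
#' when generating cohorts and in screening-mode pipelines.
#'
#' @param geometry a [VesselGeometry-class].
#' @return stress amplitude (kPa).
#' @examples
#' g <- ringGeometry(1, 2, pressureMin = 1, pressureMax = 2)
#' surrogateStressAmplitude(g)  # 1 kPa
#' @export
surrogateStressAmplitude <- function(geometry) {
  ctr <- polygonCentroid(geometry@lumen)
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  rl <- vapply(th, function(t) rayPolygonDistance(geometry@lumen, ctr, t), 0)
  re <- vapply(th, function(t) rayPolygonDistance(geometry@eem, ctr, t), 0)
  tMean <- mean(re - rl)
  if (tMean <= 0) stop("non-positive mean wall thickness")
  dP <- geometry@pressureMax - geometry@pressureMin
  dP * sqrt(lumenArea(geometry) / pi) / tMean
}

#' Generate a synthetic baseline/follow-up cohort
#'
#' Draws per-patient pressures and slice geometries, then applies the
#' generative progression rule: the follow-up lumen area is the baseline
#' area minus `DLA = gamma0 + gammaFatigue * A + gammaPb * PB +
#' b_patient + eps`, where `A` is [surrogateStressAmplitude()], `PB` the
#' baseline plaque burden (percent), `b_patient ~ N(0, sigmaPatient^2)`
#' and `eps ~ N(0, sigmaNoise^2)`. The follow-up contour is the baseline
#' lumen rescaled uniformly to the new area; the EEM is held fixed.
#' Fully reproducible given `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @return list of pairs, each `list(baseline =, followup =)` of
#'   [VesselGeometry-class]; attribute `"truth"` is a data.frame of the
#'   generative quantities (patient intercepts, surrogate amplitudes,
#'   plaque burden, DLA and label) and attribute `"config"` the config.
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(config$seed)
  nP <- config$nPatients
  rng <- seq(config$slicesPerPatient[1], config$slicesPerPatient[2])
  counts <- if (length(rng) == 1L) rep(rng, nP) else
    sample(rng, nP, replace = TRUE)
  if (!is.null(config$totalSlices)) {
    i <- 0L
    while (sum(counts) != config$totalSlices) {
      i <- i %% nP + 1L
      d <- sign(config$totalSlices - sum(counts))
      cand <- counts[i] + d
      if (cand >= 1L) counts[i] <- cand
    }
  }

  pairs <- list()
  truth <- list()
  nFail <- 0L; nDraw <- 0L
  for (p in seq_len(nP)) {
    set.seed((config$seed + p * 7919L) %% .Machine$integer.max)
    pid <- sprintf("P%02d", p)
    pmin <- truncNorm(1, config$pressureMin[1], config$pressureMin[2], 4)
    pmax <- max(truncNorm(1, config$pressureMax[1], config$pressureMax[2], 6),
                pmin + 2)
    bPatient <- stats::rnorm(1, 0, config$sigmaPatient)
    for (s in seq_len(counts[p])) {
      sid <- sprintf("S%03d", s)
      g <- NULL
      for (attempt in seq_len(50L)) {
        nDraw <- nDraw + 1L
        g <- drawSliceGeometry(config, pid, sid, pmin, pmax)
        if (!is.null(g)) break
        nFail <- nFail + 1L
      }
      if (is.null(g))
        stop("could not draw a valid slice geometry in 50 attempts; ",
             "config distributions make nested contours infeasible")
      A <- surrogateStressAmplitude(g)
      pb <- 100 * wallArea(g) / eemArea(g)
      eps <- stats::rnorm(1, 0, config$sigmaNoise)
      dla <- config$gamma0 + config$gammaFatigue * A + config$gammaPb * pb +
        bPatient + eps
      aBase <- lumenArea(g)
      aFollow <- aBase - dla
      if (aFollow <= 0)
        stop("generative rule produced a non-positive follow-up lumen area; ",
             "check the DLA coefficients against the geometry scale")
      fu <- g
      fu@timepoint <- "followup"
      fu@lumen <- scalePolygon(g@lumen, sqrt(aFollow / aBase),
                               polygonCentroid(g@lumen))
      pairs[[length(pairs) + 1L]] <- list(baseline = g, followup = fu)
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, slice_id = sid, b_patient = bPatient,
        surrogate_amplitude = A, pb = pb, dla = dla,
        label = as.integer(dla > 0))
    }
  }
  if (nFail > 0.01 * nDraw)
    stop(sprintf("geometry draw failure rate %.1f%% exceeds 1%%; adjust config",
                 100 * nFail / nDraw))
  attr(pairs, "truth") <- do.call(rbind, truth)
  attr(pairs, "config") <- config
  pairs
}

#' Generative ground truth of a synthetic cohort
#' @param pairs output of [generateCohort()].
#' @return data.frame with one row per pair.
#' @export
cohortTruth <- function(pairs) attr(pairs, "truth")

#' Write / read slice contour files
#'
#' One JSON document per slice with the [VesselGeometry-class] fields;
#' coordinates in mm, polygons as `[[x, y], ...]` with the first vertex
#' not repeated.
#'
#' @param pairs output of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `writeContours`: invisible character vector of files written;
#'   `readContours`: list of baseline/follow-up pairs.
#' @export
writeContours <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (pr in pairs) for (g in pr) {
    doc <- list(patient_id = g@patientId, slice_id = g@sliceId,
                timepoint = g@timepoint,
                lumen_contour = unname(g@lumen),
                eem_contour = unname(g@eem),
                components = lapply(g@components, function(cmp)
                  list(tissue = cmp$tissue, polygon = unname(cmp$polygon))),
                pressure_min = g@pressureMin, pressure_max = g@pressureMax,
                slice_thickness = g@sliceThickness)
    f <- file.path(dir, sprintf("%s_%s_%s.json", g@patientId, g@sliceId,
                                g@timepoint))
    jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}

#' @rdname writeContours
#' @export
readContours <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  geoms <- lapply(files, function(f) {
    doc <- jsonlite::read_json(f, simplifyVector = TRUE)
    comps <- list()
    if (length(doc$components))
      comps <- lapply(seq_len(nrow(doc$components)), function(i)
        list(tissue = doc$components$tissue[i],
             polygon = doc$components$polygon[[i]]))
    vesselGeometry(doc$lumen_contour, doc$eem_contour, comps,
                   pressureMin = doc$pressure_min,
                   pressureMax = doc$pressure_max,
                   patientId = doc$patient_id, sliceId = doc$slice_id,
                   timepoint = doc$timepoint,
                   sliceThickness = doc$slice_thickness)
  })
  key <- vapply(geoms, function(g) paste(g@patientId, g@sliceId), "")
  pairs <- lapply(unique(key), function(k) {
    grp <- geoms[key == k]
    tp <- vapply(grp, function(g) g@timepoint, "")
    list(baseline = grp[[which(tp == "baseline")]],
         followup = grp[[which(tp == "followup")]])
  })
  pairs
}
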