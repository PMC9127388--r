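#' Uniformly shrink a geometry in-plane
#'
#' Scales all contours by `s` about the lumen centroid; the elementary
#' step of the circumferential shrinkage search.
#'
#' @param geometry a [VesselGeometry-class].
#' @param s scale factor in (0, 1].
#' @return a [VesselGeometry-class] with scaled contours.
#' @export
shrinkGeometry <- function(geometry, s) {
  stopifnot(s > 0)
  ctr <- polygonCentroid(geometry@lumen)
  g <- geometry
  g@lumen <- scalePolygon(geometry@lumen, s, ctr)
  g@eem <- scalePolygon(geometry@eem, s, ctr)
  g@components <- lapply(geometry@components, function(cmp) {
    cmp$polygon <- scalePolygon(cmp$polygon, s, ctr); cmp
  })
  g
}

#' Find the circumferential shrink recovering the imaged shape
#'
#' IVUS frames gated at the R-wave peak show the vessel pressurized at
#' the diastolic (minimum) pressure, so the imaged contours are not
#' stress-free. This routine searches for the uniform in-plane scale `s`
#' such that inflating the `s`-scaled geometry to `pressureMin` (with
#' the axial pre-stretch active) reproduces the imaged lumen area.
#' Fixed-point iteration `s <- s * sqrt(A_target / A_computed)`, at most
#' `maxIter` iterations.
#'
#' @param geometry the imaged [VesselGeometry-class].
#' @param materials named tissue material list, see [vesselMaterials()].
#' @param tolerance relative lumen-area mismatch accepted (default 1
#'   percent, below IVUS segmentation precision).
#' @param config a [solverConfig()].
#' @param targetEdgeLength mesh resolution used during the search (mm).
#' @param maxIter fixed-point iteration cap.
#' @return A [ReferenceGeometry-class]; attribute `"trace"` records the
#'   (s, area) iterates.
#' @export
findCircumferentialShrink <- function(geometry, materials = vesselMaterials(),
                                      tolerance = 0.01,
                                      config = solverConfig(),
                                      targetEdgeLength = 0.12,
                                      maxIter = 20L) {
  stopifnot(tolerance > 0)
  aTarget <- lumenArea(geometry)
  mesh0 <- buildMesh(geometry, targetEdgeLength)
  ctr <- polygonCentroid(geometry@lumen)
  s <- 1
  trace <- data.frame(s = numeric(), area = numeric(), mismatch = numeric())
  for (it in seq_len(maxIter)) {
    meshS <- mesh0
    meshS@nodes <- scalePolygon(mesh0@nodes, s, ctr)
    sol <- solveInflation(meshS, materials, geometry@pressureMin, config)
    a <- lumenArea(sol)
    mis <- abs(a - aTarget) / aTarget
    trace <- rbind(trace, data.frame(s = s, area = a, mismatch = mis))
    if (mis <= tolerance) {
      g <- shrinkGeometry(geometry, s)
      ref <- new("ReferenceGeometry", g, circumferentialShrink = s,
                 axialStretch = config$axialStretch)
      attr(ref, "trace") <- trace
      # the search's final state IS the diastolic solution on the
      # reference mesh; downstream stages reuse it instead of re-solving
      attr(ref, "mesh") <- meshS
      attr(ref, "solutionMin") <- sol
      return(ref)
    }
    s <- s * sqrt(aTarget / a)
  }
  err <- simpleError(sprintf(
    "circumferential shrink search did not converge in %d iterations (last mismatch %.3g)",
    maxIter, mis))
  err$trace <- trace
  stop(err)
}
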