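#' @import methods
NULL

#' VesselGeometry: one imaged vessel cross-section
#'
#' Holds the segmented contours of a single slice at one timepoint: the
#' lumen border, the external elastic membrane (EEM), optional plaque
#' component polygons (lipid-rich necrotic core, calcium), and the
#' pulsating luminal pressure range for the patient. Coordinates are in
#' mm, pressures in kPa. Contours are simple CCW polygons, first vertex
#' not repeated; the lumen lies strictly inside the EEM and components
#' lie inside the wall ring.
#'
#' @slot patientId,sliceId character identifiers.
#' @slot timepoint `"baseline"` or `"followup"`.
#' @slot lumen,eem n x 2 contour matrices (mm).
#' @slot components list of `list(tissue = "lipid"|"calcium", polygon =
#'   matrix)`.
#' @slot pressureMin,pressureMax luminal pressure range (kPa).
#' @slot sliceThickness slice extrusion thickness (mm, default 0.5, the
#'   catheter pullback inter-frame spacing).
#' @aliases VesselGeometry
#' @exportClass VesselGeometry
setClass("VesselGeometry",
  representation(
    patientId = "character", sliceId = "character", timepoint = "character",
    lumen = "matrix", eem = "matrix", components = "list",
    pressureMin = "numeric", pressureMax = "numeric",
    sliceThickness = "numeric"))

setValidity("VesselGeometry", function(object) {
  msg <- character()
  chkPoly <- function(p, nm) {
    if (!is.numeric(p) || ncol(p) != 2 || nrow(p) < 8)
      return(sprintf("%s must be an n x 2 numeric matrix with n >= 8", nm))
    if (!all(is.finite(p))) return(sprintf("%s has non-finite vertices", nm))
    if (!isCCW(p)) return(sprintf("%s must be counter-clockwise", nm))
    if (!polygonIsSimple(p)) return(sprintf("%s self-intersects", nm))
    NULL
  }
  msg <- c(msg, chkPoly(object@lumen, "lumen"), chkPoly(object@eem, "eem"))
  if (!length(msg)) {
    if (!all(pointsInPolygon(object@lumen, object@eem)))
      msg <- c(msg, "lumen contour must lie inside the EEM contour")
    for (cmp in object@components) {
      if (!cmp$tissue %in% c("lipid", "calcium"))
        msg <- c(msg, sprintf("unknown component tissue '%s'", cmp$tissue))
      # vertex-based containment: crescent-shaped components can have
      # their centroid outside themselves (inside the lumen)
      if (!all(pointsInPolygon(cmp$polygon, object@eem)) ||
          any(pointsInPolygon(cmp$polygon, object@lumen)))
        msg <- c(msg, "component polygon must sit in the wall ring")
    }
  }
  if (!object@timepoint %in% c("baseline", "followup"))
    msg <- c(msg, "timepoint must be 'baseline' or 'followup'")
  if (object@pressureMin < 0 || object@pressureMax <= object@pressureMin)
    msg <- c(msg, "need pressureMax > pressureMin >= 0")
  if (object@sliceThickness <= 0) msg <- c(msg, "sliceThickness must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a VesselGeometry
#'
#' @param lumen,eem n x 2 CCW contour matrices (mm).
#' @param components list of `list(tissue, polygon)` plaque inclusions.
#' @param pressureMin,pressureMax luminal pressure range (kPa).
#' @param patientId,sliceId,timepoint identifiers.
#' @param sliceThickness slice thickness (mm).
#' @return A [VesselGeometry-class] object.
#' @examples
#' g <- ringGeometry(rLumen = 1.5, rEem = 2.2)
#' lumenArea(g)
#' @export
vesselGeometry <- function(lumen, eem, components = list(),
                           pressureMin = 10.67, pressureMax = 16.0,
                           patientId = "P1", sliceId = "S1",
                           timepoint = "baseline", sliceThickness = 0.5) {
  new("VesselGeometry",
      patientId = as.character(patientId), sliceId = as.character(sliceId),
      timepoint = timepoint, lumen = ensureCCW(lumen), eem = ensureCCW(eem),
      components = components, pressureMin = pressureMin,
      pressureMax = pressureMax, sliceThickness = sliceThickness)
}

#' Concentric circular benchmark geometry
#'
#' @param rLumen,rEem lumen and EEM radii (mm).
#' @param n vertices per contour.
#' @param ... passed to [vesselGeometry()].
#' @return A [VesselGeometry-class] ring.
#' @export
ringGeometry <- function(rLumen = 1.5, rEem = 2.2, n = 64L, ...) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  vesselGeometry(lumen = cbind(rLumen * cos(th), rLumen * sin(th)),
                 eem = cbind(rEem * cos(th), rEem * sin(th)), ...)
}

#' ReferenceGeometry: stress-free computational reference
#'
#' A [VesselGeometry-class] whose contours have been uniformly shrunk
#' in-plane so that re-inflation to `pressureMin` (with the axial
#' pre-stretch applied) recovers the imaged, pressurized shape.
#'
#' @slot circumferentialShrink applied uniform in-plane scale (0,1].
#' @slot axialStretch axial stretch lambda_z applied during the solve;
#'   1/(1 - 0.05) for the default 5 percent axial shrinkage.
#' @exportClass ReferenceGeometry
setClass("ReferenceGeometry", contains = "VesselGeometry",
  representation(circumferentialShrink = "numeric", axialStretch = "numeric"))

setValidity("ReferenceGeometry", function(object) {
  msg <- character()
  # shrink is expected to be < 1 (imaged shape is pressurized); values
  # slightly above 1 can arise for very stiff walls where the axial
  # pre-stretch outweighs the pressure inflation
  if (object@circumferentialShrink <= 0 || object@circumferentialShrink > 1.5)
    msg <- c(msg, "circumferentialShrink must be in (0, 1.5)")
  if (object@axialStretch <= 0) msg <- c(msg, "axialStretch must be > 0")
  if (length(msg)) msg else TRUE
})

#' VesselMesh: quadratic-triangle mesh of the wall ring
#'
#' Six-node (quadratic) triangles over the ring between lumen and EEM.
#' Element rows list corner nodes 1-3 (CCW) then midside nodes on edges
#' 1-2, 2-3, 3-1. Tissue labels are `"wall"`, `"lipid"` or `"calcium"`.
#'
#' @slot nodes n x 2 coordinates (mm).
#' @slot elements e x 6 integer connectivity.
#' @slot tissue character vector, one label per element.
#' @slot lumenNodes,outerNodes integer node indices on the two
#'   boundaries (corner and midside).
#' @slot lumenEdges m x 3 integer matrix of quadratic boundary edges on
#'   the lumen, ordered CCW around the cavity: (start, end, midside).
#' @exportClass VesselMesh
setClass("VesselMesh",
  representation(nodes = "matrix", elements = "matrix", tissue = "character",
                 lumenNodes = "integer", outerNodes = "integer",
                 lumenEdges = "matrix"))

setValidity("VesselMesh", function(object) {
  msg <- character()
  if (ncol(object@elements) != 6)
    msg <- c(msg, "elements must have 6 columns")
  if (length(object@tissue) != nrow(object@elements))
    msg <- c(msg, "one tissue label per element required")
  if (!all(object@tissue %in% c("wall", "lipid", "calcium")))
    msg <- c(msg, "tissue labels must be wall/lipid/calcium")
  a <- elementAreas(object)
  if (any(a <= 0)) msg <- c(msg, "all elements must have positive area")
  if (!length(object@lumenNodes)) msg <- c(msg, "empty lumen boundary")
  if (length(msg)) msg else TRUE
})

#' FESolution: converged inflation state of a slice
#'
#' Displacements and recovered nodal fields from a static finite-strain
#' solve at one luminal pressure. `stress` is the nodal in-plane maximum
#' principal Cauchy stress (kPa); `strain` the nodal in-plane maximum
#' principal Green-Lagrange strain.
#'
#' @slot mesh the [VesselMesh-class] solved on.
#' @slot displacement n x 2 nodal displacements (mm).
#' @slot stress,strain nodal fields (length n).
#' @slot pressure applied luminal pressure (kPa).
#' @slot lumenArea,wallArea deformed areas (mm^2).
#' @slot converged logical; `iterations` total Newton iterations.
#' @exportClass FESolution
setClass("FESolution",
  representation(mesh = "VesselMesh", displacement = "matrix",
                 stress = "numeric", strain = "numeric", pressure = "numeric",
                 lumenArea = "numeric", wallArea = "numeric",
                 converged = "logical", iterations = "integer"))

setValidity("FESolution", function(object) {
  msg <- character()
  if (nrow(object@displacement) != nrow(object@mesh@nodes))
    msg <- c(msg, "displacement/node count mismatch")
  if (!all(is.finite(object@displacement)) || !all(is.finite(object@stress)) ||
      !all(is.finite(object@strain)))
    msg <- c(msg, "solution fields must be finite")
  if (object@lumenArea <= 0) msg <- c(msg, "deformed lumen area must be > 0")
  if (length(msg)) msg else TRUE
})

#' MaterialParams: modified Mooney-Rivlin parameter set
#'
#' Strain energy (deviatoric invariants, see the methods vignette):
#' \deqn{W = c_1(\bar I_1-3)+c_2(\bar I_2-3)+D_1[e^{D_2(\bar I_1-3)}-1]
#'       + \frac{K_1}{K_2}[e^{K_2(I_4-1)^2}-1] + \kappa (J-1)^2}
#' with the anisotropic \eqn{I_4} term active only when
#' `anisotropic = TRUE` (fibres circumferential).
#'
#' @slot c1,c2,D1 kPa; @slot D2,K2 unitless; @slot K1 kPa.
#' @slot kappaVol volumetric penalty modulus (kPa).
#' @slot anisotropic logical.
#' @exportClass MaterialParams
setClass("MaterialParams",
  representation(c1 = "numeric", c2 = "numeric", D1 = "numeric",
                 D2 = "numeric", K1 = "numeric", K2 = "numeric",
                 kappaVol = "numeric", anisotropic = "logical"))

setValidity("MaterialParams", function(object) {
  msg <- character()
  if (object@kappaVol <= 0) msg <- c(msg, "kappaVol must be > 0")
  if (object@anisotropic && (object@K2 <= 0))
    msg <- c(msg, "K2 must be > 0 for the anisotropic term")
  if (object@D1 != 0 && object@D2 <= 0)
    msg <- c(msg, "D2 must be > 0 when D1 != 0")
  if (length(msg)) msg else TRUE
})

#' ConfusionCounts: 2 x 2 classification outcome
#'
#' @slot tp,fn,fp,tn counts; @slot positive the class treated as
#'   positive in the sensitivity/specificity/PPV/NPV definitions.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "numeric", fn = "numeric", fp = "numeric",
                 tn = "numeric", positive = "character"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fn, object@fp, object@tn)
  if (any(v < 0) || any(v != round(v))) return("counts must be non-negative integers")
  if (sum(v) == 0) return("empty confusion matrix")
  TRUE
})

#' RFResult: tuned random-forest progression classifier
#'
#' @slot mtry,ntree chosen hyperparameters.
#' @slot oobError out-of-bag misclassification rate (percent).
#' @slot importance named mean-decrease-Gini vector over all factors.
#' @slot selected factor names retained by backward elimination,
#'   ordered by importance.
#' @slot confusion a [ConfusionCounts-class] from OOB predictions.
#' @slot metrics named numeric: accuracy, sensitivity, specificity,
#'   ppv, npv (percent).
#' @slot forest the fitted [randomForest::randomForest] object.
#' @exportClass RFResult
setClass("RFResult",
  representation(mtry = "numeric", ntree = "numeric", oobError = "numeric",
                 importance = "numeric", selected = "character",
                 confusion = "ConfusionCounts", metrics = "numeric",
                 forest = "ANY"))
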