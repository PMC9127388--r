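#' Accessors for vessel geometry and solution objects
#'
#' @param object a package S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lumenContour", function(object) standardGeneric("lumenContour"))
#' @rdname accessors
#' @export
setGeneric("eemContour", function(object) standardGeneric("eemContour"))
#' @rdname accessors
#' @export
setGeneric("plaqueComponents", function(object) standardGeneric("plaqueComponents"))
#' @rdname accessors
#' @export
setGeneric("pressureRange", function(object) standardGeneric("pressureRange"))
#' @rdname accessors
#' @export
setGeneric("lumenArea", function(object) standardGeneric("lumenArea"))
#' @rdname accessors
#' @export
setGeneric("eemArea", function(object) standardGeneric("eemArea"))
#' @rdname accessors
#' @export
setGeneric("wallArea", function(object) standardGeneric("wallArea"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("sliceId", function(object) standardGeneric("sliceId"))

setMethod("lumenContour", "VesselGeometry", function(object) object@lumen)
setMethod("eemContour", "VesselGeometry", function(object) object@eem)
setMethod("plaqueComponents", "VesselGeometry", function(object) object@components)
setMethod("pressureRange", "VesselGeometry",
          function(object) c(min = object@pressureMin, max = object@pressureMax))
setMethod("lumenArea", "VesselGeometry", function(object) polygonArea(object@lumen))
setMethod("eemArea", "VesselGeometry", function(object) polygonArea(object@eem))
setMethod("wallArea", "VesselGeometry",
          function(object) polygonArea(object@eem) - polygonArea(object@lumen))
setMethod("patientId", "VesselGeometry", function(object) object@patientId)
setMethod("sliceId", "VesselGeometry", function(object) object@sliceId)

setMethod("lumenArea", "FESolution", function(object) object@lumenArea)
setMethod("wallArea", "FESolution", function(object) object@wallArea)

#' @rdname accessors
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))
#' @rdname accessors
#' @export
setGeneric("elementTissue", function(object) standardGeneric("elementTissue"))
setMethod("nodeCoords", "VesselMesh", function(object) object@nodes)
setMethod("elementTissue", "VesselMesh", function(object) object@tissue)

#' @rdname accessors
#' @export
setGeneric("nodalStress", function(object) standardGeneric("nodalStress"))
#' @rdname accessors
#' @export
setGeneric("nodalStrain", function(object) standardGeneric("nodalStrain"))
setMethod("nodalStress", "FESolution", function(object) object@stress)
setMethod("nodalStrain", "FESolution", function(object) object@strain)

setMethod("show", "VesselGeometry", function(object) {
  cat(sprintf("%s slice %s/%s (%s)\n", class(object), object@patientId,
              object@sliceId, object@timepoint))
  cat(sprintf("  lumen area %.3f mm^2, EEM area %.3f mm^2, PB %.1f%%\n",
              lumenArea(object), eemArea(object),
              100 * wallArea(object) / eemArea(object)))
  if (length(object@components))
    cat("  components:", paste(vapply(object@components, `[[`, "", "tissue"),
                               collapse = ", "), "\n")
  cat(sprintf("  pressure %.2f-%.2f kPa, thickness %.2f mm\n",
              object@pressureMin, object@pressureMax, object@sliceThickness))
})

setMethod("show", "ReferenceGeometry", function(object) {
  callNextMethod()
  cat(sprintf("  circumferential shrink %.4f, axial stretch %.4f\n",
              object@circumferentialShrink, object@axialStretch))
})

setMethod("show", "VesselMesh", function(object) {
  cat(sprintf("VesselMesh: %d nodes, %d quadratic triangles (%s)\n",
              nrow(object@nodes), nrow(object@elements),
              paste(sprintf("%s: %d", names(table(object@tissue)),
                            table(object@tissue)), collapse = ", ")))
})

setMethod("show", "FESolution", function(object) {
  cat(sprintf("FESolution at %.2f kPa (%s, %d Newton iterations)\n",
              object@pressure, if (object@converged) "converged" else "NOT converged",
              object@iterations))
  cat(sprintf("  lumen area %.3f mm^2, wall area %.3f mm^2\n",
              object@lumenArea, object@wallArea))
  cat(sprintf("  max principal stress %.2f kPa, max principal strain %.4f\n",
              max(object@stress), max(object@strain)))
})

setMethod("show", "MaterialParams", function(object) {
  cat(sprintf("MaterialParams: c1=%g c2=%g D1=%g D2=%g%s, kappa=%g kPa\n",
              object@c1, object@c2, object@D1, object@D2,
              if (object@anisotropic) sprintf(" K1=%g K2=%g", object@K1, object@K2)
              else "", object@kappaVol))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (positive class:", object@positive, ")\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, byrow = TRUE,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
})

setMethod("show", "RFResult", function(object) {
  cat(sprintf("RFResult: mtry=%d, ntree=%d, OOB error %.2f%%\n",
              object@mtry, object@ntree, object@oobError))
  cat("  selected factors:", paste(object@selected, collapse = ", "), "\n")
  cat(sprintf("  accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              object@metrics["accuracy"], object@metrics["sensitivity"],
              object@metrics["specificity"]))
})
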