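# Accessors and show methods for the S4 containers.

#' @describeIn regionOfInterest ROI label accessor.
#' @export
setGeneric("roiLabel", function(object) standardGeneric("roiLabel"))
#' @export
setMethod("roiLabel", "RegionOfInterest", function(object) object@label)

#' @describeIn regionOfInterest section identifier accessor.
#' @export
setGeneric("sectionId", function(object) standardGeneric("sectionId"))
#' @export
setMethod("sectionId", "RegionOfInterest", function(object) object@sectionId)
#' @export
setMethod("sectionId", "EstimateRecord", function(object) object@sectionId)

#' Numerical density accessor
#' @param object an \linkS4class{EstimateRecord}.
#' @export
setGeneric("qA", function(object) standardGeneric("qA"))
#' @export
setMethod("qA", "EstimateRecord", function(object) object@qA)

#' Area-fraction accessor
#' @param object an \linkS4class{EstimateRecord}.
#' @export
setGeneric("areaFractionOf", function(object) standardGeneric("areaFractionOf"))
#' @export
setMethod("areaFractionOf", "EstimateRecord", function(object)
  object@areaFraction)

#' Profile table accessor
#' @param object a \linkS4class{CellProfiles}.
#' @export
setGeneric("profileData", function(object) standardGeneric("profileData"))
#' @export
setMethod("profileData", "CellProfiles", function(object) object@data)

#' Image raster accessor
#' @param object a \linkS4class{StainImage}.
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @export
setMethod("imageData", "StainImage", function(object) object@data)

#' Pixel size accessor
#' @param object a \linkS4class{StainImage}.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @export
setMethod("pixelSize", "StainImage", function(object) object@pixelSize)

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest '%s' (section %s): %d vertices, %d hole(s), %.3f mm^2\n",
              object@label, object@sectionId, nrow(object@vertices),
              length(object@holes), polygonArea(object)))
})

setMethod("show", "CellProfiles", function(object) {
  d <- object@data
  cat(sprintf("CellProfiles: %d profiles", nrow(d)))
  if (nrow(d))
    cat(sprintf(" (%s; mean equivalent diameter %.1f um)",
                paste(sprintf("%s: %d", names(table(d$marker)),
                              as.integer(table(d$marker))), collapse = ", "),
                mean(2 * sqrt(d$a * d$b))))
  cat("\n")
})

setMethod("show", "SamplingDesign", function(object) {
  cat(sprintf("SamplingDesign: %d FOVs (%s density), FOV %.0fx%.0f um, frame %.0f um^2, grid %.2f um, seed %d\n",
              object@nFov, object@densityClass, object@fovWidth,
              object@fovHeight, object@frameWidth * object@frameHeight,
              object@gridSpacing, object@seed))
})

setMethod("show", "StainImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("StainImage (%s): %d x %d px at %.3f um/px (%.2f x %.2f mm)\n",
              object@marker, d[1], d[2], object@pixelSize,
              d[2] * object@pixelSize / 1e3, d[1] * object@pixelSize / 1e3))
})

setMethod("show", "DetectionModel", function(object) {
  cat(sprintf("DetectionModel (schema %s): cell classifier %s, artifact classifier %s\n",
              object@version,
              if (length(object@cell)) "fitted" else "untrained",
              if (length(object@artifact)) "fitted" else "untrained"))
  cat(sprintf("  blob radius %.1f-%.1f um, min area %.0f um^2, weak-stain cutoff %.2f\n",
              object@blobRadiusRange[1], object@blobRadiusRange[2],
              object@minObjectArea, object@weakStainCutoff))
})

setMethod("show", "EstimateRecord", function(object) {
  cat(sprintf("EstimateRecord [%s] %s/%s (%s): Q_A = %.1f cells/mm^2, AF = %.4f\n",
              object@method, object@sectionId, object@roiLabel,
              object@marker, object@qA, object@areaFraction))
})
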