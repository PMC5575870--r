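#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Region of interest on a tissue section
#'
#' A labeled planar polygon in micrometer coordinates, optionally with
#' exclusion holes. Coordinates follow the image convention: origin at the
#' slide top-left, x increasing rightward, y increasing downward. The outer
#' ring is normalized to positive signed area and holes to negative signed
#' area on construction, so areas are unambiguous.
#'
#' @slot vertices numeric matrix (n x 2) of outer-ring vertices in um,
#'   columns x and y; the ring is implicitly closed.
#' @slot holes list of numeric matrices, interior exclusion polygons (um).
#' @slot label character, one of \code{"central"} or \code{"invasive"}.
#' @slot sectionId character identifier of the parent section.
#'
#' @export
setClass("RegionOfInterest",
  representation(
    vertices  = "matrix",
    holes     = "list",
    label     = "character",
    sectionId = "character"
  )
)

setValidity("RegionOfInterest", function(object) {
  msg <- character()
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    msg <- c(msg, "vertices must be a numeric n x 2 matrix")
  else {
    if (nrow(v) < 3L)
      msg <- c(msg, "invalid geometry: outer ring needs at least 3 vertices")
    else {
      if (.signedArea(v) <= 0)
        msg <- c(msg, "outer ring must have positive area")
      if (.ringSelfIntersects(v))
        msg <- c(msg, "invalid geometry: outer ring self-intersects")
    }
  }
  for (h in object@holes) {
    if (!is.numeric(h) || ncol(h) != 2L || nrow(h) < 3L)
      msg <- c(msg, "each hole must be a numeric matrix with >= 3 vertices")
  }
  if (!object@label %in% c("central", "invasive"))
    msg <- c(msg, "label must be 'central' or 'invasive'")
  if (length(msg)) msg else TRUE
})

#' Set of annotated lymphocyte profiles
#'
#' Cell profiles are modeled as ellipses (disks when the two semi-axes are
#' equal): this keeps the 2D unbiased counting rule exact, since any ellipse
#' maps to the unit disk under an affine transform that also maps frame edges
#' to line segments. Profiles carry the annotations an observer would use:
#' marker class, stain strength, and whether a nucleus is discernible.
#'
#' @slot data data.frame with columns \code{x}, \code{y} (centroid, um),
#'   \code{a}, \code{b} (semi-axes, um), \code{theta} (orientation, radians),
#'   \code{marker} ("CD3"/"CD8"), \code{stainStrength} (in [0,1]) and
#'   \code{nucleusVisible} (logical).
#'
#' @export
setClass("CellProfiles", representation(data = "data.frame"))

setValidity("CellProfiles", function(object) {
  d <- object@data
  need <- c("x", "y", "a", "b", "theta", "marker", "stainStrength",
            "nucleusVisible")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d) && (any(d$a <= 0) || any(d$b <= 0)))
    return("semi-axes must be positive")
  if (nrow(d) && (any(d$stainStrength < 0) || any(d$stainStrength > 1)))
    return("stainStrength must lie in [0, 1]")
  TRUE
})

#' Stereological sampling design
#'
#' Bundles the test system: the counting-frame template, the point grid, the
#' target number of fields of view (FOVs), and the seed controlling the two
#' random lattice phases (FOV lattice and point grid).
#'
#' @slot nFov integer, target number of FOVs whose centers fall in the ROI.
#' @slot fovWidth,fovHeight FOV dimensions in um.
#' @slot frameWidth,frameHeight counting-frame dimensions in um (frame is
#'   centered in the FOV).
#' @slot gridSpacing point-grid spacing in um (area per point = spacing^2).
#' @slot densityClass "low", "medium" or "high"; maps to 100/40/25 FOVs.
#' @slot stainThreshold minimum stain strength for a profile to be eligible.
#' @slot seed integer seed.
#'
#' @export
setClass("SamplingDesign",
  representation(
    nFov           = "integer",
    fovWidth       = "numeric",
    fovHeight      = "numeric",
    frameWidth     = "numeric",
    frameHeight    = "numeric",
    gridSpacing    = "numeric",
    densityClass   = "character",
    stainThreshold = "numeric",
    seed           = "integer"
  )
)

setValidity("SamplingDesign", function(object) {
  msg <- character()
  if (object@nFov < 1L) msg <- c(msg, "nFov must be >= 1")
  if (object@fovWidth <= 0 || object@fovHeight <= 0)
    msg <- c(msg, "FOV dimensions must be positive")
  if (object@frameWidth > object@fovWidth ||
      object@frameHeight > object@fovHeight)
    msg <- c(msg, "counting frame must fit inside the FOV")
  if (object@gridSpacing <= 0) msg <- c(msg, "gridSpacing must be positive")
  if (!object@densityClass %in% c("low", "medium", "high"))
    msg <- c(msg, "densityClass must be low/medium/high")
  if (length(msg)) msg else TRUE
})

#' RGB section image with pixel geometry
#'
#' @slot data numeric array H x W x 3, channel values in [0, 255]; rows are
#'   image rows (y), columns are x.
#' @slot pixelSize um per pixel (isotropic).
#' @slot marker stain marker of the section ("CD3" or "CD8").
#'
#' @export
setClass("StainImage",
  representation(data = "array", pixelSize = "numeric", marker = "character")
)

setValidity("StainImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != 3L)
    return("data must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("image must be non-empty")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  rng <- range(object@data)
  if (rng[1] < 0 || rng[2] > 255) return("channel values must lie in [0, 255]")
  TRUE
})

#' Parameters of the automated detection pipeline
#'
#' Holds the two linear Bayesian (shared-covariance Gaussian) pixel
#' classifiers -- the low-resolution artifact classifier and the
#' full-resolution positive/negative cell classifier -- together with the
#' object post-filter thresholds and pipeline constants. Fit with
#' \code{\link{trainDetectionModel}}; persistable as JSON.
#'
#' @slot cell list with elements \code{classes}, \code{means} (class x
#'   feature matrix), \code{cov} (pooled covariance), \code{priors},
#'   \code{features}; empty until trained.
#' @slot artifact same structure for the artifact classes; empty until
#'   trained.
#' @slot blobRadiusRange numeric length-2, cell radius range in um for the
#'   blob enhancement filter.
#' @slot minObjectArea minimum object area in um^2.
#' @slot weakStainCutoff minimum mean red chromaticity of an accepted object.
#' @slot lowresPixelSize target pixel size (um) of the artifact-segmentation
#'   resolution.
#' @slot meanFilterWindow side (pixels) of the box mean filter used in the
#'   feature stack.
#' @slot watershedTolerance minimum normalized peak prominence for the
#'   watershed split.
#' @slot version schema version string.
#'
#' @export
setClass("DetectionModel",
  representation(
    cell             = "list",
    artifact         = "list",
    blobRadiusRange  = "numeric",
    minObjectArea    = "numeric",
    weakStainCutoff  = "numeric",
    lowresPixelSize  = "numeric",
    meanFilterWindow = "numeric",
    watershedTolerance = "numeric",
    version          = "character"
  ),
  prototype(
    cell = list(), artifact = list(),
    blobRadiusRange = c(3, 5),
    minObjectArea = 12,
    weakStainCutoff = 0.38,
    lowresPixelSize = 9,
    meanFilterWindow = 5,
    watershedTolerance = 0.05,
    version = "1"
  )
)

setValidity("DetectionModel", function(object) {
  msg <- character()
  if (length(object@blobRadiusRange) != 2L ||
      any(object@blobRadiusRange <= 0) ||
      diff(object@blobRadiusRange) < 0)
    msg <- c(msg, "blobRadiusRange must be an increasing positive pair")
  for (nm in c("cell", "artifact")) {
    m <- slot(object, nm)
    if (length(m)) {
      if (abs(sum(m$priors) - 1) > 1e-8)
        msg <- c(msg, sprintf("%s priors must sum to 1", nm))
      ev <- eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev <= 0))
        msg <- c(msg, sprintf("%s covariance must be positive-definite", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-ROI quantification result
#'
#' One record per (section, ROI, marker, method): the numerical density
#' Q_A (cells/mm^2), the area fraction, and the raw tallies they were
#' computed from.
#'
#' @slot method "stereology" or "image_analysis".
#' @slot sectionId,roiLabel,marker identifiers.
#' @slot qA numerical density, cells per mm^2.
#' @slot areaFraction dimensionless area fraction in [0, 1].
#' @slot raw data.frame of per-FOV tallies (stereology) or per-image counts
#'   (image analysis), kept for audit.
#' @slot nFov number of fields contributing.
#' @slot seed seed used (NA for the deterministic image pipeline).
#'
#' @export
setClass("EstimateRecord",
  representation(
    method       = "character",
    sectionId    = "character",
    roiLabel     = "character",
    marker       = "character",
    qA           = "numeric",
    areaFraction = "numeric",
    raw          = "data.frame",
    nFov         = "integer",
    seed         = "integer"
  )
)

setValidity("EstimateRecord", function(object) {
  msg <- character()
  if (!object@method %in% c("stereology", "image_analysis"))
    msg <- c(msg, "method must be 'stereology' or 'image_analysis'")
  if (!is.na(object@qA) && object@qA < 0) msg <- c(msg, "qA must be >= 0")
  if (!is.na(object@areaFraction) &&
      (object@areaFraction < 0 || object@areaFraction > 1))
    msg <- c(msg, "areaFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
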