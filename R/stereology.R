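# Design-based stereology: systematic uniform random sampling (SURS) of
# fields of view, the 2D unbiased counting frame, point-grid counting, and
# the two estimators (numerical density Q_A and area fraction).

#' Construct a set of cell profiles
#'
#' @param x numeric vector of centroid x (um), or a data.frame already holding
#'   the profile columns.
#' @param y centroid y (um).
#' @param radius disk radius (um); shorthand for \code{a = b = radius}.
#' @param a,b ellipse semi-axes (um).
#' @param theta ellipse orientation (radians).
#' @param marker "CD3" or "CD8".
#' @param stainStrength stain strength in [0, 1].
#' @param nucleusVisible logical; whether a nucleus is discernible.
#' @return A \linkS4class{CellProfiles}.
#' @export
cellProfiles <- function(x, y = NULL, radius = NULL, a = NULL, b = NULL,
                         theta = 0, marker = "CD3", stainStrength = 1,
                         nucleusVisible = TRUE) {
  if (is.data.frame(x)) {
    d <- x
    if (!is.null(d$radius) && is.null(d$a)) { d$a <- d$radius; d$b <- d$radius }
    for (col in c("theta", "stainStrength")) if (is.null(d[[col]]))
      d[[col]] <- c(theta = 0, stainStrength = 1)[[col]]
    if (is.null(d$marker)) d$marker <- marker
    if (is.null(d$nucleusVisible)) d$nucleusVisible <- TRUE
  } else {
    n <- length(x)
    if (!is.null(radius)) { a <- radius; b <- radius }
    d <- data.frame(
      x = x, y = y, a = rep_len(a, n), b = rep_len(b, n),
      theta = rep_len(theta, n), marker = rep_len(marker, n),
      stainStrength = rep_len(stainStrength, n),
      nucleusVisible = rep_len(nucleusVisible, n)
    )
  }
  d$radius <- NULL
  new("CellProfiles", data = d[, c("x", "y", "a", "b", "theta", "marker",
                                   "stainStrength", "nucleusVisible")])
}

#' Stereological sampling design
#'
#' Defaults follow the test system used for TIL quantification: counting-frame
#' area 1575 um^2 for CD3 and 2925 um^2 for CD8, a square point grid with
#' 559.69 um^2 per point, 130 x 130 um fields of view, and the density-class
#' to FOV-number mapping low/medium/high -> 100/40/25 chosen so that roughly
#' 200 positive profiles are counted per section.
#'
#' @param marker "CD3" or "CD8"; selects the default frame area.
#' @param densityClass "low", "medium" or "high".
#' @param nFov target number of FOVs; overrides the density-class mapping.
#' @param frameArea counting-frame area in um^2 (square frame).
#' @param areaPerPoint point-grid area per point in um^2.
#' @param fovWidth,fovHeight FOV dimensions in um.
#' @param stainThreshold minimum stain strength for an eligible profile.
#' @param seed integer seed for the two lattice phases.
#' @return A \linkS4class{SamplingDesign}.
#' @export
samplingDesign <- function(marker = "CD3",
                           densityClass = c("medium", "low", "high"),
                           nFov = NULL, frameArea = NULL,
                           areaPerPoint = 559.69,
                           fovWidth = 130, fovHeight = 130,
                           stainThreshold = 0.3, seed = 1L) {
  densityClass <- match.arg(densityClass)
  if (is.null(nFov))
    nFov <- c(low = 100L, medium = 40L, high = 25L)[[densityClass]]
  if (is.null(frameArea))
    frameArea <- c(CD3 = 1575, CD8 = 2925)[[marker]]
  side <- sqrt(frameArea)
  new("SamplingDesign",
      nFov = as.integer(nFov), fovWidth = fovWidth, fovHeight = fovHeight,
      frameWidth = side, frameHeight = side,
      gridSpacing = sqrt(areaPerPoint), densityClass = densityClass,
      stainThreshold = stainThreshold, seed = as.integer(seed))
}

# Eligibility of profiles under the observer rule: discernible nucleus and
# stain strength at or above the threshold.
.eligible <- function(cells, stainThreshold) {
  d <- cells@data
  d$nucleusVisible & d$stainStrength >= stainThreshold
}

#' Systematic uniform random sampling of fields of view
#'
#' Lays a square FOV lattice over the ROI with step chosen so that the
#' expected number of lattice points falling inside the ROI equals the design
#' target, and a lattice phase drawn uniformly in [0, step)^2. Every point of
#' the ROI then has equal inclusion probability (the SURS property). FOVs are
#' returned in raster order.
#'
#' @param roi A \linkS4class{RegionOfInterest}.
#' @param design A \linkS4class{SamplingDesign}.
#' @return data.frame with one row per FOV: center (\code{cx}, \code{cy}),
#'   top-left origin (\code{x0}, \code{y0}), dimensions, and lattice indices;
#'   the lattice step is attached as attribute \code{"step"}.
#' @export
sampleFOVs <- function(roi, design) {
  stopifnot(is(roi, "RegionOfInterest"), is(design, "SamplingDesign"))
  areaUm2 <- polygonArea(roi) * 1e6
  fw <- design@fovWidth; fh <- design@fovHeight
  if (areaUm2 < fw * fh) {
    warning("ROI smaller than one FOV; returning the single FOV covering it")
    bb <- .roiBBox(roi)
    cx <- (bb[1] + bb[3]) / 2; cy <- (bb[2] + bb[4]) / 2
    out <- data.frame(cx = cx, cy = cy, x0 = cx - fw / 2, y0 = cy - fh / 2,
                      width = fw, height = fh, ix = 0L, iy = 0L)
    attr(out, "step") <- max(bb[3] - bb[1], bb[4] - bb[2])
    return(out)
  }
  step <- sqrt(areaUm2 / design@nFov)
  phase <- .withSeed(.fovPhaseSeed(design@seed), stats::runif(2) * step)
  bb <- .roiBBox(roi)
  kx <- seq(floor((bb[1] - phase[1]) / step) - 1L,
            ceiling((bb[3] - phase[1]) / step) + 1L)
  ky <- seq(floor((bb[2] - phase[2]) / step) - 1L,
            ceiling((bb[4] - phase[2]) / step) + 1L)
  centers <- expand.grid(ix = kx, iy = ky)      # ix varies fastest: raster order
  centers <- centers[order(centers$iy, centers$ix), ]
  cx <- phase[1] + centers$ix * step
  cy <- phase[2] + centers$iy * step
  keep <- pointInROI(cbind(cx, cy), roi)
  if (!any(keep)) {
    warning("no lattice point fell inside the ROI; returning one covering FOV")
    ctr <- c(mean(roi@vertices[, 1L]), mean(roi@vertices[, 2L]))
    out <- data.frame(cx = ctr[1], cy = ctr[2], x0 = ctr[1] - fw / 2,
                      y0 = ctr[2] - fh / 2, width = fw, height = fh,
                      ix = 0L, iy = 0L)
    attr(out, "step") <- step
    return(out)
  }
  out <- data.frame(cx = cx[keep], cy = cy[keep],
                    x0 = cx[keep] - fw / 2, y0 = cy[keep] - fh / 2,
                    width = fw, height = fh,
                    ix = centers$ix[keep], iy = centers$iy[keep])
  rownames(out) <- NULL
  attr(out, "step") <- step
  out
}

# ---- 2D unbiased counting frame ------------------------------------------
#
# Frame rectangle [x0, x1] x [y0, y1] in image coordinates (y down; the
# visual bottom edge is y = y1). The forbidden (exclusion) set is the
# classical staircase: the left edge extended upward beyond the top-left
# corner, the left edge, the bottom edge, and the extension downward below
# the bottom-right corner. A profile is counted iff it intersects the open
# frame rectangle and does not touch the forbidden set; touching only the
# inclusion edges (top, right) does not exclude. Over a complete tiling of
# frames this counts every profile exactly once.

.FORBIDDEN_EXT <- 1e7   # "infinite" extension length (um)

# counted status of circle profiles (vectorized): centers (cx, cy), radius r
.countCircles <- function(cx, cy, r, x0, y0, x1, y1) {
  # distance from center to closed frame rectangle (0 if inside)
  dx <- pmax(x0 - cx, 0, cx - x1)
  dy <- pmax(y0 - cy, 0, cy - y1)
  intersects <- sqrt(dx^2 + dy^2) < r
  # distance to the three forbidden segments
  d1 <- .distPointSegV(cx, cy, x0, y1, x0, y1 - .FORBIDDEN_EXT)  # left + up
  d2 <- .distPointSegV(cx, cy, x0, y1, x1, y1)                   # bottom
  d3 <- .distPointSegV(cx, cy, x1, y1, x1, y1 + .FORBIDDEN_EXT)  # down-right
  touches <- pmin(d1, d2, d3) <= r
  intersects & !touches
}

# vectorized point-to-segment distance
.distPointSegV <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  qx <- ax + t * dx; qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

# counted status of one ellipse profile: map the ellipse to the unit disk;
# frame corners and forbidden segments map to segments, so the test reduces
# to origin-to-segment distances.
.countEllipse <- function(cx, cy, a, b, theta, x0, y0, x1, y1) {
  ct <- cos(theta); st <- sin(theta)
  tf <- function(px, py) {
    u <- ct * (px - cx) + st * (py - cy)
    v <- -st * (px - cx) + ct * (py - cy)
    c(u / a, v / b)
  }
  q <- list(tf(x0, y0), tf(x1, y0), tf(x1, y1), tf(x0, y1))  # TL TR BR BL
  # origin-in-convex-quad: same sign of cross products around the ring
  cr <- vapply(1:4, function(i) {
    p1 <- q[[i]]; p2 <- q[[i %% 4 + 1]]
    (p2[1] - p1[1]) * (-p1[2]) - (p2[2] - p1[2]) * (-p1[1])
  }, numeric(1))
  insideQuad <- all(cr >= 0) || all(cr <= 0)
  dEdge <- min(vapply(1:4, function(i)
    .distOriginSeg(q[[i]], q[[i %% 4 + 1]]), numeric(1)))
  intersects <- insideQuad || dEdge < 1
  f1 <- tf(x0, y1); f2 <- tf(x0, y1 - .FORBIDDEN_EXT)
  f3 <- tf(x1, y1); f4 <- tf(x1, y1 + .FORBIDDEN_EXT)
  dForb <- min(.distOriginSeg(f1, f2), .distOriginSeg(f1, f3),
               .distOriginSeg(f3, f4))
  intersects && dForb > 1
}

#' Apply the 2D unbiased counting frame
#'
#' Counts profiles by the unbiased counting rule: a profile is counted iff it
#' intersects the open frame rectangle and does not touch the exclusion
#' lines -- the left edge, the bottom edge, and their extensions (upward from
#' the top-left corner, downward from the bottom-right corner). Touching only
#' the inclusion edges (top, right) is allowed. Only eligible profiles
#' (discernible nucleus, stain strength at or above the threshold) enter the
#' count, mirroring the observer rule.
#'
#' @param frame numeric length-4: \code{c(x0, y0, x1, y1)} in um (y down, so
#'   \code{y1} is the visual bottom edge).
#' @param cells A \linkS4class{CellProfiles}.
#' @param stainThreshold eligibility threshold on stain strength.
#' @return Integer indices (into \code{cells}) of the counted profiles.
#' @export
applyCountingFrame <- function(frame, cells, stainThreshold = 0.3) {
  stopifnot(length(frame) == 4L, is(cells, "CellProfiles"))
  d <- cells@data
  if (!nrow(d)) return(integer())
  elig <- .eligible(cells, stainThreshold)
  idx <- which(elig)
  if (!length(idx)) return(integer())
  x0 <- frame[1]; y0 <- frame[2]; x1 <- frame[3]; y1 <- frame[4]
  # cheap prefilter: centroid within frame bbox dilated by the major axis
  rmax <- pmax(d$a[idx], d$b[idx])
  near <- d$x[idx] > x0 - rmax & d$x[idx] < x1 + rmax &
          d$y[idx] > y0 - rmax & d$y[idx] < y1 + rmax
  idx <- idx[near]
  if (!length(idx)) return(integer())
  isCircle <- d$a[idx] == d$b[idx]
  counted <- logical(length(idx))
  if (any(isCircle)) {
    ci <- idx[isCircle]
    counted[isCircle] <- .countCircles(d$x[ci], d$y[ci], d$a[ci],
                                       x0, y0, x1, y1)
  }
  for (k in which(!isCircle)) {
    i <- idx[k]
    counted[k] <- .countEllipse(d$x[i], d$y[i], d$a[i], d$b[i], d$theta[i],
                                x0, y0, x1, y1)
  }
  idx[counted]
}

# grid test points of one FOV: cross corners at offset + k * spacing, kept
# with the half-open FOV membership [x0, x0+w) x [y0, y0+h)
.gridPointsInFOV <- function(fov, spacing, offset) {
  kx <- seq(ceiling((fov$x0 - offset[1]) / spacing),
            floor((fov$x0 + fov$width - offset[1]) / spacing))
  ky <- seq(ceiling((fov$y0 - offset[2]) / spacing),
            floor((fov$y0 + fov$height - offset[2]) / spacing))
  px <- offset[1] + kx * spacing
  py <- offset[2] + ky * spacing
  px <- px[px >= fov$x0 & px < fov$x0 + fov$width]
  py <- py[py >= fov$y0 & py < fov$y0 + fov$height]
  if (!length(px) || !length(py)) return(matrix(numeric(), ncol = 2L))
  as.matrix(expand.grid(x = px, y = py))
}

# are points inside any eligible positive profile? (closed ellipses)
.pointsInProfiles <- function(pts, cells, stainThreshold) {
  if (!nrow(pts)) return(logical())
  d <- cells@data[.eligible(cells, stainThreshold), , drop = FALSE]
  hit <- rep(FALSE, nrow(pts))
  if (!nrow(d)) return(hit)
  # only profiles whose bbox can reach the point set
  rmax <- pmax(d$a, d$b)
  near <- d$x > min(pts[, 1L]) - rmax & d$x < max(pts[, 1L]) + rmax &
          d$y > min(pts[, 2L]) - rmax & d$y < max(pts[, 2L]) + rmax
  d <- d[near, , drop = FALSE]
  if (!nrow(d)) return(hit)
  for (i in seq_len(nrow(d))) {
    ct <- cos(d$theta[i]); st <- sin(d$theta[i])
    u <- ct * (pts[, 1L] - d$x[i]) + st * (pts[, 2L] - d$y[i])
    v <- -st * (pts[, 1L] - d$x[i]) + ct * (pts[, 2L] - d$y[i])
    hit <- hit | ((u / d$a[i])^2 + (v / d$b[i])^2 <= 1)
  }
  hit
}

#' Point-grid counting within one field of view
#'
#' Places the point grid (test point = the upper-right corner of each cross)
#' over the FOV with the given phase and tallies hits: \code{pPositive} = test
#' points covered by a viable positive cell profile, \code{pTumor} = test
#' points on vital tumor tissue (positive cells count as tumor). Points on
#' excluded tissue (necrosis, mucin, clefts, folds, or outside the ROI)
#' contribute to neither tally.
#'
#' @param fov one row of the \code{\link{sampleFOVs}} result (or a list with
#'   \code{x0}, \code{y0}, \code{width}, \code{height}).
#' @param spacing grid spacing in um.
#' @param offset grid phase, length-2 (um).
#' @param cells A \linkS4class{CellProfiles}.
#' @param tissueClassifier function mapping an n x 2 point matrix to a logical
#'   vector (TRUE = vital tumor, FALSE = excluded).
#' @param stainThreshold eligibility threshold.
#' @return list with \code{pPositive}, \code{pTumor}, \code{nPoints}.
#' @export
countGridPoints <- function(fov, spacing, offset, cells, tissueClassifier,
                            stainThreshold = 0.3) {
  pts <- .gridPointsInFOV(fov, spacing, offset)
  if (!nrow(pts))
    return(list(pPositive = 0L, pTumor = 0L, nPoints = 0L))
  vital <- tissueClassifier(pts)
  inCell <- .pointsInProfiles(pts, cells, stainThreshold)
  list(pPositive = sum(vital & inCell), pTumor = sum(vital),
       nPoints = nrow(pts))
}

#' Numerical density estimator Q_A
#'
#' Q_A = sum(Q) / (sum(P) * frame area), where Q are the profiles counted by
#' the unbiased counting frame and P the frame corner points hitting vital
#' tumor tissue; the denominator is the total sampled reference area.
#'
#' @param tallies data.frame of per-FOV tallies with columns \code{q} and
#'   \code{pFrame}.
#' @param frameArea counting-frame area in um^2.
#' @return Numerical density in cells/mm^2.
#' @export
numericalDensity <- function(tallies, frameArea) {
  sQ <- sum(tallies$q); sP <- sum(tallies$pFrame)
  if (sP * frameArea <= 0)
    stop("estimate undefined: no vital reference area was sampled")
  sQ / (sP * frameArea) * 1e6
}

#' Area-fraction estimator
#'
#' AF = sum of grid points hitting positive lymphocytes divided by the sum of
#' grid points hitting vital tumor tissue.
#'
#' @param tallies data.frame with columns \code{pPositive} and \code{pTumor}.
#' @return Dimensionless fraction in [0, 1].
#' @export
areaFraction <- function(tallies) {
  sTum <- sum(tallies$pTumor)
  if (sTum <= 0)
    stop("estimate undefined: no vital-tumor grid points were sampled")
  sum(tallies$pPositive) / sTum
}

#' Tissue classifier from ROI and artifact polygons
#'
#' Returns the point classifier used by the stereology engine: a point is
#' vital tumor iff it lies inside the ROI and outside every artifact polygon.
#'
#' @param roi A \linkS4class{RegionOfInterest}.
#' @param artifacts list of polygons (n x 2 matrices, um) to exclude.
#' @return function(points matrix) -> logical.
#' @export
makeTissueClassifier <- function(roi, artifacts = list()) {
  force(roi); force(artifacts)
  function(pts) {
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
    vital <- pointInROI(pts, roi)
    for (a in artifacts)
      vital <- vital & !.pointsInRing(pts[, 1L], pts[, 2L], a)
    vital
  }
}

#' Run the full stereological estimation on one ROI
#'
#' Composes SURS FOV sampling, the unbiased counting frame, and point-grid
#' counting into an \linkS4class{EstimateRecord}. The counting frame is
#' centered in each FOV; its reference corner point (upper-right corner) is
#' classified as vital/excluded for the Q_A denominator. Emits a warning when
#' fewer than 200 profiles were counted in total (the design aim).
#'
#' @param roi A \linkS4class{RegionOfInterest}.
#' @param cells A \linkS4class{CellProfiles} (annotated observer surrogate).
#' @param design A \linkS4class{SamplingDesign}.
#' @param tissueClassifier optional classifier as from
#'   \code{\link{makeTissueClassifier}}; defaults to "inside the ROI".
#' @param marker marker to count; profiles of other markers are ignored.
#' @param minCount count below which the low-count warning fires.
#' @return An \linkS4class{EstimateRecord} with method \code{"stereology"}.
#' @export
runStereology <- function(roi, cells, design, tissueClassifier = NULL,
                          marker = NULL, minCount = 200L) {
  stopifnot(is(roi, "RegionOfInterest"), is(cells, "CellProfiles"),
            is(design, "SamplingDesign"))
  if (is.null(tissueClassifier))
    tissueClassifier <- makeTissueClassifier(roi)
  d <- cells@data
  if (is.null(marker))
    marker <- if (nrow(d)) as.character(d$marker[1L]) else "CD3"
  cells <- new("CellProfiles", data = d[d$marker == marker, , drop = FALSE])

  fovs <- sampleFOVs(roi, design)
  spacing <- design@gridSpacing
  offset <- .withSeed(.gridPhaseSeed(design@seed), stats::runif(2) * spacing)
  fw <- design@frameWidth; fh <- design@frameHeight

  tallies <- lapply(seq_len(nrow(fovs)), function(i) {
    fov <- fovs[i, ]
    fx0 <- fov$cx - fw / 2; fy0 <- fov$cy - fh / 2
    frame <- c(fx0, fy0, fx0 + fw, fy0 + fh)
    q <- length(applyCountingFrame(frame, cells, design@stainThreshold))
    corner <- matrix(c(frame[3], frame[2]), ncol = 2L)   # upper-right
    pFrame <- as.integer(tissueClassifier(corner))
    g <- countGridPoints(fov, spacing, offset, cells, tissueClassifier,
                         design@stainThreshold)
    data.frame(ix = fov$ix, iy = fov$iy, q = q, pFrame = pFrame,
               pPositive = g$pPositive, pTumor = g$pTumor,
               nPoints = g$nPoints)
  })
  tallies <- do.call(rbind, tallies)

  qa <- numericalDensity(tallies, fw * fh)
  af <- areaFraction(tallies)
  if (sum(tallies$q) < minCount)
    warning(sprintf("only %d profiles counted (aim: >= %d); consider a lower density class",
                    sum(tallies$q), minCount))
  new("EstimateRecord", method = "stereology", sectionId = roi@sectionId,
      roiLabel = roi@label, marker = marker, qA = qa, areaFraction = af,
      raw = tallies, nFov = nrow(fovs), seed = design@seed)
}
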