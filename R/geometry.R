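# Planar geometry in micrometer space. Image convention throughout: origin
# top-left, x rightward, y downward. All polygons are open rings (last vertex
# != first; closure is implicit).

.closeRing <- function(v) {
  if (nrow(v) > 1L && all(v[1L, ] == v[nrow(v), ])) v[-nrow(v), , drop = FALSE] else v
}

# Shoelace signed area (um^2). Positive for one orientation, negative for the
# other; which is "counter-clockwise" visually depends on the y-down axis, so
# code only relies on the sign, never on the visual handedness.
.signedArea <- function(v) {
  v <- .closeRing(v)
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.segIntersects <- function(p1, p2, q1, q2) {
  d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Proper self-intersection test for a ring (adjacent edges share endpoints and
# are skipped). O(n^2); rings here are small.
.ringSelfIntersects <- function(v) {
  v <- .closeRing(v)
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      if (.segIntersects(v[idx[i, 1L], ], v[idx[i, 2L], ],
                         v[idx[j, 1L], ], v[idx[j, 2L], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Construct a region of interest
#'
#' Orientation is normalized on ingest (outer ring to positive signed area,
#' holes to negative), so downstream area computations are sign-unambiguous.
#'
#' @param vertices n x 2 numeric matrix of outer-ring vertices (um).
#' @param holes optional list of hole polygons (n x 2 matrices, um).
#' @param label `"central"` or `"invasive"`.
#' @param sectionId section identifier carried as metadata.
#' @return A \linkS4class{RegionOfInterest}.
#' @examples
#' roi <- regionOfInterest(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
#' polygonArea(roi)  # 1 mm^2
#' @export
regionOfInterest <- function(vertices, holes = list(), label = "central",
                             sectionId = "s1") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  vertices <- .closeRing(vertices)
  if (nrow(vertices) >= 3L && .signedArea(vertices) < 0)
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  holes <- lapply(holes, function(h) {
    h <- as.matrix(h)
    storage.mode(h) <- "double"
    h <- .closeRing(h)
    if (nrow(h) >= 3L && .signedArea(h) > 0)
      h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
    h
  })
  new("RegionOfInterest", vertices = vertices, holes = holes,
      label = label, sectionId = as.character(sectionId))
}

#' Area of a region of interest
#'
#' Shoelace area of the outer ring minus the hole areas, converted from um^2
#' to mm^2.
#'
#' @param roi A \linkS4class{RegionOfInterest}.
#' @return Area in mm^2.
#' @export
polygonArea <- function(roi) {
  stopifnot(is(roi, "RegionOfInterest"))
  if (nrow(roi@vertices) < 3L)
    stop("invalid geometry: outer ring needs at least 3 vertices")
  a <- abs(.signedArea(roi@vertices))
  for (h in roi@holes) a <- a - abs(.signedArea(h))
  if (a <= 0) stop("invalid geometry: non-positive net area")
  a / 1e6
}

# Vectorized even-odd (crossing number) test with a half-open boundary rule:
# an edge is crossed when its y-range contains py as [ymin, ymax) and the
# upward ray from the point passes strictly left of the edge at height py.
# For axis-aligned tessellations this puts the minimum-x and minimum-y edges
# of each tile inside and the maximum-x / maximum-y edges outside, so
# congruent tiles partition the plane.
.pointsInRing <- function(px, py, ring) {
  ring <- .closeRing(ring)
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Point-in-ROI test
#'
#' Even-odd rule with a half-open boundary convention (see the methods
#' vignette): each point of the plane belongs to exactly one tile of any
#' tessellation of congruent polygons, which the sampling lattice relies on.
#' A point is in the ROI when it is inside the outer ring and outside every
#' hole.
#'
#' @param p numeric vector of length 2, or an n x 2 matrix of points (um).
#' @param roi A \linkS4class{RegionOfInterest}.
#' @return Logical vector.
#' @export
pointInROI <- function(p, roi) {
  stopifnot(is(roi, "RegionOfInterest"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  px <- p[, 1L]; py <- p[, 2L]
  inside <- .pointsInRing(px, py, roi@vertices)
  for (h in roi@holes) inside <- inside & !.pointsInRing(px, py, h)
  inside
}

#' Pixel / micrometer coordinate maps
#'
#' Affine maps between 0-based pixel indices and micrometer positions. A
#' pixel index refers to the pixel's top-left corner, so the maps form an
#' exact inverse pair.
#'
#' @param p numeric vector of length 2 or n x 2 matrix of coordinates.
#' @param pixelSize um per pixel.
#' @param origin micrometer position of pixel (0, 0).
#' @return Matrix (or vector) of mapped coordinates.
#' @export
pixelToMicron <- function(p, pixelSize, origin = c(0, 0)) {
  stopifnot(pixelSize > 0)
  drop1 <- is.null(dim(p))
  if (drop1) p <- matrix(p, ncol = 2L)
  out <- sweep(p * pixelSize, 2L, origin, "+")
  if (drop1) out[1L, ] else out
}

#' @rdname pixelToMicron
#' @export
micronToPixel <- function(p, pixelSize, origin = c(0, 0)) {
  stopifnot(pixelSize > 0)
  drop1 <- is.null(dim(p))
  if (drop1) p <- matrix(p, ncol = 2L)
  out <- sweep(p, 2L, origin, "-") / pixelSize
  if (drop1) out[1L, ] else out
}

# Bounding box of an ROI outer ring: c(xmin, ymin, xmax, ymax).
.roiBBox <- function(roi) {
  v <- roi@vertices
  c(min(v[, 1L]), min(v[, 2L]), max(v[, 1L]), max(v[, 2L]))
}

# Distance from the origin to segment p1--p2 (used in the transformed frame
# coordinates of the counting rule).
.distOriginSeg <- function(p1, p2) {
  d <- p2 - p1
  l2 <- sum(d * d)
  t <- if (l2 == 0) 0 else max(0, min(1, -sum(p1 * d) / l2))
  q <- p1 + t * d
  sqrt(sum(q * q))
}
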