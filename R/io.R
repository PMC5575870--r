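# GeoJSON and CSV interfaces. Coordinates are micrometers in the slide frame
# (a documented deviation from geographic CRS usage).

#' Read / write ROI polygons as GeoJSON
#'
#' A FeatureCollection of Polygon features; each feature carries properties
#' \code{label} ("central"/"invasive") and \code{section_id}. The first ring
#' is the outer boundary, further rings are holes.
#'
#' @param path file path.
#' @return \code{readROIGeoJSON} returns a list of
#'   \linkS4class{RegionOfInterest}.
#' @export
readROIGeoJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(doc$type, "FeatureCollection"))
  lapply(doc$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(rg)
      do.call(rbind, lapply(rg, function(p) c(p[[1]], p[[2]]))))
    regionOfInterest(rings[[1L]], holes = rings[-1L],
                     label = f$properties$label,
                     sectionId = f$properties$section_id)
  })
}

.ringCoords <- function(v) {
  v <- rbind(v, v[1L, ])                    # GeoJSON rings are closed
  lapply(seq_len(nrow(v)), function(i) c(v[i, 1L], v[i, 2L]))
}

#' @param rois list of \linkS4class{RegionOfInterest}.
#' @rdname readROIGeoJSON
#' @export
writeROIGeoJSON <- function(rois, path) {
  if (is(rois, "RegionOfInterest")) rois <- list(rois)
  features <- lapply(rois, function(r) {
    coords <- c(list(.ringCoords(r@vertices)), lapply(r@holes, .ringCoords))
    list(type = "Feature",
         properties = list(label = r@label, section_id = r@sectionId),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write cell profiles as GeoJSON
#'
#' Point features with properties \code{marker}, \code{stain_strength},
#' \code{nucleus_visible} and \code{radius} (um). Polygon features are
#' accepted on read and converted to an equal-area disk at the ring centroid.
#'
#' @param path file path.
#' @return \code{readCellsGeoJSON} returns a \linkS4class{CellProfiles}.
#' @export
readCellsGeoJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(doc$features, function(f) {
    g <- f$geometry; p <- f$properties
    if (identical(g$type, "Point")) {
      x <- g$coordinates[[1]]; y <- g$coordinates[[2]]
      r <- if (!is.null(p$radius)) p$radius else 4.5
    } else {
      ring <- do.call(rbind, lapply(g$coordinates[[1L]],
                                    function(q) c(q[[1]], q[[2]])))
      ring <- .closeRing(ring)
      x <- mean(ring[, 1L]); y <- mean(ring[, 2L])
      r <- sqrt(abs(.signedArea(ring)) / pi)
    }
    data.frame(x = x, y = y, a = r, b = r, theta = 0,
               marker = if (is.null(p$marker)) "CD3" else p$marker,
               stainStrength = if (is.null(p$stain_strength)) 1 else
                 p$stain_strength,
               nucleusVisible = if (is.null(p$nucleus_visible)) TRUE else
                 p$nucleus_visible)
  })
  cellProfiles(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' @param cells A \linkS4class{CellProfiles}.
#' @rdname readCellsGeoJSON
#' @export
writeCellsGeoJSON <- function(cells, path) {
  d <- cells@data
  features <- lapply(seq_len(nrow(d)), function(i) {
    list(type = "Feature",
         properties = list(marker = d$marker[i],
                           stain_strength = d$stainStrength[i],
                           nucleus_visible = d$nucleusVisible[i],
                           radius = sqrt(d$a[i] * d$b[i])),
         geometry = list(type = "Point",
                         coordinates = c(d$x[i], d$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cell centroids from CSV
#'
#' Expects columns \code{x}, \code{y}, \code{radius} and optionally
#' \code{marker}, \code{stain_strength}, \code{nucleus_visible}.
#'
#' @param path file path.
#' @return A \linkS4class{CellProfiles}.
#' @export
readCellsCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d)[names(d) == "stain_strength"] <- "stainStrength"
  names(d)[names(d) == "nucleus_visible"] <- "nucleusVisible"
  cellProfiles(d)
}

#' Tabulate estimate records
#'
#' Flattens \linkS4class{EstimateRecord} objects to the standard CSV layout:
#' method, section_id, roi_label, marker, q_a_per_mm2, area_fraction, sum_q,
#' sum_p_tumor, sum_p_positive, n_fov, seed.
#'
#' @param records list of \linkS4class{EstimateRecord} (or a single one).
#' @return data.frame, one row per record.
#' @export
estimateTable <- function(records) {
  if (is(records, "EstimateRecord")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    st <- r@method == "stereology"
    data.frame(method = r@method, section_id = r@sectionId,
               roi_label = r@roiLabel, marker = r@marker,
               q_a_per_mm2 = r@qA, area_fraction = r@areaFraction,
               sum_q = if (st) sum(r@raw$q) else NA_integer_,
               sum_p_tumor = if (st) sum(r@raw$pTumor) else NA_integer_,
               sum_p_positive = if (st) sum(r@raw$pPositive) else NA_integer_,
               n_fov = r@nFov, seed = r@seed)
  }))
}

#' @param path output CSV path.
#' @rdname estimateTable
#' @export
writeEstimates <- function(records, path) {
  utils::write.csv(estimateTable(records), path, row.names = FALSE)
  invisible(path)
}
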