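# Object formation and the end-to-end automated count.

#' Separate and post-filter detected objects
#'
#' Splits the positive-pixel mask into objects with a watershed on the
#' blob-enhanced response (flooded from local maxima found within a
#' neighborhood equal to the lower blob radius, with a fixed prominence
#' tolerance -- fully deterministic), then applies the object post-filters:
#' objects smaller than \code{minObjectArea} are relabeled
#' \code{rejected_negative} and objects whose mean red chromaticity falls
#' below \code{weakStainCutoff} are relabeled \code{rejected_weak}.
#'
#' @param posMask logical matrix of positive pixels.
#' @param enhanced blob-enhanced response matrix (same size).
#' @param model a \linkS4class{DetectionModel}.
#' @param pixelSize um per pixel.
#' @param redChroma red-chromaticity matrix used for the weak-stain filter.
#' @return data.frame of detected objects: centroid (\code{x}, \code{y}, um),
#'   \code{areaUm2}, \code{meanRedChroma}, \code{label}.
#' @export
separateAndFilter <- function(posMask, enhanced, model, pixelSize,
                              redChroma) {
  stopifnot(all(dim(posMask) == dim(enhanced)))
  empty <- data.frame(x = numeric(), y = numeric(), areaUm2 = numeric(),
                      meanRedChroma = numeric(), label = character())
  if (!any(posMask)) return(empty)
  surf <- enhanced
  lo <- min(surf[posMask]); hi <- max(surf[posMask])
  surf <- if (hi > lo) (surf - lo) / (hi - lo) * 0.95 + 0.05 else
    matrix(1, nrow(surf), ncol(surf))
  surf[!posMask] <- 0
  # neighborhood for maxima detection: half the lower blob radius; a larger
  # neighborhood also merges distinct nearby components, not only peaks
  extPx <- max(1L, floor(model@blobRadiusRange[1] / (2 * pixelSize)))
  ws <- EBImage::watershed(surf, tolerance = model@watershedTolerance,
                           ext = extPx)
  ws <- as.matrix(ws)
  n <- max(ws)
  if (n == 0L) return(empty)
  idx <- which(ws > 0L)
  lab <- ws[idx]
  rows <- ((idx - 1L) %% nrow(ws)) + 1L
  cols <- ((idx - 1L) %/% nrow(ws)) + 1L
  areaPx <- tabulate(lab, n)
  cy <- (vapply(split(rows, lab), mean, numeric(1)) - 0.5) * pixelSize
  cx <- (vapply(split(cols, lab), mean, numeric(1)) - 0.5) * pixelSize
  chroma <- vapply(split(redChroma[idx], lab), mean, numeric(1))
  areaUm2 <- areaPx * pixelSize^2
  labToIdx <- as.integer(names(cy))   # split() orders by label value
  out <- data.frame(x = cx, y = cy, areaUm2 = areaUm2[labToIdx],
                    meanRedChroma = chroma, label = "positive",
                    stringsAsFactors = FALSE)
  out$label[out$areaUm2 < model@minObjectArea] <- "rejected_negative"
  out$label[out$label == "positive" &
            out$meanRedChroma < model@weakStainCutoff] <- "rejected_weak"
  rownames(out) <- NULL
  out
}

# upsample a low-res mask to full resolution by pixel replication
.upsampleMask <- function(mask, fac, dimFull) {
  r <- pmin(nrow(mask), (seq_len(dimFull[1]) - 1L) %/% fac + 1L)
  c <- pmin(ncol(mask), (seq_len(dimFull[2]) - 1L) %/% fac + 1L)
  mask[r, c, drop = FALSE]
}

# rasterize ROI membership over the full pixel grid
.roiRaster <- function(roi, dimFull, pixelSize) {
  xs <- (seq_len(dimFull[2]) - 0.5) * pixelSize
  ys <- (seq_len(dimFull[1]) - 0.5) * pixelSize
  g <- expand.grid(y = ys, x = xs)
  matrix(pointInROI(cbind(g$x, g$y), roi), dimFull[1], dimFull[2])
}

#' Run the automated detection pipeline on one ROI
#'
#' Composes the two processing steps of the automated count: (1) artifact
#' exclusion on the software-generated low-magnification image, and (2)
#' full-resolution chromaticity classification with blob enhancement,
#' watershed separation and object post-filtering, restricted to the ROI
#' minus the artifact mask. The pipeline is fully deterministic.
#'
#' @param img A \linkS4class{StainImage}.
#' @param roi A \linkS4class{RegionOfInterest} (micrometer coordinates within
#'   the image bounds).
#' @param model a trained \linkS4class{DetectionModel}.
#' @return An \linkS4class{EstimateRecord} with method
#'   \code{"image_analysis"}: \code{qA} = accepted objects per mm^2 of
#'   analyzable ROI area, \code{areaFraction} = accepted-object pixel area
#'   over analyzable area.
#' @export
runDetection <- function(img, roi, model) {
  stopifnot(is(img, "StainImage"), is(roi, "RegionOfInterest"))
  px <- img@pixelSize
  dimFull <- dim(img@data)[1:2]

  fac <- max(1L, round(model@lowresPixelSize / px))
  art <- segmentArtifacts(makeLowres(img, fac), model)
  artFull <- .upsampleMask(art$mask, fac, dimFull)

  roiMask <- .roiRaster(roi, dimFull, px)
  analyzable <- roiMask & !artFull
  analyzableMm2 <- sum(analyzable) * px^2 / 1e6
  if (analyzableMm2 <= 0)
    stop("estimate undefined: analyzable area is zero")

  feats <- chromaticityFeatures(img, model@meanFilterWindow)
  posMask <- classifyPixels(feats, model) & analyzable
  enhanced <- blobEnhance(feats$red, model@blobRadiusRange, px)
  objects <- separateAndFilter(posMask, enhanced, model, px, feats$red)

  # objects are attributed to the ROI by centroid
  keepPos <- objects$label == "positive"
  nPos <- sum(keepPos)
  posAreaMm2 <- sum(objects$areaUm2[keepPos]) / 1e6
  raw <- data.frame(nPositive = nPos,
                    nRejectedWeak = sum(objects$label == "rejected_weak"),
                    nRejectedNegative = sum(objects$label == "rejected_negative"),
                    analyzableAreaMm2 = analyzableMm2,
                    positiveAreaMm2 = posAreaMm2)
  new("EstimateRecord", method = "image_analysis", sectionId = roi@sectionId,
      roiLabel = roi@label, marker = img@marker,
      qA = nPos / analyzableMm2,
      areaFraction = min(1, posAreaMm2 / analyzableMm2),
      raw = raw, nFov = 1L, seed = NA_integer_)
}

# memoized default model: render two labeled training sections and fit
.modelCache <- new.env(parent = emptyenv())

#' Default detection model trained on synthetic sections
#'
#' Renders a small labeled training set (two sections with artifacts, weak
#' cells and counterstained nuclei) and fits the classifiers. The result is
#' memoized per seed within the session.
#'
#' @param seed integer seed for the training renders.
#' @return A trained \linkS4class{DetectionModel}.
#' @export
defaultDetectionModel <- function(seed = 99L) {
  key <- as.character(seed)
  if (!is.null(.modelCache[[key]])) return(.modelCache[[key]])
  secs <- list(
    renderSection(trueDensity = c(central = 500, invasive = 800),
                  artifactFraction = 0.08, weakFraction = 0.15,
                  sectionWidth = 500, sectionHeight = 500,
                  sectionId = "train1", seed = seed),
    renderSection(trueDensity = c(central = 1200, invasive = 150),
                  artifactFraction = 0.08, weakFraction = 0.15,
                  sectionWidth = 500, sectionHeight = 500,
                  sectionId = "train2", seed = seed + 1L)
  )
  m <- trainDetectionModel(secs)
  .modelCache[[key]] <- m
  m
}
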