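# Synthetic cohort and section generator. Emulates DAB-stained CD3+/CD8+
# lymphocytes (brown membranous/cytoplasmic rim with a darker nuclear core)
# on a hematoxylin-counterstained background, with optional mucin, fold and
# necrosis artifact regions, plus a two-level (tumor, section) log-normal
# density hierarchy. Every quantity the estimators target is emitted as
# ground truth.

# stain color anchors (8-bit RGB)
.COL_BG       <- c(207, 203, 223)  # hematoxylin-tinted stroma
.COL_NUC      <- c(118, 108, 178)  # counterstained immuno-negative nuclei
.COL_DAB      <- c(148,  82,  46)  # DAB-brown cytoplasmic stain
.COL_DAB_CORE <- c( 96,  56,  36)  # nuclear core of a positive cell
.COL_MUCIN    <- c(240, 240, 244)
.COL_FOLD     <- c( 72,  70,  92)
.COL_NECROSIS <- c(192, 165, 158)

#' Simulate a hierarchical cohort of true TIL densities
#'
#' Log-densities follow a two-level normal hierarchy:
#' log lambda_tsr = mu_r + a_t + b_ts with a_t ~ N(0, sigma2Tumor) (tumor
#' level) and b_ts ~ N(0, sigma2Section) (section-within-tumor level); the
#' invasive region mean is shifted by \code{invasiveExcess}. The implied true
#' intraclass correlation sigma2Tumor / (sigma2Tumor + sigma2Section) is
#' attached as attribute \code{"trueICC"}.
#'
#' @param nTumors number of tumors.
#' @param sectionsPerTumor sections per tumor.
#' @param muLogDensity mean log density (cells/mm^2, natural log) of the
#'   central region.
#' @param invasiveExcess additive log-scale shift of the invasive region.
#' @param sigma2Tumor between-tumor variance (log scale).
#' @param sigma2Section between-section-within-tumor variance (log scale).
#' @param seed integer seed.
#' @return data.frame with columns \code{tumor}, \code{section},
#'   \code{region}, \code{trueDensity}; attribute \code{trueICC}.
#' @export
simulateCohort <- function(nTumors = 43L, sectionsPerTumor = 3L,
                           muLogDensity = log(350), invasiveExcess = 0.25,
                           sigma2Tumor = 0.49, sigma2Section = 0.21,
                           seed = 1L) {
  stopifnot(nTumors >= 2L, sectionsPerTumor >= 1L,
            sigma2Tumor >= 0, sigma2Section >= 0)
  .withSeed(seed, {
    aT <- stats::rnorm(nTumors, 0, sqrt(sigma2Tumor))
    bTS <- matrix(stats::rnorm(nTumors * sectionsPerTumor, 0,
                               sqrt(sigma2Section)),
                  nTumors, sectionsPerTumor)
    out <- expand.grid(region = c("central", "invasive"),
                       section = seq_len(sectionsPerTumor),
                       tumor = seq_len(nTumors))[, 3:1]
    mu <- ifelse(out$region == "invasive",
                 muLogDensity + invasiveExcess, muLogDensity)
    out$trueDensity <- exp(mu + aT[out$tumor] +
                           bTS[cbind(out$tumor, out$section)])
    attr(out, "trueICC") <- if (sigma2Tumor + sigma2Section > 0)
      sigma2Tumor / (sigma2Tumor + sigma2Section) else 0
    out
  })
}

# regular 24-gon approximating an ellipse patch (used for artifact regions)
.ellipsePoly <- function(cx, cy, a, b, theta = 0, n = 24L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(theta); st <- sin(theta)
  cbind(cx + a * cos(t) * ct - b * sin(t) * st,
        cy + a * cos(t) * st + b * sin(t) * ct)
}

.rectPoly <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# slightly irregular octagon inside a rectangle (ROI outline)
.octagonROI <- function(x0, y0, x1, y1, cut = 0.18) {
  dx <- (x1 - x0) * cut; dy <- (y1 - y0) * cut
  rbind(c(x0 + dx, y0), c(x1 - dx, y0), c(x1, y0 + dy), c(x1, y1 - dy),
        c(x1 - dx, y1), c(x0 + dx, y1), c(x0, y1 - dy), c(x0, y0 + dy))
}

# hard-core sequential placement of N cell centers inside region (ROI minus
# artifacts), with pairwise center separation
# >= (r_i + r_j) * (1 - allowance) + margin
.placeCells <- function(n, roi, artifacts, radii, overlapAllowance,
                        margin = 1.5) {
  if (n == 0L) return(cbind(numeric(), numeric()))
  bb <- .roiBBox(roi)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L; attempts <- 0L; maxAttempts <- 400L * n + 2000L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("hard-core packing failed at this density; increase overlapAllowance")
    px <- stats::runif(1, bb[1], bb[3]); py <- stats::runif(1, bb[2], bb[4])
    if (!pointInROI(c(px, py), roi)) next
    bad <- FALSE
    for (a in artifacts)
      if (.pointsInRing(px, py, a$poly)) { bad <- TRUE; break }
    if (bad) next
    if (placed > 0L) {
      minSep <- (radii[seq_len(placed)] + radii[placed + 1L]) *
        (1 - overlapAllowance) + margin
      if (any((xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2 <
              minSep^2)) next
    }
    placed <- placed + 1L
    xs[placed] <- px; ys[placed] <- py
  }
  cbind(xs, ys)
}

# paint disks into the 3-channel raster; alpha-blend toward col
.paintDisks <- function(arr, px, cx, cy, r, col, alpha) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  for (i in seq_along(cx)) {
    c0 <- max(1L, floor((cx[i] - r[i]) / px)); c1 <- min(W, ceiling((cx[i] + r[i]) / px) + 1L)
    r0 <- max(1L, floor((cy[i] - r[i]) / px)); r1 <- min(H, ceiling((cy[i] + r[i]) / px) + 1L)
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1 - 0.5) * px; ys <- (r0:r1 - 0.5) * px
    dd <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
    sel <- dd <= r[i]^2
    if (!any(sel)) next
    for (k in 1:3) {
      sub <- arr[r0:r1, c0:c1, k]
      sub[sel] <- (1 - alpha[i]) * sub[sel] + alpha[i] * col[k]
      arr[r0:r1, c0:c1, k] <- sub
    }
  }
  arr
}

# disk mask rasterization into a logical matrix
.maskDisks <- function(mask, px, cx, cy, r) {
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_along(cx)) {
    c0 <- max(1L, floor((cx[i] - r[i]) / px)); c1 <- min(W, ceiling((cx[i] + r[i]) / px) + 1L)
    r0 <- max(1L, floor((cy[i] - r[i]) / px)); r1 <- min(H, ceiling((cy[i] + r[i]) / px) + 1L)
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1 - 0.5) * px; ys <- (r0:r1 - 0.5) * px
    dd <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (dd <= r[i]^2)
  }
  mask
}

# rasterize a polygon over pixel centers
.maskPoly <- function(H, W, px, poly) {
  xs <- (seq_len(W) - 0.5) * px
  ys <- (seq_len(H) - 0.5) * px
  g <- expand.grid(y = ys, x = xs)       # column-major: rows vary fastest
  matrix(.pointsInRing(g$x, g$y, poly), H, W)
}

#' Render a synthetic IHC section with ground truth
#'
#' Produces an RGB raster emulating a DAB/hematoxylin-stained section with
#' two labeled ROIs (central and invasive), positive lymphocytes at the
#' requested densities (Poisson locations with hard-core thinning), optional
#' weakly stained cells, counterstained immuno-negative nuclei, and optional
#' artifact regions (pale mucin, dark fold band, mottled necrosis). Ground
#' truth (cell list, masks, realized densities and area fractions over the
#' analyzable area) is returned alongside.
#'
#' @param trueDensity named numeric, target density (cells/mm^2) per region,
#'   e.g. \code{c(central = 400, invasive = 550)}.
#' @param marker "CD3" or "CD8".
#' @param sectionWidth,sectionHeight canvas size in um.
#' @param pixelSize render resolution, um per pixel.
#' @param artifactFraction approximate fraction of each ROI covered by
#'   artifact regions (0 disables artifacts).
#' @param weakFraction probability that a cell is weakly stained (stain
#'   strength below the observer threshold).
#' @param nucleusVisibleProb probability that a cell's nucleus is discernible.
#' @param negativeNucleiDensity density (per mm^2) of counterstained
#'   immuno-negative nuclei rendered for realism.
#' @param cellRadiusRange cell radius range in um (8-10 um diameter default).
#' @param overlapAllowance fraction of the radius sum by which neighboring
#'   cells may overlap (0 = strict hard core).
#' @param hardCoreMargin additional boundary gap (um) enforced between
#'   profiles so that distinct cells render as disjoint objects.
#' @param noiseSD additive Gaussian pixel noise SD (8-bit scale).
#' @param sectionId section identifier.
#' @param seed integer seed; the render is byte-identical for a fixed seed.
#' @return list with \code{image} (\linkS4class{StainImage}), \code{cells}
#'   (\linkS4class{CellProfiles}), \code{rois}, \code{artifacts},
#'   \code{truth} (per-region data.frame), \code{masks}, \code{pixelSize},
#'   \code{sectionId}, \code{seed}.
#' @export
renderSection <- function(trueDensity = c(central = 400, invasive = 550),
                          marker = "CD3",
                          sectionWidth = 600, sectionHeight = 600,
                          pixelSize = 0.904,
                          artifactFraction = 0,
                          weakFraction = 0,
                          nucleusVisibleProb = 1,
                          negativeNucleiDensity = 1200,
                          cellRadiusRange = c(4, 5),
                          overlapAllowance = 0,
                          hardCoreMargin = 1.5,
                          noiseSD = 4,
                          sectionId = "s1",
                          seed = 1L) {
  stopifnot(all(trueDensity >= 0), artifactFraction >= 0, artifactFraction <= 0.5)
  regions <- names(trueDensity)
  stopifnot(all(regions %in% c("central", "invasive")))
  W <- sectionWidth; H <- sectionHeight
  m <- 15
  gap <- 12
  roiBoxes <- list(
    central  = c(m, m, W / 2 - gap, H - m),
    invasive = c(W / 2 + gap, m, W - m, H - m)
  )
  .withSeed(seed, {
    rois <- list()
    artifacts <- list()
    for (rg in regions) {
      bb <- roiBoxes[[rg]]
      rois[[rg]] <- regionOfInterest(.octagonROI(bb[1], bb[2], bb[3], bb[4]),
                                     label = rg, sectionId = sectionId)
      if (artifactFraction > 0) {
        roiA <- polygonArea(rois[[rg]]) * 1e6      # um^2
        targetA <- artifactFraction * roiA
        cx <- (bb[1] + bb[3]) / 2; cy <- (bb[2] + bb[4]) / 2
        wRoi <- bb[3] - bb[1]; hRoi <- bb[4] - bb[2]
        # one pale mucin pool (upper third), one necrosis patch (lower third),
        # one thin dark fold band; areas split ~ 40/40/20
        aM <- sqrt(0.40 * targetA / pi)
        artifacts[[length(artifacts) + 1L]] <- list(
          class = "mucin", region = rg,
          poly = .ellipsePoly(cx - wRoi * 0.15, bb[2] + hRoi * 0.25,
                              aM * 1.3, aM / 1.3,
                              stats::runif(1, 0, pi)))
        aN <- sqrt(0.40 * targetA / pi)
        artifacts[[length(artifacts) + 1L]] <- list(
          class = "necrosis", region = rg,
          poly = .ellipsePoly(cx + wRoi * 0.12, bb[4] - hRoi * 0.25,
                              aN * 1.2, aN / 1.2,
                              stats::runif(1, 0, pi)))
        bandW <- max(6, 0.20 * targetA / (hRoi * 0.7))
        bx <- cx + wRoi * stats::runif(1, -0.25, 0.25)
        artifacts[[length(artifacts) + 1L]] <- list(
          class = "fold", region = rg,
          poly = .rectPoly(bx - bandW / 2, cy - hRoi * 0.35,
                           bx + bandW / 2, cy + hRoi * 0.35))
      }
    }

    # ---- cells -----------------------------------------------------------
    cellRows <- list()
    for (rg in regions) {
      roi <- rois[[rg]]
      artR <- Filter(function(a) a$region == rg, artifacts)
      areaMm2 <- polygonArea(roi) -
        sum(vapply(artR, function(a) abs(.signedArea(a$poly)), numeric(1))) / 1e6
      n <- stats::rpois(1, trueDensity[[rg]] * areaMm2)
      radii <- stats::runif(n, cellRadiusRange[1], cellRadiusRange[2])
      ctr <- .placeCells(n, roi, artR, radii, overlapAllowance,
                         hardCoreMargin)
      if (n > 0L) {
        weak <- stats::runif(n) < weakFraction
        strength <- ifelse(weak, stats::runif(n, 0.05, 0.20),
                           stats::runif(n, 0.70, 1.00))
        cellRows[[rg]] <- data.frame(
          x = ctr[, 1L], y = ctr[, 2L], a = radii, b = radii, theta = 0,
          marker = marker, stainStrength = strength,
          nucleusVisible = stats::runif(n) < nucleusVisibleProb,
          region = rg)
      }
    }
    cellDf <- if (length(cellRows)) do.call(rbind, cellRows) else
      data.frame(x = numeric(), y = numeric(), a = numeric(), b = numeric(),
                 theta = numeric(), marker = character(),
                 stainStrength = numeric(), nucleusVisible = logical(),
                 region = character())
    rownames(cellDf) <- NULL

    # ---- raster ----------------------------------------------------------
    Hpx <- round(H / pixelSize); Wpx <- round(W / pixelSize)
    npx <- Hpx * Wpx
    arr <- array(0, c(Hpx, Wpx, 3))
    for (k in 1:3)
      arr[, , k] <- .COL_BG[k] + stats::rnorm(npx, 0, noiseSD)

    # counterstained immuno-negative nuclei
    nNeg <- stats::rpois(1, negativeNucleiDensity * W * H / 1e6)
    if (nNeg > 0) {
      nx <- stats::runif(nNeg, 0, W); ny <- stats::runif(nNeg, 0, H)
      nr <- stats::runif(nNeg, 2.2, 3.2)
      arr <- .paintDisks(arr, pixelSize, nx, ny, nr, .COL_NUC,
                         stats::runif(nNeg, 0.55, 0.8))
    }

    # artifact regions
    artifactClasses <- c("mucin", "fold", "necrosis")
    artMask <- matrix(0L, Hpx, Wpx)
    for (a in artifacts) {
      sel <- .maskPoly(Hpx, Wpx, pixelSize, a$poly)
      col <- switch(a$class, mucin = .COL_MUCIN, fold = .COL_FOLD,
                    necrosis = .COL_NECROSIS)
      sdA <- switch(a$class, mucin = 2, fold = 4, necrosis = 16)
      for (k in 1:3) {
        sub <- arr[, , k]
        sub[sel] <- col[k] + stats::rnorm(sum(sel), 0, sdA)
        arr[, , k] <- sub
      }
      artMask[sel] <- match(a$class, artifactClasses)
    }

    # positive cells: stained rim then darker nuclear core
    if (nrow(cellDf)) {
      arr <- .paintDisks(arr, pixelSize, cellDf$x, cellDf$y, cellDf$a,
                         .COL_DAB, pmin(1, 0.15 + 0.85 * cellDf$stainStrength))
      core <- cellDf$nucleusVisible
      if (any(core))
        arr <- .paintDisks(arr, pixelSize, cellDf$x[core], cellDf$y[core],
                           cellDf$a[core] * 0.5, .COL_DAB_CORE,
                           pmin(1, 0.2 + 0.8 * cellDf$stainStrength[core]))
    }
    arr[arr < 0] <- 0; arr[arr > 255] <- 255

    # ---- masks & truth ---------------------------------------------------
    roiMask <- matrix(0L, Hpx, Wpx)
    for (i in seq_along(regions))
      roiMask[.maskPoly(Hpx, Wpx, pixelSize, rois[[regions[i]]]@vertices)] <-
        i
    strong <- cellDf$stainStrength >= 0.3
    elig <- strong & cellDf$nucleusVisible
    cellStrongMask <- .maskDisks(matrix(FALSE, Hpx, Wpx), pixelSize,
                                 cellDf$x[strong], cellDf$y[strong],
                                 cellDf$a[strong])
    cellEligMask <- .maskDisks(matrix(FALSE, Hpx, Wpx), pixelSize,
                               cellDf$x[elig], cellDf$y[elig],
                               cellDf$a[elig])
    cellAllMask <- .maskDisks(matrix(FALSE, Hpx, Wpx), pixelSize,
                              cellDf$x, cellDf$y, cellDf$a)

    truth <- do.call(rbind, lapply(seq_along(regions), function(i) {
      rg <- regions[i]
      analyzable <- roiMask == i & artMask == 0L
      aMm2 <- sum(analyzable) * pixelSize^2 / 1e6
      nE <- sum(elig & cellDf$region == rg)
      data.frame(region = rg, analyzableAreaMm2 = aMm2, nEligible = nE,
                 trueDensity = nE / aMm2,
                 trueAreaFraction = sum(cellEligMask & analyzable) /
                   sum(analyzable))
    }))

    img <- new("StainImage", data = arr, pixelSize = pixelSize,
               marker = marker)
    cells <- cellProfiles(cellDf[, setdiff(names(cellDf), "region")])
    list(image = img, cells = cells, rois = rois, artifacts = artifacts,
         truth = truth, cellRegions = cellDf$region,
         masks = list(roi = roiMask, artifact = artMask,
                      artifactClasses = artifactClasses,
                      cellStrong = cellStrongMask,
                      cellEligible = cellEligMask, cellAll = cellAllMask),
         pixelSize = pixelSize, sectionId = sectionId, seed = seed)
  })
}

#' Write a deterministic fixture suite to disk
#'
#' Simulates a cohort, renders every (tumor, section) at thumbnail scale, and
#' writes \code{images/*.png}, \code{roi/*.geojson}, \code{truth/*.geojson}
#' and a \code{manifest.csv} with the realized ground truth.
#'
#' @param outDir output directory (created if needed).
#' @param nTumors,sectionsPerTumor cohort shape.
#' @param sectionWidth,sectionHeight canvas size in um.
#' @param artifactFraction,weakFraction passed to \code{\link{renderSection}}.
#' @param seed integer master seed; per-section seeds are derived from it.
#' @param ... further arguments to \code{\link{renderSection}}.
#' @return Invisibly, the manifest data.frame.
#' @export
makeFixtureSuite <- function(outDir, nTumors = 43L, sectionsPerTumor = 3L,
                             sectionWidth = 450, sectionHeight = 450,
                             artifactFraction = 0.05, weakFraction = 0.1,
                             seed = 1L, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("images", "roi", "truth"))
    dir.create(file.path(outDir, sub), showWarnings = FALSE)
  cohort <- simulateCohort(nTumors = nTumors,
                           sectionsPerTumor = sectionsPerTumor, seed = seed)
  rows <- list()
  for (t in seq_len(nTumors)) {
    for (s in seq_len(sectionsPerTumor)) {
      dens <- cohort[cohort$tumor == t & cohort$section == s, ]
      td <- stats::setNames(dens$trueDensity, as.character(dens$region))
      sid <- sprintf("t%02d_s%d", t, s)
      secSeed <- (as.integer(seed) %% 20000L) * 100000L + t * 100L + s
      sec <- renderSection(trueDensity = td[c("central", "invasive")],
                           sectionWidth = sectionWidth,
                           sectionHeight = sectionHeight,
                           artifactFraction = artifactFraction,
                           weakFraction = weakFraction,
                           sectionId = sid, seed = secSeed, ...)
      png::writePNG(sec$image@data / 255,
                    file.path(outDir, "images", paste0(sid, ".png")))
      writeROIGeoJSON(sec$rois, file.path(outDir, "roi",
                                          paste0(sid, ".geojson")))
      writeCellsGeoJSON(sec$cells, file.path(outDir, "truth",
                                             paste0(sid, ".geojson")))
      rows[[sid]] <- data.frame(
        tumor_id = t, section_id = sid, region = sec$truth$region,
        true_density = sec$truth$trueDensity,
        true_area_fraction = sec$truth$trueAreaFraction, seed = secSeed)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
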