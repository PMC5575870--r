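test_that("counting frame applies inclusion/exclusion edges correctly", {
  fr <- c(0, 0, 40, 40)   # y down: bottom edge at y = 40
  inside <- cellProfiles(x = 20, y = 20, radius = 5)
  expect_length(applyCountingFrame(fr, inside), 1L)

  crossingLeft <- cellProfiles(x = 2, y = 20, radius = 5)
  expect_length(applyCountingFrame(fr, crossingLeft), 0L)
  onLeftExtension <- cellProfiles(x = 2, y = -30, radius = 5)  # above frame
  expect_length(applyCountingFrame(fr, onLeftExtension), 0L)
  crossingBottom <- cellProfiles(x = 20, y = 39, radius = 5)
  expect_length(applyCountingFrame(fr, crossingBottom), 0L)
  crossingRight <- cellProfiles(x = 39, y = 20, radius = 5)   # inclusion edge
  expect_length(applyCountingFrame(fr, crossingRight), 1L)
  crossingTop <- cellProfiles(x = 20, y = 1, radius = 5)      # inclusion edge
  expect_length(applyCountingFrame(fr, crossingTop), 1L)

  noNucleus <- cellProfiles(x = 20, y = 20, radius = 5, nucleusVisible = FALSE)
  expect_length(applyCountingFrame(fr, noNucleus), 0L)
  faint <- cellProfiles(x = 20, y = 20, radius = 5, stainStrength = 0.1)
  expect_length(applyCountingFrame(fr, faint), 0L)
})

test_that("complete frame tilings count every elliptical profile exactly once", {
  for (s in 1:5) {
    cells <- randomEllipses(200, seed = s)
    expect_identical(tessellationTotal(cells, side = 40), 200L)
  }
  # also under a different tile size
  expect_identical(tessellationTotal(randomEllipses(150, seed = 9), side = 25),
                   150L)
})

test_that("adding a profile inside a frame increases the count", {
  fr <- c(0, 0, 40, 40)
  cells <- randomEllipses(30, size = 60, seed = 4)
  base <- length(applyCountingFrame(fr, cells))
  d <- rbind(profileData(cells),
             data.frame(x = 20, y = 20, a = 3, b = 3, theta = 0,
                        marker = "CD3", stainStrength = 1,
                        nucleusVisible = TRUE))
  expect_gt(length(applyCountingFrame(fr, cellProfiles(d))), base)
})

test_that("numerical density and area fraction match hand computations", {
  tal <- data.frame(q = rep(5, 40), pFrame = 1, pPositive = 0, pTumor = 0)
  expect_equal(numericalDensity(tal, 1575), 200 / (40 * 1575) * 1e6)
  expect_equal(numericalDensity(transform(tal, q = 0), 1575), 0)
  expect_error(numericalDensity(transform(tal, pFrame = 0), 1575),
               "undefined")

  expect_equal(areaFraction(data.frame(pPositive = 2, pTumor = 30)), 2 / 30)
  expect_equal(areaFraction(data.frame(pPositive = 0, pTumor = 30)), 0)
  expect_error(areaFraction(data.frame(pPositive = 0, pTumor = 0)),
               "undefined")
})

test_that("grid counting: empty FOV, excluded tissue, mask-fraction oracle", {
  fov <- list(x0 = 0, y0 = 0, width = 130, height = 130)
  empty <- cellProfiles(data.frame(x = numeric(), y = numeric(),
                                   a = numeric(), b = numeric(),
                                   theta = numeric(), marker = character(),
                                   stainStrength = numeric(),
                                   nucleusVisible = logical()))
  g <- countGridPoints(fov, sqrt(559.69), c(5, 5), empty, vitalEverywhere)
  expect_identical(g$pPositive, 0L)
  expect_equal(g$pTumor, g$nPoints)
  expect_gt(g$nPoints, 0L)

  allExcluded <- function(pts) rep(FALSE, nrow(pts))
  g2 <- countGridPoints(fov, sqrt(559.69), c(5, 5), empty, allExcluded)
  expect_identical(g2$pTumor, 0L)

  # fine grid converges to the rasterized coverage of a disk pattern
  set.seed(21)
  cells <- cellProfiles(x = runif(40, 0, 130), y = runif(40, 0, 130),
                        radius = 8)
  gp <- countGridPoints(fov, 2, c(0.7, 0.3), cells, vitalEverywhere)
  est <- gp$pPositive / gp$pTumor
  xs <- seq(0.25, 129.75, by = 0.5)
  msk <- outer(xs, xs, function(yy, xx) {
    hit <- rep(FALSE, length(xx))
    d <- profileData(cells)
    for (i in seq_len(nrow(d)))
      hit <- hit | ((xx - d$x[i])^2 + (yy - d$y[i])^2 <= 64)
    hit
  })
  expect_lt(abs(est - mean(msk)), 0.02)
})

test_that("SURS lattice: tessellation limit, determinism, uniform coverage", {
  roi <- regionOfInterest(rbind(c(0, 0), c(5000, 0), c(5000, 5000),
                                c(0, 5000)))
  des <- samplingDesign(densityClass = "high", nFov = 25, fovWidth = 1000,
                        fovHeight = 1000, seed = 5)
  f1 <- sampleFOVs(roi, des)
  expect_identical(nrow(f1), 25L)
  expect_equal(attr(f1, "step"), 1000)
  expect_identical(f1, sampleFOVs(roi, des))

  # coverage frequency of FOV centers uniform over a 10x10 binning
  des2 <- samplingDesign(nFov = 36, fovWidth = 500, fovHeight = 500)
  counts <- matrix(0, 10, 10)
  for (s in 1:400) {
    des2@seed <- s
    f <- sampleFOVs(roi, des2)
    bx <- pmin(10, floor(f$cx / 500) + 1); by <- pmin(10, floor(f$cy / 500) + 1)
    for (k in seq_along(bx)) counts[by[k], bx[k]] <- counts[by[k], bx[k]] + 1
  }
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)

  expect_warning(
    sampleFOVs(regionOfInterest(rbind(c(0, 0), c(50, 0), c(50, 50), c(0, 50))),
               samplingDesign()),
    "smaller than one FOV")
})

test_that("full stereology run: empty input, determinism, scale invariance", {
  roi <- regionOfInterest(rbind(c(0, 0), c(2000, 0), c(2000, 2000),
                                c(0, 2000)))
  empty <- cellProfiles(data.frame(x = numeric(), y = numeric(),
                                   a = numeric(), b = numeric(),
                                   theta = numeric(), marker = character(),
                                   stainStrength = numeric(),
                                   nucleusVisible = logical()))
  des <- samplingDesign(seed = 8)
  rec0 <- suppressWarnings(runStereology(roi, empty, des,
                                         tissueClassifier = vitalEverywhere))
  expect_equal(qA(rec0), 0)
  expect_equal(areaFractionOf(rec0), 0)

  set.seed(31)
  cells <- cellProfiles(x = runif(900, 0, 2000), y = runif(900, 0, 2000),
                        radius = 4.5)
  r1 <- suppressWarnings(runStereology(roi, cells, des,
                                       tissueClassifier = vitalEverywhere))
  r2 <- suppressWarnings(runStereology(roi, cells, des,
                                       tissueClassifier = vitalEverywhere))
  expect_identical(estimateTable(r1), estimateTable(r2))
  expect_identical(r1@raw, r2@raw)

  # scale everything by k = 2: AF unchanged, Q_A divided by k^2
  k <- 2
  roiK <- regionOfInterest(roi@vertices * k)
  d <- profileData(cells)
  cellsK <- cellProfiles(transform(d, x = x * k, y = y * k, a = a * k,
                                   b = b * k))
  desK <- samplingDesign(seed = 8, frameArea = 1575 * k^2,
                         areaPerPoint = 559.69 * k^2,
                         fovWidth = 130 * k, fovHeight = 130 * k)
  rK <- suppressWarnings(runStereology(roiK, cellsK, desK,
                                       tissueClassifier = vitalEverywhere))
  expect_equal(areaFractionOf(rK), areaFractionOf(r1))
  expect_equal(qA(rK), qA(r1) / k^2)
})

test_that("Q_A is unbiased for a Poisson profile process (pilot power)", {
  qa <- vapply(1:80, function(r) qA(poissonReplicate(500, "medium",
                                                     9000 + r)),
               numeric(1))
  se <- sd(qa) / sqrt(length(qa))
  expect_lt(abs(mean(qa) - 500), 3 * se)
})
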