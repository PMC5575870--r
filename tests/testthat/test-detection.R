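# shared fitted model for the detection tests (memoized in the package)
.testModel <- function() defaultDetectionModel(99L)

.flatImage <- function(col, H = 64, W = 64, pixelSize = 0.904) {
  arr <- array(0, c(H, W, 3))
  for (k in 1:3) arr[, , k] <- col[k]
  new("StainImage", data = arr, pixelSize = pixelSize, marker = "CD3")
}

test_that("block-mean downsampling is exact", {
  img <- .flatImage(c(120, 130, 140), 40, 40)
  expect_identical(makeLowres(img, 1), img)
  one <- makeLowres(img, 40)
  expect_equal(dim(one@data), c(1L, 1L, 3L))
  expect_equal(as.numeric(one@data), c(120, 130, 140))
  expect_equal(one@pixelSize, 0.904 * 40)

  chk <- array(0, c(4, 4, 3))
  chk[, , 1] <- matrix(c(0, 255), 4, 4)[, c(1, 1, 1, 1)]
  chk[, , 1] <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) * 255)
  chk[, , 2] <- chk[, , 1]; chk[, , 3] <- chk[, , 1]
  lo <- makeLowres(new("StainImage", data = chk, pixelSize = 1,
                       marker = "CD3"), 2)
  expect_true(all(lo@data == 127.5))
  expect_warning(makeLowres(img, 100), "1x1")
})

test_that("chromaticity features match hand computations", {
  f <- chromaticityFeatures(.flatImage(c(255, 0, 0)), window = 1)
  expect_equal(f$red[1, 1], 1); expect_equal(f$blue[1, 1], 0)
  g <- chromaticityFeatures(.flatImage(c(100, 100, 100)), window = 1)
  expect_equal(g$red[1, 1], 1 / 3); expect_equal(g$blue[1, 1], 1 / 3)
  dab <- chromaticityFeatures(.flatImage(c(150, 90, 60)), window = 1)
  expect_equal(dab$red[1, 1], 0.5); expect_equal(dab$blue[1, 1], 0.2)
  blk <- chromaticityFeatures(.flatImage(c(0, 0, 0)), window = 1)
  expect_equal(blk$red[1, 1], 1 / 3)
})

test_that("blob enhancement: zero on flat, peak at disk center, equivariant", {
  flat <- matrix(0.4, 80, 80)
  expect_lt(max(abs(blobEnhance(flat, c(2.5, 6), 0.904))), 1e-10)

  disk <- matrix(0, 101, 101)
  xs <- (1:101 - 0.5) * 0.904
  dd <- outer((xs - xs[51])^2, (xs - xs[51])^2, "+")
  disk[dd <= 16] <- 1          # radius 4 um
  resp <- blobEnhance(disk, c(2.5, 6), 0.904)
  expect_equal(which(resp == max(resp), arr.ind = TRUE)[1, ],
               c(row = 51L, col = 51L))

  shift <- matrix(0, 101, 101)
  shift[dd[c(11:101, 1:10), ] <= 16] <- 1   # same disk shifted by 10 rows
  respS <- blobEnhance(shift, c(2.5, 6), 0.904)
  expect_equal(respS[31:81, 21:81], resp[41:91, 21:81], tolerance = 1e-10)
})

test_that("LDA training recovers closed-form moments and separates clouds", {
  set.seed(5)
  X <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 4), ncol = 2),
             matrix(rnorm(100, c(0, 8)), ncol = 2, byrow = TRUE))
  y <- rep(c("a", "b", "c"), c(100, 100, 50))
  fit <- TILcount:::.fitLDA(X, y, c("f1", "f2"))
  expect_equal(unname(fit$means["a", ]), colMeans(X[y == "a", ]))
  expect_equal(fit$priors, c(100, 100, 50) / 250)
  pooled <- (crossprod(scale(X[y == "a", ], scale = FALSE)) +
             crossprod(scale(X[y == "b", ], scale = FALSE)) +
             crossprod(scale(X[y == "c", ], scale = FALSE))) / (250 - 3)
  expect_equal(unname(fit$cov), unname(pooled), tolerance = 1e-7)

  refit <- TILcount:::.fitLDA(X, y, c("f1", "f2"))
  expect_identical(fit, refit)

  # perfectly separated clouds classify their own training set
  sc <- TILcount:::.ldaScores(X, fit)
  acc <- mean(fit$classes[max.col(sc)] == y)
  expect_gt(acc, 0.97)
  expect_error(TILcount:::.fitLDA(X[1:100, ], factor(y[1:100],
                                                    levels = c("a", "b")),
                                  c("f1", "f2")), "training error")
})

test_that("pixel classification matches a brute-force posterior oracle", {
  model <- .testModel()
  fit <- model@cell
  set.seed(8)
  n <- 64 * 64
  X <- cbind(runif(n, 0.25, 0.55), runif(n, 0.15, 0.45), runif(n, 0.3, 1))
  feats <- list(red = matrix(X[, 1], 64), blue = matrix(X[, 2], 64),
                intensity = matrix(X[, 3], 64))
  mine <- classifyPixels(feats, model)
  post <- brutePosterior(X, fit$means, fit$cov, fit$priors)
  oracle <- post[, match("positive", fit$classes)] > 0.5
  expect_gt(mean(as.vector(mine) == oracle), 0.99)

  # the positive class mean itself is classified positive
  mu <- fit$means[match("positive", fit$classes), , drop = FALSE]
  fm <- list(red = matrix(mu[1], 1), blue = matrix(mu[2], 1),
             intensity = matrix(mu[3], 1))
  expect_true(classifyPixels(fm, model)[1, 1])

  # equidistant point with equal priors resolves to negative
  m2 <- model
  m2@cell$priors <- c(0.5, 0.5)
  mid <- colMeans(fit$means)
  # reflect so the point is exactly Mahalanobis-equidistant: the midpoint is
  fmid <- list(red = matrix(mid[1], 1), blue = matrix(mid[2], 1),
               intensity = matrix(mid[3], 1))
  expect_false(classifyPixels(fmid, m2)[1, 1])

  expect_error(classifyPixels(feats, detectionModel()), "not fitted")
})

test_that("MASS::lda agrees with the package discriminant on a toy set", {
  skip_if_not_installed("MASS")
  set.seed(12)
  X <- rbind(matrix(rnorm(300, 0), ncol = 3),
             matrix(rnorm(300, 1.5), ncol = 3))
  y <- rep(c("negative", "positive"), each = 100)
  fit <- TILcount:::.fitLDA(X, y, c("a", "b", "c"))
  sc <- TILcount:::.ldaScores(X, fit)
  mine <- fit$classes[max.col(sc)]
  ref <- as.character(predict(MASS::lda(X, grouping = y))$class)
  expect_gt(mean(mine == ref), 0.995)
})

test_that("artifact segmentation excludes an inserted band and is deterministic", {
  model <- .testModel()
  sec <- renderSection(trueDensity = c(central = 300, invasive = 300),
                       artifactFraction = 0.1, seed = 303)
  lr <- makeLowres(sec$image, round(9 / sec$pixelSize))
  a1 <- segmentArtifacts(lr, model)
  a2 <- segmentArtifacts(lr, model)
  expect_identical(a1, a2)

  # high-contrast pale cleft band inserted into plain tissue: near-exact mask
  arr <- array(0, c(775, 775, 3))
  for (k in 1:3) arr[, , k] <- TILcount:::.COL_BG[k]
  bandCols <- 222:498                       # 200.7..450.2 um at 0.904 um/px
  for (k in 1:3) arr[, bandCols, k] <- TILcount:::.COL_MUCIN[k]
  band <- new("StainImage", data = arr, pixelSize = 0.904, marker = "CD3")
  ab <- segmentArtifacts(makeLowres(band, 10), model)
  truthEx <- matrix(FALSE, nrow(ab$mask), ncol(ab$mask))
  truthEx[, ceiling(222 / 10):floor(498 / 10)] <- TRUE
  iouBand <- sum(truthEx & ab$mask) / sum(truthEx | ab$mask)
  expect_gte(iouBand, 0.9)

  # rendered sections: each artifact class recovered with decent recall,
  # gross mask overlap as a functional floor
  fac <- lr@pixelSize / sec$pixelSize
  lab <- TILcount:::.lowresLabels(sec$masks, fac, dim(lr@data)[1:2])
  for (cl in c("mucin", "fold", "necrosis")) {
    sel <- !is.na(lab) & lab == cl
    expect_gt(mean(a1$mask[sel]), 0.8)
  }
  truthEx2 <- !is.na(lab) & lab != "tissue"
  predEx2 <- a1$mask & !is.na(lab)
  iou <- sum(truthEx2 & predEx2) / sum(truthEx2 | predEx2)
  expect_gt(iou, 0.55)
  # uniform tissue-colored image stays analyzable
  flat <- makeLowres(.flatImage(c(207, 203, 223), 120, 120), 10)
  expect_false(any(segmentArtifacts(flat, model)$mask))
  expect_error(segmentArtifacts(lr, detectionModel()), "not fitted")
})

test_that("watershed separation splits overlapping disks and filters objects", {
  model <- .testModel()
  px <- 0.904
  draw <- function(centers, r = 4.5) {
    arr <- array(0, c(90, 90, 3))
    for (k in 1:3) arr[, , k] <- TILcount:::.COL_BG[k]
    img <- TILcount:::.paintDisks(arr, px, centers[, 1], centers[, 2],
                                  rep(r, nrow(centers)),
                                  TILcount:::.COL_DAB, rep(0.9, nrow(centers)))
    new("StainImage", data = img, pixelSize = px, marker = "CD3")
  }
  one <- draw(cbind(40, 40))
  f <- chromaticityFeatures(one, model@meanFilterWindow)
  pos <- classifyPixels(f, model)
  enh <- blobEnhance(f$red, model@blobRadiusRange, px)
  obj <- separateAndFilter(pos, enh, model, px, f$red)
  expect_identical(sum(obj$label == "positive"), 1L)

  # two disks overlapping by ~30% of the radius -> split into 2
  two <- draw(rbind(c(36, 40), c(36 + 2 * 4.5 * 0.85, 40)))
  f2 <- chromaticityFeatures(two, model@meanFilterWindow)
  pos2 <- classifyPixels(f2, model)
  enh2 <- blobEnhance(f2$red, model@blobRadiusRange, px)
  obj2 <- separateAndFilter(pos2, enh2, model, px, f2$red)
  expect_identical(sum(obj2$label == "positive"), 2L)

  # an object below the minimum area is rejected
  tiny <- draw(cbind(40, 40), r = 1.2)
  f3 <- chromaticityFeatures(tiny, model@meanFilterWindow)
  obj3 <- separateAndFilter(classifyPixels(f3, model),
                            blobEnhance(f3$red, model@blobRadiusRange, px),
                            model, px, f3$red)
  expect_identical(sum(obj3$label == "positive"), 0L)
})

test_that("end-to-end detection: blank tissue, recovery, determinism, artifact monotonicity", {
  model <- .testModel()
  blank <- renderSection(trueDensity = c(central = 0, invasive = 0),
                         seed = 61)
  rb <- runDetection(blank$image, blank$rois$central, model)
  expect_equal(qA(rb), 0)
  expect_equal(areaFractionOf(rb), 0)

  sec <- renderSection(trueDensity = c(central = 700, invasive = 400),
                       seed = 62)
  r1 <- runDetection(sec$image, sec$rois$central, model)
  r2 <- runDetection(sec$image, sec$rois$central, model)
  expect_identical(estimateTable(r1), estimateTable(r2))
  truth <- sec$truth$trueDensity[sec$truth$region == "central"]
  expect_lt(abs(qA(r1) - truth) / truth, 0.05)

  # punching a hole (enlarged exclusion) cannot increase the count
  v <- sec$rois$central@vertices
  cx <- mean(v[, 1]); cy <- mean(v[, 2])
  holed <- regionOfInterest(v, holes = list(
    rbind(c(cx - 60, cy - 60), c(cx + 60, cy - 60), c(cx + 60, cy + 60),
          c(cx - 60, cy + 60))), label = "central",
    sectionId = sec$sectionId)
  rh <- runDetection(sec$image, holed, model)
  expect_lte(rh@raw$nPositive, r1@raw$nPositive)
})
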