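# Independent oracles used across the suite. These deliberately re-derive
# quantities by different algorithms than the package implementation.

# scalar crossing-number point-in-polygon (upward-ray casting, edge loop)
crossingNumberOracle <- function(px, py, ring) {
  n <- nrow(ring)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- ring[i, 1]; y1 <- ring[i, 2]; x2 <- ring[j, 1]; y2 <- ring[j, 2]
    if ((y1 > py) != (y2 > py)) {
      xAt <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (xAt > px) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Monte-Carlo area of an ROI (mm^2) via rejection sampling with the oracle
mcPolygonArea <- function(roi, n = 1e6, seed = 1) {
  set.seed(seed)
  v <- roi@vertices
  bb <- c(min(v[, 1]), min(v[, 2]), max(v[, 1]), max(v[, 2]))
  px <- runif(n, bb[1], bb[3]); py <- runif(n, bb[2], bb[4])
  inside <- vapply(seq_len(n), function(i) {
    if (!crossingNumberOracle(px[i], py[i], v)) return(FALSE)
    for (h in roi@holes)
      if (crossingNumberOracle(px[i], py[i], h)) return(FALSE)
    TRUE
  }, logical(1))
  mean(inside) * (bb[3] - bb[1]) * (bb[4] - bb[2]) / 1e6
}

# brute-force Gaussian class posterior (full density evaluation, no
# discriminant shortcut)
brutePosterior <- function(X, means, covm, priors) {
  iC <- solve(covm)
  logdet <- determinant(covm, logarithm = TRUE)$modulus
  ll <- sapply(seq_len(nrow(means)), function(k) {
    d <- sweep(X, 2, means[k, ])
    -0.5 * rowSums((d %*% iC) * d) - 0.5 * logdet + log(priors[k])
  })
  mx <- apply(ll, 1, max)
  e <- exp(ll - mx)
  e / rowSums(e)
}

# random simple-ish convex-star polygon for area tests
randomStarPolygon <- function(nv = 12, seed = 1, rMin = 200, rMax = 600,
                              center = c(500, 500)) {
  set.seed(seed)
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- runif(nv, rMin, rMax)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

# random elliptical profile pattern on [0, size]^2
randomEllipses <- function(n, size = 400, seed = 1, marker = "CD3") {
  set.seed(seed)
  cellProfiles(data.frame(
    x = runif(n, 0, size), y = runif(n, 0, size),
    a = runif(n, 2.5, 6), b = runif(n, 2, 5), theta = runif(n, 0, pi),
    marker = marker, stainStrength = 1, nucleusVisible = TRUE))
}

# total counted over a complete frame tiling covering all profiles
tessellationTotal <- function(cells, side = 40) {
  d <- profileData(cells)
  lo <- floor(min(d$x - d$a, d$y - d$a) / side) - 1L
  hi <- ceiling(max(d$x + d$a, d$y + d$a) / side) + 1L
  tot <- 0L
  for (i in lo:hi) for (j in lo:hi) {
    fr <- c(i * side, j * side, (i + 1) * side, (j + 1) * side)
    tot <- tot + length(applyCountingFrame(fr, cells))
  }
  tot
}

# all-vital tissue classifier
vitalEverywhere <- function(pts) rep(TRUE, nrow(pts))

# Poisson Boolean-model replicate on an ROI with collar; returns a
# runStereology record (used by unbiasedness checks)
poissonReplicate <- function(lambda, dclass, seed, L = 2000, collar = 160,
                             radius = 4.5) {
  roi <- regionOfInterest(rbind(c(0, 0), c(L, 0), c(L, L), c(0, L)))
  area <- (L + 2 * collar)^2 / 1e6
  set.seed(seed)
  n <- rpois(1, lambda * area)
  cells <- cellProfiles(x = runif(n, -collar, L + collar),
                        y = runif(n, -collar, L + collar), radius = radius)
  des <- samplingDesign(densityClass = dclass, seed = seed)
  runStereology(roi, cells, des, tissueClassifier = vitalEverywhere,
                minCount = 0)
}
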