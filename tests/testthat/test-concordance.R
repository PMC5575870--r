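test_that("Spearman correlation: exact cases, ties and tumor means", {
  p <- data.frame(valueA = 1:10, valueB = (1:10)^3, tumor = rep(1:5, 2))
  expect_equal(spearmanConcordance(p)$rho, 1)
  p$valueB <- -p$valueA
  expect_equal(spearmanConcordance(p)$rho, -1)

  # tied example against the direct average-rank formula
  a <- c(1, 2, 2, 3, 5, 5); b <- c(2, 1, 4, 4, 4, 6)
  rho <- spearmanConcordance(data.frame(valueA = a, valueB = b))$rho
  expect_equal(rho, cor(rank(a), rank(b)), tolerance = 1e-12)

  # per-tumor means first average the sections of each tumor
  q <- data.frame(valueA = c(1, 3, 10, 30, 2, 20),
                  valueB = c(6, 4, 60, 40, 5, 50),
                  tumor = c(1, 1, 2, 2, 3, 3))
  byTumor <- spearmanConcordance(q, "per_tumor_mean")
  expect_identical(byTumor$n, 3L)
  expect_equal(byTumor$rho,
               cor(tapply(q$valueA, q$tumor, mean),
                   tapply(q$valueB, q$tumor, mean), method = "spearman"))

  expect_error(spearmanConcordance(
    data.frame(valueA = rep(1, 5), valueB = 1:5)), "constant")
  expect_error(spearmanConcordance(
    data.frame(valueA = 1:2, valueB = 2:1)), "3 pairs")
})

test_that("ICC: degenerate cases and invariances", {
  g <- rep(1:6, each = 3)
  pure <- rep(c(10, 20, 40, 80, 160, 320), each = 3)
  r1 <- iccOneWay(pure, g)
  expect_equal(r1$icc, 1, tolerance = 1e-6)

  set.seed(9)
  noise <- exp(rnorm(18))
  r0 <- iccOneWay(noise, g)
  expect_lt(r0$icc, 0.5)

  expect_warning(rEq <- iccOneWay(rep(7, 18), g), "all values equal")
  expect_equal(rEq$icc, 0)
  expect_warning(iccOneWay(c(0, exp(rnorm(17))), g), "offset")

  # multiplying raw values by a constant (log scale) leaves ICC unchanged
  set.seed(10)
  y <- exp(rnorm(6, sd = 1)[g] + rnorm(18, sd = 0.5))
  expect_equal(iccOneWay(y, g)$icc, iccOneWay(y * 37.5, g)$icc,
               tolerance = 1e-10)
  # adding a constant to all log values likewise
  expect_equal(iccOneWay(log(y), g, logTransform = FALSE)$icc,
               iccOneWay(log(y) + 5, g, logTransform = FALSE)$icc,
               tolerance = 1e-10)
})

test_that("REML ICC matches the ANOVA moment estimator on balanced data", {
  set.seed(14)
  g <- factor(rep(1:43, each = 3))
  y <- rnorm(43, sd = sqrt(0.49))[g] + rnorm(129, sd = sqrt(0.21))
  r <- iccOneWay(y, g, logTransform = FALSE)
  ms <- summary(stats::aov(y ~ g))[[1]][["Mean Sq"]]
  s2w <- ms[2]; s2b <- (ms[1] - ms[2]) / 3
  expect_equal(r$icc, s2b / (s2b + s2w), tolerance = 1e-5)
})

test_that("ICC estimator is calibrated across the reported regime", {
  for (target in c(0.3, 0.6, 0.75)) {
    icc <- numeric(500); covered <- logical(500)
    set.seed(1000 + round(100 * target))
    for (r in 1:500) {
      g <- rep(1:43, each = 3)
      y <- rnorm(43, 0, sqrt(target))[g] + rnorm(129, 0, sqrt(1 - target))
      res <- iccOneWay(y, g, logTransform = FALSE)
      icc[r] <- res$icc
      covered[r] <- res$ciLow <= target && res$ciHigh >= target
    }
    expect_lt(abs(mean(icc) - target), 0.03)
    expect_gte(mean(covered), 0.92)
    expect_lte(mean(covered), 0.98)
  }
})

test_that("Bland-Altman limits match hand computations and coverage", {
  idp <- blandAltman(c(3, 5, 9), c(3, 5, 9))
  expect_equal(idp$meanDiff, 0)
  expect_equal(idp$loaLow, 0); expect_equal(idp$loaHigh, 0)

  ba <- blandAltman(c(1, 2), c(2, 1))   # diffs -1, +1
  expect_equal(ba$meanDiff, 0)
  expect_equal(ba$sdDiff, sqrt(2))
  expect_equal(ba$loaHigh, 1.96 * sqrt(2))

  set.seed(15)
  a <- rnorm(1e4); b <- a - rnorm(1e4)
  bb <- blandAltman(a, b)
  inLoa <- mean(bb$diffs >= bb$loaLow & bb$diffs <= bb$loaHigh)
  expect_gt(inLoa, 0.94); expect_lt(inLoa, 0.96)
})

test_that("concordance report reproduces independent recomputation", {
  set.seed(16)
  grid <- expand.grid(tumor = 1:8, section = 1:3,
                      region = c("central", "invasive"),
                      marker = c("CD3", "CD8"))
  truth <- exp(rnorm(8, 6, 0.6))[grid$tumor] *
    ifelse(grid$region == "invasive", 1.3, 1)
  stereo <- truth * exp(rnorm(nrow(grid), 0, 0.1))
  imga <- truth * exp(rnorm(nrow(grid), 0, 0.1))
  mk <- function(vals, method) data.frame(
    method = method, section_id = sprintf("t%02d_s%d", grid$tumor,
                                          grid$section),
    roi_label = as.character(grid$region), marker = as.character(grid$marker),
    q_a_per_mm2 = vals, area_fraction = pmin(1, vals / 1e4),
    tumor_id = grid$tumor)
  est <- rbind(mk(stereo, "stereology"), mk(imga, "image_analysis"))
  rep <- concordanceReport(est)

  expect_identical(nrow(rep$spearman), 2L * 2L * 2L)  # marker x region x grouping
  row <- rep$spearman[rep$spearman$marker == "CD3" &
                      rep$spearman$region == "central" &
                      rep$spearman$grouping == "per_section", ]
  sel <- grid$marker == "CD3" & grid$region == "central"
  expect_equal(row$rho, cor(imga[sel], stereo[sel], method = "spearman"))

  expect_identical(nrow(rep$icc), 2L * 2L * 2L)       # marker x region x method
  expect_identical(nrow(rep$iccPooled), 2L * 2L)      # marker x method
  expect_true(all(c("invasive_vs_central_stereology") %in%
                  rep$blandAltman$comparison))

  # identical method columns give rho = 1 everywhere
  est2 <- rbind(mk(stereo, "stereology"), mk(stereo, "image_analysis"))
  rep2 <- concordanceReport(est2)
  expect_true(all(abs(rep2$spearman$rho - 1) < 1e-12))

  # CSVs and optional plots are written to the output directory
  od <- file.path(tempdir(), "rep")
  concordanceReport(est, outDir = od, plots = TRUE)
  expect_true(file.exists(file.path(od, "spearman.csv")))
  expect_true(file.exists(file.path(od, "CD3_central_scatter.png")))
  expect_true(file.exists(file.path(od, "CD3_central_bland_altman.png")))
  unlink(od, recursive = TRUE)
})
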