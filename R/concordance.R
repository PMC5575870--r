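# Concordance and heterogeneity statistics: Spearman correlation between
# method estimates, variance-ratio ICC from a one-way random-effects model
# (REML), and Bland-Altman limits of agreement.

#' Spearman correlation between paired estimates
#'
#' Rank correlation with average ranks for ties, either per section or on
#' per-tumor means (the mean of the sections of each tumor is taken before
#' correlating).
#'
#' @param paired data.frame with columns \code{valueA}, \code{valueB} and,
#'   for the per-tumor grouping, \code{tumor}.
#' @param grouping "per_section" or "per_tumor_mean".
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
spearmanConcordance <- function(paired,
                                grouping = c("per_section",
                                             "per_tumor_mean")) {
  grouping <- match.arg(grouping)
  x <- paired$valueA; y <- paired$valueB
  if (grouping == "per_tumor_mean") {
    x <- tapply(x, paired$tumor, mean)
    y <- tapply(y, paired$tumor, mean)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way random-effects intraclass correlation
#'
#' Decomposes (log) values into between-tumor and within-tumor variance by a
#' one-way random-intercept model fitted with REML (tumors random, sections
#' as replicates) and reports ICC = sigma2_between / (sigma2_between +
#' sigma2_within): the share of the total estimator variation attributable to
#' differences among tumors. The 95% CI uses the large-sample (delta-method)
#' variance of the variance-component ratio, with bounds clipped to [0, 1];
#' \code{ci = "fstat"} instead inverts the one-way ANOVA F statistic.
#'
#' @param values numeric vector of estimates.
#' @param group grouping factor (tumor).
#' @param logTransform take natural logs first (zeros are offset by half the
#'   smallest positive value, with a warning).
#' @param ci "delta" or "fstat".
#' @param conf confidence level.
#' @return list of class \code{"ICCResult"}: \code{icc}, \code{ciLow},
#'   \code{ciHigh}, \code{sigma2Between}, \code{sigma2Within},
#'   \code{nGroups}, \code{nPerGroup}.
#' @export
iccOneWay <- function(values, group, logTransform = TRUE,
                      ci = c("delta", "fstat"), conf = 0.95) {
  ci <- match.arg(ci)
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  y <- values
  if (logTransform) {
    if (any(y < 0)) stop("negative values cannot be log-transformed")
    if (any(y == 0)) {
      off <- min(y[y > 0]) / 2
      warning(sprintf("zeros offset by %.4g before log transform", off))
      y <- y + off
    }
    y <- log(y)
  }
  if (stats::sd(y) == 0) {
    warning("all values equal; ICC defined as 0")
    return(structure(list(icc = 0, ciLow = 0, ciHigh = 0,
                          sigma2Between = 0, sigma2Within = 0,
                          nGroups = nlevels(group),
                          nPerGroup = mean(table(group))),
                     class = "ICCResult"))
  }
  ni0 <- as.numeric(table(group))
  if (length(unique(ni0)) == 1L && ni0[1] > 1L) {
    # balanced design: REML has a closed form (identical to the numerical
    # optimum, exact and invariant under affine data transforms)
    k <- ni0[1]; gN <- nlevels(group)
    gm <- tapply(y, group, mean)
    ssw <- sum((y - gm[group])^2)
    ssb <- k * sum((gm - mean(gm))^2)
    msw <- ssw / (gN * (k - 1))
    msb <- ssb / (gN - 1)
    if (msb > msw) {
      s2w <- msw
      s2b <- (msb - msw) / k
    } else {
      warning("between-tumor component at the zero boundary")
      s2b <- 0
      s2w <- (ssw + ssb) / (gN * k - 1)
    }
  } else {
    fit <- lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = y, g = group),
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                        lme4::.makeCC(action = "ignore", tol = 1e-4)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2b <- vc$vcov[vc$grp == "g"]
    s2w <- vc$vcov[vc$grp == "Residual"]
  }
  icc <- if (s2b + s2w > 0) s2b / (s2b + s2w) else 0

  g <- nlevels(group); N <- length(y)
  ni <- as.numeric(table(group))
  n0 <- (N - sum(ni^2) / N) / (g - 1)          # ANOVA replication coefficient
  alpha <- 1 - conf
  if (ci == "delta") {
    # large-sample variance via the mean squares implied by the REML fit
    msw <- s2w
    msb <- s2w + n0 * s2b
    den <- msb + (n0 - 1) * msw
    vMSB <- 2 * msb^2 / (g - 1)
    vMSW <- 2 * msw^2 / (N - g)
    vICC <- ((n0 * msw)^2 * vMSB + (n0 * msb)^2 * vMSW) / den^4
    z <- stats::qnorm(1 - alpha / 2)
    lo <- max(0, icc - z * sqrt(vICC)); hi <- min(1, icc + z * sqrt(vICC))
  } else {
    a <- stats::aov(y ~ group)
    ms <- summary(a)[[1L]][["Mean Sq"]]
    Fobs <- ms[1L] / ms[2L]
    Fl <- Fobs / stats::qf(1 - alpha / 2, g - 1, N - g)
    Fu <- Fobs / stats::qf(alpha / 2, g - 1, N - g)
    lo <- max(0, (Fl - 1) / (Fl + n0 - 1))
    hi <- min(1, (Fu - 1) / (Fu + n0 - 1))
  }
  structure(list(icc = icc, ciLow = lo, ciHigh = hi,
                 sigma2Between = s2b, sigma2Within = s2w,
                 nGroups = g, nPerGroup = mean(ni)),
            class = "ICCResult")
}

#' @export
print.ICCResult <- function(x, ...) {
  cat(sprintf("ICC (one-way random effects): %.3f (95%% CI %.3f-%.3f)\n",
              x$icc, x$ciLow, x$ciHigh))
  cat(sprintf("  sigma2 between: %.4g  within: %.4g  (%d groups, mean %.1f/group)\n",
              x$sigma2Between, x$sigma2Within, x$nGroups, x$nPerGroup))
  invisible(x)
}

#' Bland-Altman agreement summary
#'
#' Mean difference, SD of differences and the +/- 1.96 SD limits of
#' agreement for paired values (method A vs B, or region vs region on
#' per-tumor means).
#'
#' @param a,b paired numeric vectors.
#' @return list of class \code{"BlandAltmanResult"}: \code{meanDiff},
#'   \code{sdDiff}, \code{loaLow}, \code{loaHigh}, \code{n}.
#' @export
blandAltman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  structure(list(meanDiff = m, sdDiff = s,
                 loaLow = m - 1.96 * s, loaHigh = m + 1.96 * s,
                 n = length(d), means = (a + b) / 2, diffs = d),
            class = "BlandAltmanResult")
}

#' @export
print.BlandAltmanResult <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g, SD %.4g, LoA [%.4g, %.4g] (n=%d)\n",
              x$meanDiff, x$sdDiff, x$loaLow, x$loaHigh, x$n))
  invisible(x)
}

#' Concordance report tables
#'
#' Builds the method-comparison tables from a flat estimate table containing
#' both methods: Spearman correlation by marker x region (per section and on
#' per-tumor means), ICC by marker x region x method, the pooled ICC using
#' all section-region values of each tumor, and Bland-Altman summaries
#' (method A vs B per section; central vs invasive on per-tumor means).
#'
#' @param estimates data.frame as from \code{\link{estimateTable}}, with an
#'   added \code{tumor_id} column (or section ids of the form
#'   \code{t<tumor>_s<section>}).
#' @param value which estimate to compare: "q_a_per_mm2" or "area_fraction".
#' @param outDir optional directory; tables are written as CSVs when given.
#' @param plots when TRUE (and \code{outDir} is set), also writes a
#'   method-vs-method scatter and a Bland-Altman plot per marker x region
#'   as PNGs.
#' @return list of data.frames: \code{spearman}, \code{icc},
#'   \code{iccPooled}, \code{blandAltman}.
#' @export
concordanceReport <- function(estimates, value = "q_a_per_mm2",
                              outDir = NULL, plots = FALSE) {
  est <- as.data.frame(estimates)
  if (is.null(est$tumor_id))
    est$tumor_id <- sub("^t([0-9]+)_.*$", "\\1", est$section_id)
  methods <- sort(unique(est$method))
  sp <- list(); ic <- list(); ba <- list(); icp <- list()
  for (mk in unique(est$marker)) {
    for (rg in unique(est$roi_label)) {
      sub <- est[est$marker == mk & est$roi_label == rg, ]
      if (length(methods) == 2L) {
        a <- sub[sub$method == methods[1L], ]
        b <- sub[sub$method == methods[2L], ]
        key <- intersect(a$section_id, b$section_id)
        if (length(setdiff(union(a$section_id, b$section_id), key)))
          message("skipping unpaired sections in ", mk, "/", rg)
        if (length(key) >= 3L) {
          a <- a[match(key, a$section_id), ]; b <- b[match(key, b$section_id), ]
          paired <- data.frame(valueA = a[[value]], valueB = b[[value]],
                               tumor = a$tumor_id)
          for (grp in c("per_section", "per_tumor_mean")) {
            s <- spearmanConcordance(paired, grp)
            sp[[length(sp) + 1L]] <- data.frame(
              marker = mk, region = rg, grouping = grp,
              methodA = methods[1L], methodB = methods[2L],
              rho = s$rho, p = s$p, n = s$n)
          }
          bb <- blandAltman(a[[value]], b[[value]])
          ba[[length(ba) + 1L]] <- data.frame(
            marker = mk, region = rg,
            comparison = paste(methods, collapse = "_vs_"),
            mean_diff = bb$meanDiff, sd_diff = bb$sdDiff,
            loa_low = bb$loaLow, loa_high = bb$loaHigh, n = bb$n)
          if (plots && !is.null(outDir)) {
            dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
            base <- file.path(outDir, paste0(mk, "_", rg))
            grDevices::png(paste0(base, "_scatter.png"), 640, 640)
            plot(a[[value]], b[[value]],
                 xlab = paste(methods[1L], value),
                 ylab = paste(methods[2L], value),
                 main = paste(mk, rg), pch = 19, col = "#00000088")
            abline(0, 1, col = "red3", lty = 2)
            grDevices::dev.off()
            grDevices::png(paste0(base, "_bland_altman.png"), 640, 640)
            plot(bb$means, bb$diffs, pch = 19, col = "#00000088",
                 xlab = paste("mean of methods,", value),
                 ylab = "difference (A - B)", main = paste(mk, rg))
            abline(h = bb$meanDiff, col = "blue3")
            abline(h = c(bb$loaLow, bb$loaHigh), col = "red3", lty = 2)
            grDevices::dev.off()
          }
        }
      }
      for (me in methods) {
        s1 <- sub[sub$method == me, ]
        if (nrow(s1) >= 4L && length(unique(s1$tumor_id)) >= 2L) {
          r <- iccOneWay(s1[[value]], s1$tumor_id)
          ic[[length(ic) + 1L]] <- data.frame(
            marker = mk, region = rg, method = me, icc = r$icc,
            ci_low = r$ciLow, ci_high = r$ciHigh,
            sigma2_between = r$sigma2Between, sigma2_within = r$sigma2Within)
        }
      }
    }
    # pooled: all section-region values per tumor, per method
    for (me in methods) {
      s1 <- est[est$marker == mk & est$method == me, ]
      if (nrow(s1) >= 4L && length(unique(s1$tumor_id)) >= 2L) {
        r <- iccOneWay(s1[[value]], s1$tumor_id)
        icp[[length(icp) + 1L]] <- data.frame(
          marker = mk, method = me, icc = r$icc,
          ci_low = r$ciLow, ci_high = r$ciHigh)
      }
    }
    # central vs invasive difference on per-tumor means, per method
    for (me in methods) {
      s1 <- est[est$marker == mk & est$method == me, ]
      if (all(c("central", "invasive") %in% s1$roi_label)) {
        ce <- tapply(s1[[value]][s1$roi_label == "central"],
                     s1$tumor_id[s1$roi_label == "central"], mean)
        iv <- tapply(s1[[value]][s1$roi_label == "invasive"],
                     s1$tumor_id[s1$roi_label == "invasive"], mean)
        key <- intersect(names(ce), names(iv))
        if (length(key) >= 2L) {
          bb <- blandAltman(iv[key], ce[key])
          ba[[length(ba) + 1L]] <- data.frame(
            marker = mk, region = "both",
            comparison = paste0("invasive_vs_central_", me),
            mean_diff = bb$meanDiff, sd_diff = bb$sdDiff,
            loa_low = bb$loaLow, loa_high = bb$loaHigh, n = bb$n)
        }
      }
    }
  }
  out <- list(spearman = do.call(rbind, sp), icc = do.call(rbind, ic),
              iccPooled = do.call(rbind, icp),
              blandAltman = do.call(rbind, ba))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) if (!is.null(out[[nm]]))
      utils::write.csv(out[[nm]], file.path(outDir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
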