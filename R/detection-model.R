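# Linear Bayesian (shared-covariance Gaussian) pixel classification: closed-
# form training moments, posterior scoring, artifact segmentation, and JSON
# persistence of all model parameters.

#' Construct an untrained detection model
#'
#' @param blobRadiusRange cell radius range in um for blob enhancement.
#' @param minObjectArea minimum accepted object area in um^2.
#' @param weakStainCutoff minimum mean red chromaticity of an accepted object.
#' @param lowresPixelSize target pixel size (um) for artifact segmentation.
#' @param meanFilterWindow box mean-filter window (pixels).
#' @param watershedTolerance normalized peak prominence for the watershed.
#' @return A \linkS4class{DetectionModel} with unfitted classifiers.
#' @export
detectionModel <- function(blobRadiusRange = c(3, 5), minObjectArea = 12,
                           weakStainCutoff = 0.38, lowresPixelSize = 9,
                           meanFilterWindow = 5, watershedTolerance = 0.05) {
  new("DetectionModel", cell = list(), artifact = list(),
      blobRadiusRange = blobRadiusRange, minObjectArea = minObjectArea,
      weakStainCutoff = weakStainCutoff, lowresPixelSize = lowresPixelSize,
      meanFilterWindow = meanFilterWindow,
      watershedTolerance = watershedTolerance, version = "1")
}

# closed-form LDA moments: class means, pooled covariance, priors
.fitLDA <- function(X, y, features) {
  y <- factor(y)
  classes <- levels(y)
  if (any(table(y) == 0L) || length(classes) < 2L)
    stop("training error: every class needs at least one labeled pixel")
  d <- ncol(X)
  means <- matrix(0, length(classes), d,
                  dimnames = list(classes, features))
  S <- matrix(0, d, d)
  for (i in seq_along(classes)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    means[i, ] <- colMeans(Xi)
    if (nrow(Xi) > 1L)
      S <- S + crossprod(sweep(Xi, 2L, means[i, ]))
  }
  S <- S / (nrow(X) - length(classes))
  # tiny ridge keeps the shared covariance invertible for degenerate samples
  S <- S + diag(1e-9 * mean(diag(S)) + 1e-12, d)
  list(classes = classes, means = means, cov = S,
       priors = as.numeric(table(y)) / length(y), features = features)
}

# linear discriminant scores: n x K matrix of log pi_k + x' iC mu_k - ...
.ldaScores <- function(X, fit) {
  iC <- solve(fit$cov)
  Wt <- iC %*% t(fit$means)                      # d x K
  b <- -0.5 * colSums(t(fit$means) * Wt) + log(fit$priors)
  sweep(X %*% Wt, 2L, b, "+")
}

# posterior of class k from scores (softmax, numerically stable)
.ldaPosterior <- function(scores) {
  mx <- apply(scores, 1L, max)
  e <- exp(scores - mx)
  e / rowSums(e)
}

#' Train the detection model on rendered training sections
#'
#' Fits both linear Bayesian pixel classifiers from labeled synthetic
#' sections (as returned by \code{\link{renderSection}}): the full-resolution
#' positive/negative cell classifier on the chromaticity feature stack, and
#' the low-resolution artifact classifier (tissue vs mucin/fold/necrosis) on
#' mean-filtered channel intensities. Parameters are the closed-form sample
#' moments of the labeled pixels, so refitting on identical data reproduces
#' the model exactly. Pixel subsampling is deterministic.
#'
#' @param sections list of \code{\link{renderSection}} results.
#' @param model A \linkS4class{DetectionModel} carrying the thresholds.
#' @param maxPerClass maximum labeled pixels retained per class.
#' @return The fitted \linkS4class{DetectionModel}.
#' @export
trainDetectionModel <- function(sections, model = detectionModel(),
                                maxPerClass = 20000L) {
  stopifnot(length(sections) >= 1L)
  Xc <- list(); yc <- list(); Xa <- list(); ya <- list()
  for (sec in sections) {
    f <- chromaticityFeatures(sec$image, model@meanFilterWindow)
    msk <- sec$masks
    analyzable <- msk$roi > 0L & msk$artifact == 0L
    pos <- which(msk$cellStrong & analyzable)
    neg <- which(!msk$cellAll & analyzable)
    Xc[[length(Xc) + 1L]] <- cbind(f$red[pos], f$blue[pos], f$intensity[pos])
    yc[[length(yc) + 1L]] <- rep("positive", length(pos))
    Xc[[length(Xc) + 1L]] <- cbind(f$red[neg], f$blue[neg], f$intensity[neg])
    yc[[length(yc) + 1L]] <- rep("negative", length(neg))

    lr <- makeLowres(sec$image,
                     max(1L, round(model@lowresPixelSize / sec$pixelSize)))
    fac <- lr@pixelSize / sec$pixelSize
    lrF <- lapply(1:3, function(k) .boxFilter(lr@data[, , k], 3L))
    # label low-res pixels by majority of the full-res masks they cover
    lab <- .lowresLabels(msk, fac, dim(lr@data)[1:2])
    keep <- !is.na(lab)
    Xa[[length(Xa) + 1L]] <- cbind(lrF[[1]][keep], lrF[[2]][keep],
                                   lrF[[3]][keep])
    ya[[length(ya) + 1L]] <- lab[keep]
  }
  Xc <- do.call(rbind, Xc); yc <- unlist(yc)
  Xa <- do.call(rbind, Xa); ya <- unlist(ya)
  sub <- function(X, y, nmax) {
    idx <- .withSeed(20260101L, unlist(lapply(split(seq_along(y), y),
      function(i) if (length(i) > nmax) sort(sample(i, nmax)) else i)))
    list(X = X[idx, , drop = FALSE], y = y[idx])
  }
  cc <- sub(Xc, yc, maxPerClass)
  aa <- sub(Xa, ya, maxPerClass)
  model@cell <- .fitLDA(cc$X, cc$y, c("red", "blue", "intensity"))
  model@artifact <- .fitLDA(aa$X, aa$y, c("meanR", "meanG", "meanB"))
  validObject(model)
  model
}

# majority-vote labels of low-res pixels: tissue / mucin / fold / necrosis,
# NA outside the ROIs
.lowresLabels <- function(msk, fac, dimLR) {
  H2 <- dimLR[1]; W2 <- dimLR[2]
  rIdx <- rep(seq_len(H2), each = fac)[seq_len(H2 * fac)]
  cIdx <- rep(seq_len(W2), each = fac)[seq_len(W2 * fac)]
  block <- function(m) {
    m <- m[seq_len(H2 * fac), seq_len(W2 * fac)]
    t(rowsum(t(rowsum(m + 0, rIdx)), cIdx)) / fac^2
  }
  inRoi <- block(msk$roi > 0L) > 0.5
  lab <- matrix(NA_character_, H2, W2)
  lab[inRoi] <- "tissue"
  for (i in seq_along(msk$artifactClasses)) {
    frac <- block(msk$artifact == i)
    lab[inRoi & frac > 0.5] <- msk$artifactClasses[i]
  }
  lab
}

#' Classify pixels as positive or negative
#'
#' Applies the trained two-class linear discriminant to the chromaticity
#' feature stack and thresholds the posterior at 0.5. The decision boundary
#' is affine in feature space; a pixel exactly on the boundary (posterior
#' 0.5) is resolved to negative.
#'
#' @param features list as returned by \code{\link{chromaticityFeatures}}.
#' @param model a trained \linkS4class{DetectionModel}.
#' @return Logical matrix, TRUE = positive.
#' @export
classifyPixels <- function(features, model) {
  if (!length(model@cell))
    stop("model not fitted: train the cell classifier first")
  fit <- model@cell
  if (length(fit$features) != 3L)
    stop("feature/model dimension mismatch")
  X <- cbind(as.vector(features$red), as.vector(features$blue),
             as.vector(features$intensity))
  sc <- .ldaScores(X, fit)
  pos <- sc[, match("positive", fit$classes)] >
         sc[, match("negative", fit$classes)]
  matrix(pos, nrow(features$red), ncol(features$red))
}

#' Segment artifacts at low resolution
#'
#' Per-pixel argmax of the artifact classifier's posterior over
#' \{tissue, mucin, fold, necrosis\} on the mean-filtered low-resolution
#' image, followed by rule-based post-processing: excluded blobs smaller than
#' \code{minBlobArea} are returned to tissue, and analyzable islands smaller
#' than \code{minHoleArea} fully enclosed in excluded regions are filled.
#'
#' @param lowres low-resolution \linkS4class{StainImage} (from
#'   \code{\link{makeLowres}}).
#' @param model a trained \linkS4class{DetectionModel}.
#' @param minBlobArea,minHoleArea post-processing areas in um^2.
#' @return list with \code{mask} (logical matrix, TRUE = excluded),
#'   \code{classMap} (character matrix), \code{pixelSize}.
#' @export
segmentArtifacts <- function(lowres, model, minBlobArea = 2000,
                             minHoleArea = 2000) {
  if (!length(model@artifact))
    stop("model not fitted: train the artifact classifier first")
  fit <- model@artifact
  lrF <- lapply(1:3, function(k) .boxFilter(lowres@data[, , k], 3L))
  X <- cbind(as.vector(lrF[[1]]), as.vector(lrF[[2]]), as.vector(lrF[[3]]))
  sc <- .ldaScores(X, fit)
  cls <- fit$classes[max.col(sc, ties.method = "first")]
  d <- dim(lowres@data)[1:2]
  classMap <- matrix(cls, d[1], d[2])
  excluded <- classMap != "tissue"
  pxArea <- lowres@pixelSize^2
  # drop small excluded blobs
  lab <- EBImage::bwlabel(excluded + 0)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes * pxArea < minBlobArea)
    excluded[lab %in% drop] <- FALSE
  }
  # fill small enclosed analyzable holes
  lab <- EBImage::bwlabel((!excluded) + 0)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    fill <- setdiff(which(sizes * pxArea < minHoleArea), border)
    excluded[lab %in% fill] <- TRUE
  }
  classMap[!excluded] <- "tissue"
  classMap[excluded & classMap == "tissue"] <- "enclosed"
  list(mask = excluded, classMap = classMap, pixelSize = lowres@pixelSize)
}

#' Persist / restore a detection model as JSON
#'
#' All parameters (class means, shared covariances, priors, thresholds) are
#' written to a schema-versioned JSON document.
#'
#' @param model a \linkS4class{DetectionModel}.
#' @param path file path.
#' @return \code{readDetectionModel} returns the restored model.
#' @export
writeDetectionModel <- function(model, path) {
  ser <- function(fit) if (!length(fit)) NULL else
    list(classes = fit$classes, means = fit$means, cov = fit$cov,
         priors = fit$priors, features = fit$features)
  doc <- list(schema_version = model@version,
              cell = ser(model@cell), artifact = ser(model@artifact),
              blob_radius_range = model@blobRadiusRange,
              min_object_area = model@minObjectArea,
              weak_stain_cutoff = model@weakStainCutoff,
              lowres_pixel_size = model@lowresPixelSize,
              mean_filter_window = model@meanFilterWindow,
              watershed_tolerance = model@watershedTolerance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeDetectionModel
#' @export
readDetectionModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  des <- function(fit) {
    if (is.null(fit)) return(list())
    means <- matrix(unlist(fit$means), nrow = length(fit$classes),
                    byrow = FALSE)
    if (is.matrix(fit$means)) means <- fit$means
    dimnames(means) <- list(fit$classes, fit$features)
    covm <- if (is.matrix(fit$cov)) fit$cov else
      matrix(unlist(fit$cov), length(fit$features), byrow = FALSE)
    list(classes = fit$classes, means = means, cov = covm,
         priors = fit$priors, features = fit$features)
  }
  new("DetectionModel", cell = des(doc$cell), artifact = des(doc$artifact),
      blobRadiusRange = doc$blob_radius_range,
      minObjectArea = doc$min_object_area,
      weakStainCutoff = doc$weak_stain_cutoff,
      lowresPixelSize = doc$lowres_pixel_size,
      meanFilterWindow = doc$mean_filter_window,
      watershedTolerance = doc$watershed_tolerance,
      version = doc$schema_version)
}
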