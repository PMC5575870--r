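# Pixel-level feature extraction for the automated detection pipeline.

#' Block-mean downsampling of a stain image
#'
#' Emulates the software-generated low-magnification representation used for
#' artifact segmentation. Each output pixel is the exact mean of a
#' factor x factor block (no integer rounding); trailing rows/columns that do
#' not fill a block are dropped.
#'
#' @param img A \linkS4class{StainImage}.
#' @param factor integer downsampling factor (>= 1).
#' @return A \linkS4class{StainImage} with pixel size scaled by \code{factor}.
#' @export
makeLowres <- function(img, factor) {
  stopifnot(is(img, "StainImage"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  d <- dim(img@data)
  H2 <- d[1] %/% factor; W2 <- d[2] %/% factor
  if (H2 < 1L || W2 < 1L) {
    warning("downsampling factor exceeds image size; returning a 1x1 image")
    out <- array(apply(img@data, 3L, mean), c(1L, 1L, 3L))
    return(new("StainImage", data = out,
               pixelSize = img@pixelSize * max(d[1:2]), marker = img@marker))
  }
  out <- array(0, c(H2, W2, 3L))
  rIdx <- rep(seq_len(H2), each = factor)
  cIdx <- rep(seq_len(W2), each = factor)
  for (k in 1:3) {
    m <- img@data[seq_len(H2 * factor), seq_len(W2 * factor), k]
    m <- rowsum(m, rIdx)                   # sum rows within blocks
    m <- t(rowsum(t(m), cIdx))             # sum cols within blocks
    out[, , k] <- m / factor^2
  }
  new("StainImage", data = out, pixelSize = img@pixelSize * factor,
      marker = img@marker)
}

.boxFilter <- function(m, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window <= 1L) return(m)
  k <- matrix(1 / window^2, window, window)
  EBImage::filter2(m, k, boundary = "replicate")
}

#' Chromaticity feature stack
#'
#' Per-pixel features used by the positive/negative pixel classifier: red
#' chromaticity R/(R+G+B), blue chromaticity B/(R+G+B), and box-mean-filtered
#' intensity (mean of the three channels, scaled to [0, 1]). Chromaticity at
#' black pixels (R+G+B = 0) is defined as 1/3.
#'
#' @param img A \linkS4class{StainImage}.
#' @param window mean-filter window (pixels, odd).
#' @return list of matrices \code{red}, \code{blue}, \code{intensity}.
#' @export
chromaticityFeatures <- function(img, window = 5) {
  stopifnot(is(img, "StainImage"))
  R <- img@data[, , 1L]; G <- img@data[, , 2L]; B <- img@data[, , 3L]
  tot <- R + G + B
  zero <- tot == 0
  tot[zero] <- 3
  red <- R / tot; blue <- B / tot
  red[zero] <- 1 / 3; blue[zero] <- 1 / 3
  list(red = red, blue = blue,
       intensity = .boxFilter(tot / 3, window) / 255)
}

# zero-sum scale-normalized LoG kernel for blob radius r (um)
.logKernel <- function(sigmaPx) {
  h <- max(2L, ceiling(3 * sigmaPx))
  xs <- -h:h
  g <- outer(xs^2, xs^2, "+")
  k <- (g - 2 * sigmaPx^2) / sigmaPx^4 * exp(-g / (2 * sigmaPx^2))
  k <- k - mean(k)              # exact zero response to flat images
  -sigmaPx^2 * k                # scale-normalized; positive at bright blobs
}

#' Circular blob enhancement
#'
#' Rotationally symmetric band-pass enhancement of bright circular objects:
#' the maximum over scales of the scale-normalized Laplacian-of-Gaussian
#' response, with scales mapped from the cell radius range through the pixel
#' geometry (sigma = r / sqrt(2)). The response to a disk of any radius in
#' range peaks at the disk center with comparable magnitude; the filter is
#' linear and shift-equivariant at each scale.
#'
#' @param x numeric matrix (a feature plane, e.g. red chromaticity).
#' @param radiusRange numeric length-2, blob radius range in um.
#' @param pixelSize um per pixel.
#' @param nScales number of scales spanning the range.
#' @return Matrix of enhanced responses (same size as \code{x}).
#' @export
blobEnhance <- function(x, radiusRange, pixelSize, nScales = 4L) {
  stopifnot(is.matrix(x), length(radiusRange) == 2L, pixelSize > 0)
  radii <- seq(radiusRange[1], radiusRange[2], length.out = nScales)
  out <- NULL
  for (r in radii) {
    sigmaPx <- r / (sqrt(2) * pixelSize)
    resp <- EBImage::filter2(x, .logKernel(sigmaPx), boundary = "replicate")
    out <- if (is.null(out)) resp else pmax(out, resp)
  }
  out
}
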