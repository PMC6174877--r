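## Hue histograms of masked pixels and two-sample KS comparison.

#' Hue of masked pixels
#'
#' Standard RGB -> HSV hue, in degrees in [0, 360), of every foreground
#' pixel of the mask.  Achromatic pixels (R = G = B) have undefined hue;
#' they are assigned 0 degrees and their count is attached as the
#' \code{nAchromatic} attribute.
#'
#' @param image height x width x 3 array on the 0-255 scale.
#' @param mask binary 0/1 matrix of matching dimensions with at least one
#'   foreground pixel.
#' @return numeric vector of hue degrees, attribute \code{nAchromatic}.
#' @examples
#' img <- array(c(0, 255, 0), dim = c(1, 1, 3))
#' maskedHues(img, matrix(1L, 1, 1))   # 120
#' @export
maskedHues <- function(image, mask) {
  stopifnotImage(image)
  stopifnotMask(mask)
  if (!identical(dim(image)[1:2], dim(mask)))
    ccStop("colorCard_geometry", "image and mask dimensions differ")
  sel <- which(mask == 1L)
  if (length(sel) == 0L)
    ccStop("colorCard_empty_object", "mask has no foreground pixels")
  px <- matrix(image, ncol = 3L)[sel, , drop = FALSE]
  hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 255)
  hues <- hsv[1, ] * 360
  hues[hues >= 360] <- 0
  structure(unname(hues),
            nAchromatic = sum(px[, 1] == px[, 2] & px[, 2] == px[, 3]))
}

#' Histogram of hue values
#'
#' Bins hue degrees into half-open bins \code{[edge, edge + width)} over
#' the full 0-360 support and normalizes to percent of all contributing
#' pixels (so percentages always sum to 100 regardless of the display
#' range, which is presentation metadata only).
#'
#' @param hues numeric vector of hue degrees in [0, 360).
#' @param binWidth bin width in degrees; must divide 360 (default 1).
#' @param displayRange length-2 numeric display window (default
#'   \code{c(0, 140)}, the green region of interest for plants).
#' @param imageId provenance label.
#' @return a [HueHistogram-class].
#' @export
hueHistogram <- function(hues, binWidth = 1, displayRange = c(0, 140),
                         imageId = "") {
  if (length(hues) == 0L)
    ccStop("colorCard_empty_object", "no hue values to histogram")
  if ((360 %% binWidth) != 0)
    ccStop("colorCard_config", "'binWidth' must divide 360")
  bins <- tabulate(pmin(hues %/% binWidth, 360 / binWidth - 1) + 1L,
                   nbins = as.integer(360 / binWidth))
  new("HueHistogram", binWidth = as.numeric(binWidth),
      percent = 100 * bins / length(hues), nPixels = length(hues),
      imageId = as.character(imageId),
      displayRange = as.numeric(displayRange))
}

#' Cumulative hue distribution
#'
#' The nondecreasing cumulative form F of a hue histogram over the full
#' 0-360 support, reaching 1 at the last bin.
#'
#' @param hist a [HueHistogram-class].
#' @return numeric vector of cumulative proportions, one per bin.
#' @export
hueCumulative <- function(hist) {
  stopifnot(is(hist, "HueHistogram"))
  cumsum(hist@percent) / 100
}

#' Average hue histograms across images
#'
#' Arithmetic mean of per-image percentage histograms, with a pointwise
#' 95\% confidence band (mean +/- 1.96 standard errors per bin).  All
#' histograms must share the same bin grid.  The pooled pixel count (sum
#' over images) is carried so the average can enter [ksCompare()] in
#' either sample-size mode.
#'
#' @param hists list of [HueHistogram-class] objects on one bin grid.
#' @param imageId label for the averaged histogram.
#' @return list with elements \code{mean} (a [HueHistogram-class]),
#'   \code{lower} and \code{upper} (numeric per-bin percent bounds).
#' @export
averageHueHistograms <- function(hists, imageId = "average") {
  stopifnot(length(hists) >= 1L,
            all(vapply(hists, is, logical(1), "HueHistogram")))
  bw <- hists[[1]]@binWidth
  if (!all(vapply(hists, function(h) h@binWidth == bw, logical(1))))
    ccStop("colorCard_grid", "histograms are on different bin grids")
  mat <- do.call(rbind, lapply(hists, function(h) h@percent))
  m <- colMeans(mat)
  se <- if (nrow(mat) > 1L) apply(mat, 2L, sd) / sqrt(nrow(mat)) else
    rep(0, ncol(mat))
  avg <- new("HueHistogram", binWidth = bw, percent = 100 * m / sum(m),
             nPixels = sum(vapply(hists, function(h) h@nPixels, numeric(1))),
             imageId = as.character(imageId),
             displayRange = hists[[1]]@displayRange)
  list(mean = avg, lower = pmax(m - 1.96 * se, 0), upper = m + 1.96 * se)
}

#' Critical coefficient of the two-sample KS test
#'
#' Closed form \eqn{c(\alpha) = \sqrt{-\tfrac12 \ln(\alpha/2)}};
#' c(0.05) = 1.3581.
#'
#' @param alpha significance level in (0, 1).
#' @return scalar c(alpha).
#' @export
ksCriticalCoefficient <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    ccStop("colorCard_config", "'alpha' must lie in (0, 1)")
  sqrt(-0.5 * log(alpha / 2))
}

#' Two-sample KS comparison of hue histograms
#'
#' Computes the sup distance K between the two cumulative hue
#' distributions over all bins of the shared grid and rejects the
#' hypothesis of a common distribution iff
#' \eqn{K > c(\alpha)\sqrt{(n+m)/(nm)}}.
#'
#' Sample sizes: with \code{sampleSize = "pixels"} (the conservative
#' default) n and m are the pixel counts behind each histogram, which for
#' large masks makes the test sensitive to minute differences; with
#' \code{"bins"} n and m are the number of bins, appropriate when the
#' inputs are averaged histograms treated as binned samples.
#'
#' @param x,y [HueHistogram-class] objects on identical bin grids.
#' @param alpha significance level (default 0.05).
#' @param sampleSize \code{"pixels"} or \code{"bins"}.
#' @return a [KSResult-class].
#' @examples
#' ksCriticalCoefficient(0.05)   # 1.3581
#' @export
ksCompare <- function(x, y, alpha = 0.05,
                      sampleSize = c("pixels", "bins")) {
  stopifnot(is(x, "HueHistogram"), is(y, "HueHistogram"))
  sampleSize <- match.arg(sampleSize)
  if (x@binWidth != y@binWidth)
    ccStop("colorCard_grid", "histograms are on different bin grids")
  cA <- ksCriticalCoefficient(alpha)
  K <- max(abs(hueCumulative(x) - hueCumulative(y)))
  if (sampleSize == "pixels") {
    n <- x@nPixels; m <- y@nPixels
  } else {
    n <- length(x@percent); m <- length(y@percent)
  }
  n <- as.numeric(n); m <- as.numeric(m)
  thr <- cA * sqrt((n + m) / (n * m))
  new("KSResult", statistic = K, n = n, m = m, alpha = alpha,
      cAlpha = cA, threshold = thr, reject = K > thr,
      sampleSize = sampleSize)
}
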