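## Central S4 classes. Images and binary masks are deliberately plain
## base-R arrays/matrices (height x width [x 3], 0-255 / 0-1); the classes
## below hold the derived, invariant-carrying objects.

#' ChipColorMatrix: sampled colors of the reference card chips
#'
#' A k x 3 matrix of mean chip intensities (columns R, G, B, native 0-255
#' scale) in canonical card order (row-major across the card grid,
#' top-left to bottom-right), together with unique chip identifiers and
#' the id of the image the chips were sampled from.  At least 9 chips are
#' required (the polynomial design has 9 columns).
#'
#' @slot values numeric k x 3 matrix, columns R, G, B, values in [0, 255].
#' @slot chipIds character vector of k unique chip labels.
#' @slot imageId id of the source image (single string).
#'
#' @param values,chipIds,imageId see slots.
#' @param x a \code{ChipColorMatrix}.
#' @return \code{ChipColorMatrix()} returns a validated object;
#'   \code{chipValues()} the k x 3 matrix; \code{chipIds()} the labels;
#'   \code{imageId()} the image id.
#' @examples
#' cc <- ChipColorMatrix(canonicalChipColors(), imageId = "reference")
#' cc
#' head(chipValues(cc))
#' @name ChipColorMatrix-class
#' @aliases ChipColorMatrix
#' @export ChipColorMatrix
#' @exportClass ChipColorMatrix
setClass("ChipColorMatrix",
         slots = c(values = "matrix", chipIds = "character",
                   imageId = "character"))

setValidity("ChipColorMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || ncol(v) != 3L)
    return("'values' must be a numeric k x 3 matrix (columns R, G, B)")
  if (nrow(v) < 9L)
    return("at least 9 chips are required to fit the 9-term design")
  if (!all(is.finite(v)))
    return("chip values must all be finite")
  if (any(v < 0) || any(v > 255))
    return("chip values must lie in [0, 255]")
  if (length(object@chipIds) != nrow(v))
    return("one chip id per row of 'values' is required")
  if (anyDuplicated(object@chipIds))
    return("chip ids must be unique")
  if (length(object@imageId) != 1L)
    return("'imageId' must be a single string")
  TRUE
})

ChipColorMatrix <- function(values, chipIds = NULL, imageId = "") {
  values <- as.matrix(values)
  if (is.null(chipIds))
    chipIds <- sprintf("chip%02d", seq_len(nrow(values)))
  colnames(values) <- c("R", "G", "B")
  rownames(values) <- chipIds
  new("ChipColorMatrix", values = values, chipIds = as.character(chipIds),
      imageId = as.character(imageId))
}

#' @rdname ChipColorMatrix-class
setMethod("chipValues", "ChipColorMatrix", function(x) x@values)
#' @rdname ChipColorMatrix-class
setMethod("chipIds", "ChipColorMatrix", function(x) x@chipIds)
#' @rdname ChipColorMatrix-class
setMethod("imageId", "ChipColorMatrix", function(x) x@imageId)

setMethod("show", "ChipColorMatrix", function(object) {
  cat("ChipColorMatrix with", nrow(object@values), "chips",
      sprintf("(image '%s')\n", object@imageId))
  print(head(round(object@values, 2), 4L))
  if (nrow(object@values) > 4L)
    cat("... and", nrow(object@values) - 4L, "more chips\n")
})

#' ColorTransform: fitted cubic polynomial standardization
#'
#' Holds the three 9-term channel coefficient vectors mapping a source
#' image's color space onto a target's.  Column \code{c} of
#' \code{coefficients} regresses the target channel \code{c} on the
#' source polynomial terms \code{(r, g, b, r^2, g^2, b^2, r^3, g^3, b^3)}.
#'
#' @slot coefficients numeric 9 x 3 matrix, columns named R, G, B.
#' @slot sourceImageId,targetImageId image ids recorded at fit time.
#' @slot chipCount number of chips used in the fit.
#' @slot solver description of the numerical method used.
#'
#' @param x a \code{ColorTransform}.
#' @param channel one of \code{"R"}, \code{"G"}, \code{"B"}.
#' @return \code{channelCoefficients()} returns the named 9-vector for one
#'   channel.
#' @seealso [fitColorTransform()], [applyColorTransform()],
#'   [writeColorTransform()]
#' @name ColorTransform-class
#' @aliases ColorTransform
#' @exportClass ColorTransform
setClass("ColorTransform",
         slots = c(coefficients = "matrix", sourceImageId = "character",
                   targetImageId = "character", chipCount = "integer",
                   solver = "character"))

setValidity("ColorTransform", function(object) {
  co <- object@coefficients
  if (!is.numeric(co) || !identical(dim(co), c(9L, 3L)))
    return("'coefficients' must be a numeric 9 x 3 matrix")
  if (!all(is.finite(co)))
    return("coefficients must be finite")
  if (!identical(colnames(co), c("R", "G", "B")))
    return("coefficient columns must be labelled R, G, B in that order")
  TRUE
})

#' @rdname ColorTransform-class
setMethod("channelCoefficients", "ColorTransform", function(x, channel) {
  channel <- match.arg(channel, c("R", "G", "B"))
  x@coefficients[, channel]
})

setMethod("show", "ColorTransform", function(object) {
  cat(sprintf("ColorTransform '%s' -> '%s' (%d chips, %s)\n",
              object@sourceImageId, object@targetImageId,
              object@chipCount, object@solver))
  print(round(object@coefficients, 6))
})

#' ColorHomography: 9x9 homography between two color profiles
#'
#' The matrix H whose nine rows are the least-squares regressions of the
#' target chip channels and their squares and cubes (R, G, B, R^2, G^2,
#' B^2, R^3, G^3, B^3) on the extended source design.  When source and
#' target share a color profile H is the identity and its determinant 1;
#' the scalar deviance D = 1 - det(H) is therefore 0 for a perfect match
#' and grows in magnitude (signed, often large and negative for dimmed
#' images) as profiles diverge.
#'
#' @slot values numeric 9 x 9 matrix.
#' @slot sourceImageId,targetImageId image ids recorded at fit time.
#'
#' @param x,object a \code{ColorHomography}.
#' @param ... ignored.
#' @return \code{homographyMatrix()} returns the 9 x 9 matrix;
#'   \code{deviance()} the scalar D = 1 - det(H).
#' @seealso [fitColorHomography()]
#' @examples
#' cc <- ChipColorMatrix(canonicalChipColors(), imageId = "ref")
#' h <- fitColorHomography(cc, cc)
#' deviance(h)   # 0 for identical profiles
#' @name ColorHomography-class
#' @aliases ColorHomography
#' @exportClass ColorHomography
setClass("ColorHomography",
         slots = c(values = "matrix", sourceImageId = "character",
                   targetImageId = "character"))

setValidity("ColorHomography", function(object) {
  v <- object@values
  if (!is.numeric(v) || !identical(dim(v), c(9L, 9L)))
    return("'values' must be a numeric 9 x 9 matrix")
  if (!all(is.finite(v)))
    return("homography entries must be finite")
  TRUE
})

#' @rdname ColorHomography-class
setMethod("homographyMatrix", "ColorHomography", function(x) x@values)

#' @rdname ColorHomography-class
#' @export
setMethod("deviance", "ColorHomography", function(object, ...) {
  1 - det(object@values)
})

setMethod("show", "ColorHomography", function(object) {
  d <- det(object@values)
  cat(sprintf("ColorHomography '%s' -> '%s'\n  det(H) = %.6g, deviance D = %.6g\n",
              object@sourceImageId, object@targetImageId, d, 1 - d))
})

#' CardLayout: geometry of the reference card in the frame
#'
#' Chip regions are axis-aligned rectangles in pixel coordinates
#' (0-based, origin top-left, x rightward, y downward, half-open
#' \code{[x, x + w) x [y, y + h)}), listed in canonical card order:
#' row-major across the \code{gridRows} x \code{gridCols} grid.  At
#' sampling time each rectangle is shrunk on every side by
#' \code{insetFraction} of its extent to avoid chip borders and shadows.
#'
#' @slot gridRows,gridCols card grid shape (default 4 x 6).
#' @slot chipROIs integer-valued k x 4 matrix with columns x, y, w, h.
#' @slot chipIds character vector of k unique chip labels.
#' @slot insetFraction fraction in [0, 0.5) trimmed from each ROI side.
#'
#' @param chipROIs,gridRows,gridCols,chipIds,insetFraction see slots.
#' @param x a \code{CardLayout}.
#' @return \code{CardLayout()} a validated layout; \code{chipROIs()} the
#'   k x 4 ROI matrix.
#' @seealso [sampleChips()], [readCardLayout()]
#' @name CardLayout-class
#' @aliases CardLayout
#' @export CardLayout
#' @exportClass CardLayout
setClass("CardLayout",
         slots = c(gridRows = "integer", gridCols = "integer",
                   chipROIs = "matrix", chipIds = "character",
                   insetFraction = "numeric"))

setValidity("CardLayout", function(object) {
  r <- object@chipROIs
  if (!is.numeric(r) || ncol(r) != 4L)
    return("'chipROIs' must be a k x 4 matrix with columns x, y, w, h")
  if (nrow(r) != object@gridRows * object@gridCols)
    return("number of chip ROIs must equal gridRows * gridCols")
  if (any(r[, 3:4] < 1))
    return("chip ROI width and height must be at least 1 pixel")
  if (length(object@chipIds) != nrow(r) || anyDuplicated(object@chipIds))
    return("chip ids must be unique, one per ROI")
  f <- object@insetFraction
  if (length(f) != 1L || f < 0 || f >= 0.5)
    return("'insetFraction' must lie in [0, 0.5)")
  ## chips must stay disjoint after the inset shrink
  dx <- floor(r[, 3] * f + 0.5); dy <- floor(r[, 4] * f + 0.5)
  ins <- cbind(r[, 1] + dx, r[, 2] + dy, r[, 3] - 2 * dx, r[, 4] - 2 * dy)
  for (i in seq_len(nrow(ins))) for (j in seq_len(i - 1L)) {
    if (ins[i, 1] < ins[j, 1] + ins[j, 3] && ins[j, 1] < ins[i, 1] + ins[i, 3] &&
        ins[i, 2] < ins[j, 2] + ins[j, 4] && ins[j, 2] < ins[i, 2] + ins[i, 4])
      return(sprintf("chip ROIs %d and %d overlap after inset", j, i))
  }
  TRUE
})

CardLayout <- function(chipROIs, gridRows = 4L, gridCols = 6L,
                       chipIds = NULL, insetFraction = 0.25) {
  chipROIs <- as.matrix(chipROIs)
  colnames(chipROIs) <- c("x", "y", "w", "h")
  if (is.null(chipIds))
    chipIds <- sprintf("chip%02d", seq_len(nrow(chipROIs)))
  new("CardLayout", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), chipROIs = chipROIs,
      chipIds = as.character(chipIds),
      insetFraction = as.numeric(insetFraction))
}

#' @rdname CardLayout-class
setMethod("chipROIs", "CardLayout", function(x) x@chipROIs)
#' @rdname CardLayout-class
setMethod("chipIds", "CardLayout", function(x) x@chipIds)

setMethod("show", "CardLayout", function(object) {
  cat(sprintf("CardLayout: %d x %d grid, %d chips, inset fraction %.2f\n",
              object@gridRows, object@gridCols, nrow(object@chipROIs),
              object@insetFraction))
})

#' ThresholdConfig: fixed-threshold segmentation bounds
#'
#' A pixel is classified as plant iff every configured bound is
#' satisfied.  Bounds are named length-2 vectors \code{c(min, max)}
#' (inclusive) for any of the RGB channels \code{r}, \code{g}, \code{b}
#' (0-255 scale) and the HSV channels \code{h} (degrees, 0-360),
#' \code{s}, \code{v} (0-1).  At least one channel must be constrained.
#' No morphological cleanup is performed unless
#' \code{keepLargestComponent} is set, so threshold mismatch shows up as
#' salt-and-pepper noise rather than being silently erased.
#'
#' @slot bounds named list of length-2 numeric vectors.
#' @slot keepLargestComponent retain only the largest 8-connected
#'   foreground component.
#' @slot configId label recorded in mask provenance.
#'
#' @param bounds,keepLargestComponent,configId see slots.
#' @return a validated \code{ThresholdConfig}.
#' @examples
#' cfg <- ThresholdConfig(list(g = c(120, 185), b = c(15, 65)))
#' @name ThresholdConfig-class
#' @aliases ThresholdConfig
#' @export ThresholdConfig
#' @exportClass ThresholdConfig
setClass("ThresholdConfig",
         slots = c(bounds = "list", keepLargestComponent = "logical",
                   configId = "character"))

setValidity("ThresholdConfig", function(object) {
  b <- object@bounds
  if (length(b) == 0L)
    return("at least one channel bound must be configured")
  ok <- c("r", "g", "b", "h", "s", "v")
  if (is.null(names(b)) || !all(names(b) %in% ok))
    return(sprintf("bound names must be among: %s", paste(ok, collapse = ", ")))
  for (nm in names(b)) {
    bb <- b[[nm]]
    if (length(bb) != 2L || !all(is.finite(bb)))
      return(sprintf("bound '%s' must be a finite c(min, max)", nm))
    if (bb[1] > bb[2])
      return(sprintf("bound '%s' has min > max", nm))
  }
  TRUE
})

ThresholdConfig <- function(bounds, keepLargestComponent = FALSE,
                            configId = "threshold") {
  new("ThresholdConfig", bounds = lapply(bounds, as.numeric),
      keepLargestComponent = isTRUE(keepLargestComponent),
      configId = as.character(configId))
}

setMethod("show", "ThresholdConfig", function(object) {
  cat(sprintf("ThresholdConfig '%s':\n", object@configId))
  for (nm in names(object@bounds))
    cat(sprintf("  %s in [%g, %g]\n", nm, object@bounds[[nm]][1],
                object@bounds[[nm]][2]))
  if (object@keepLargestComponent)
    cat("  keeping largest connected component only\n")
})

#' HueHistogram: per-degree hue distribution of masked pixels
#'
#' Percent of masked pixels per hue bin over the full 0-360 degree
#' support (half-open bins \code{[edge, edge + width)}).  The display
#' range (default 0-140 degrees, the green region relevant to plants) is
#' presentation metadata only: percentages always sum to 100 over the
#' full support and comparisons use all bins.
#'
#' @slot binWidth bin width in degrees (must divide 360).
#' @slot percent numeric vector of per-bin percentages (length 360/binWidth).
#' @slot nPixels number of mask pixels contributing.
#' @slot imageId provenance label.
#' @slot displayRange length-2 numeric, presentation-only.
#'
#' @param x a \code{HueHistogram}.
#' @seealso [hueHistogram()], [hueCumulative()], [ksCompare()]
#' @name HueHistogram-class
#' @aliases HueHistogram
#' @exportClass HueHistogram
setClass("HueHistogram",
         slots = c(binWidth = "numeric", percent = "numeric",
                   nPixels = "numeric", imageId = "character",
                   displayRange = "numeric"))

setValidity("HueHistogram", function(object) {
  bw <- object@binWidth
  if (length(bw) != 1L || bw <= 0 || (360 %% bw) != 0)
    return("'binWidth' must be a positive divisor of 360")
  p <- object@percent
  if (length(p) != 360 / bw)
    return("'percent' must have one entry per bin over the 0-360 support")
  if (any(p < 0))
    return("percentages must be nonnegative")
  if (abs(sum(p) - 100) > 1e-6)
    return("percentages must sum to 100 over the full support")
  if (object@nPixels < 1)
    return("'nPixels' must be at least 1")
  TRUE
})

#' @rdname HueHistogram-class
#' @export
hueBreaks <- function(x) seq(0, 360 - x@binWidth, by = x@binWidth)

setMethod("show", "HueHistogram", function(object) {
  pk <- which.max(object@percent)
  cat(sprintf(paste0("HueHistogram '%s': %d bins of %g deg, %g pixels, ",
                     "peak %.1f%% at %g deg\n"),
              object@imageId, length(object@percent), object@binWidth,
              object@nPixels, object@percent[pk],
              (pk - 1) * object@binWidth))
})

#' KSResult: two-sample Kolmogorov-Smirnov comparison of hue histograms
#'
#' Holds the sup-distance statistic K between the two cumulative hue
#' distributions, the critical coefficient
#' \eqn{c(\alpha) = \sqrt{-\tfrac12 \ln(\alpha/2)}}, the rejection
#' threshold \eqn{c(\alpha)\sqrt{(n+m)/(nm)}} and the decision
#' (reject iff K exceeds the threshold).
#'
#' @slot statistic sup |F_x - F_y| over hue bins.
#' @slot n,m sample sizes of the two histograms.
#' @slot alpha significance level.
#' @slot cAlpha critical coefficient c(alpha).
#' @slot threshold rejection threshold.
#' @slot reject logical decision.
#' @slot sampleSize \code{"pixels"} or \code{"bins"} (how n, m were taken).
#'
#' @seealso [ksCompare()]
#' @name KSResult-class
#' @aliases KSResult
#' @exportClass KSResult
setClass("KSResult",
         slots = c(statistic = "numeric", n = "numeric", m = "numeric",
                   alpha = "numeric", cAlpha = "numeric",
                   threshold = "numeric", reject = "logical",
                   sampleSize = "character"))

setValidity("KSResult", function(object) {
  if (object@statistic < 0 || object@statistic > 1)
    return("K must lie in [0, 1]")
  if (!identical(object@reject, object@statistic > object@threshold))
    return("'reject' must equal K > threshold")
  TRUE
})

setMethod("show", "KSResult", function(object) {
  cat(sprintf(paste0("Two-sample KS: K = %.4f, threshold = %.4f ",
                     "(alpha = %g, n = %g, m = %g, by %s) -> %s\n"),
              object@statistic, object@threshold, object@alpha,
              object@n, object@m, object@sampleSize,
              if (object@reject) "reject" else "fail to reject"))
})
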