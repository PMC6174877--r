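## Fixed-threshold segmentation and mask set arithmetic.

#' Fixed-threshold plant segmentation
#'
#' Classifies a pixel as plant (1) iff every configured channel bound is
#' satisfied.  RGB bounds act on the 0-255 channels; HSV bounds on the
#' standard conversion (hue in degrees 0-360, saturation and value in
#' 0-1).  Deliberately no morphological cleanup is applied -- threshold
#' mismatch on unstandardized images is supposed to be visible as
#' salt-and-pepper noise -- unless the config's
#' \code{keepLargestComponent} is set, in which case only the largest
#' 8-connected foreground component is retained.
#'
#' @param image height x width x 3 array on the 0-255 scale.
#' @param cfg a [ThresholdConfig-class].
#' @param imageId provenance label attached to the mask.
#' @return a binary 0/1 integer matrix with attributes \code{imageId} and
#'   \code{configId}.
#' @examples
#' scene <- renderScene(sceneSpec())
#' cfg <- ThresholdConfig(list(r = c(25, 115), g = c(120, 185), b = c(15, 65)))
#' mask <- thresholdSegment(scene$image, cfg)
#' sum(mask) == sum(scene$mask)
#' @export
thresholdSegment <- function(image, cfg, imageId = "") {
  stopifnotImage(image)
  if (!is(cfg, "ThresholdConfig"))
    ccStop("colorCard_config", "expected a ThresholdConfig")
  d <- dim(image)
  n <- d[1] * d[2]
  px <- matrix(image, nrow = n, ncol = 3L)
  keep <- rep(TRUE, n)
  b <- cfg@bounds
  rgbIdx <- c(r = 1L, g = 2L, b = 3L)
  for (nm in intersect(names(b), names(rgbIdx))) {
    v <- px[, rgbIdx[[nm]]]
    keep <- keep & v >= b[[nm]][1] & v <= b[[nm]][2]
  }
  hsvNames <- intersect(names(b), c("h", "s", "v"))
  if (length(hsvNames)) {
    hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 255)
    chan <- list(h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ])
    for (nm in hsvNames)
      keep <- keep & chan[[nm]] >= b[[nm]][1] & chan[[nm]] <= b[[nm]][2]
  }
  mask <- matrix(as.integer(keep), d[1], d[2])
  if (cfg@keepLargestComponent && any(mask == 1L)) {
    lab <- labels8(mask)
    counts <- tabulate(lab[lab > 0L])
    mask <- matrix(as.integer(lab == which.max(counts)), d[1], d[2])
  }
  attr(mask, "imageId") <- imageId
  attr(mask, "configId") <- cfg@configId
  mask
}

#' Pixelwise overlap of two masks
#'
#' Exact set arithmetic between two equally sized binary masks: counts of
#' pixels only in the first, only in the second, and in both.  The three
#' counts sum to the size of the union.
#'
#' @param a,b binary 0/1 matrices of identical dimensions.
#' @return named list \code{onlyA}, \code{onlyB}, \code{both}.
#' @export
compareMasks <- function(a, b) {
  stopifnotMask(a); stopifnotMask(b)
  if (!identical(dim(a), dim(b)))
    ccStop("colorCard_geometry",
           "mask dimensions differ: %s vs %s",
           paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  list(onlyA = sum(a == 1L & b == 0L),
       onlyB = sum(a == 0L & b == 1L),
       both = sum(a == 1L & b == 1L))
}
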