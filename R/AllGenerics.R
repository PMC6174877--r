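#' @rdname ChipColorMatrix-class
#' @export
setGeneric("chipValues", function(x) standardGeneric("chipValues"))

#' @rdname ChipColorMatrix-class
#' @export
setGeneric("chipIds", function(x) standardGeneric("chipIds"))

#' @rdname ChipColorMatrix-class
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname ColorTransform-class
#' @export
setGeneric("channelCoefficients",
           function(x, channel) standardGeneric("channelCoefficients"))

#' @rdname ColorHomography-class
#' @export
setGeneric("homographyMatrix", function(x) standardGeneric("homographyMatrix"))

#' @rdname CardLayout-class
#' @export
setGeneric("chipROIs", function(x) standardGeneric("chipROIs"))

#' Apply a fitted color transform
#'
#' Applies the fitted cubic polynomial standardization to an RGB pixel
#' (length-3 vector) or a whole image (height x width x 3 array), both on
#' the 0-255 scale.  Each output channel is the dot product of the
#' 9-vector of polynomial terms \code{(r, g, b, r^2, g^2, b^2, r^3, g^3,
#' b^3)} of the input pixel with that channel's coefficient vector.
#'
#' Clipping to \code{[0, 255]} is applied after the polynomial, never
#' during fitting.  In \code{bitDepth = "8bit"} mode values are clipped
#' and then rounded half-up to integers; \code{"float"} mode returns the
#' unclipped polynomial values so downstream analysis can see out-of-gamut
#' excursions.
#'
#' @param transform a [ColorTransform-class] object.
#' @param x a length-3 RGB vector or a height x width x 3 array.
#' @param bitDepth \code{"8bit"} (clip + round half-up) or \code{"float"}.
#' @return An object shaped like \code{x}.
#' @examples
#' chips <- ChipColorMatrix(canonicalChipColors(), imageId = "ref")
#' tr <- fitColorTransform(chips, chips)
#' applyColorTransform(tr, c(100, 200, 40))
#' @export
setGeneric("applyColorTransform",
           function(transform, x, bitDepth = c("8bit", "float"))
             standardGeneric("applyColorTransform"))
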