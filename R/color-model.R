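## Polynomial color standardization: design extension, pseudoinverse,
## per-channel transform fitting, pixel/image application, the 9x9 color
## homography and its deviance score.

#' Extend chip colors to the cubic polynomial design
#'
#' Builds the k x 9 design matrix whose columns are the chip channels and
#' their elementwise squares and cubes:
#' \code{(r, g, b, r^2, g^2, b^2, r^3, g^3, b^3)}.  The design carries no
#' intercept: the transform maps black to black by construction.
#'
#' @param chips a [ChipColorMatrix-class], or a numeric n x 3 matrix of
#'   RGB values on the 0-255 scale.
#' @return numeric k x 9 matrix with columns
#'   \code{r, g, b, r2, g2, b2, r3, g3, b3}.
#' @examples
#' extendDesign(rbind(c(2, 3, 4)))
#' @export
extendDesign <- function(chips) {
  v <- if (is(chips, "ChipColorMatrix")) chipValues(chips) else as.matrix(chips)
  if (!is.numeric(v) || ncol(v) != 3L)
    ccStop("colorCard_invalid_input", "expected an n x 3 RGB matrix")
  if (!all(is.finite(v)))
    ccStop("colorCard_invalid_input", "chip values must be finite")
  out <- cbind(v, v^2, v^3)
  colnames(out) <- c("r", "g", "b", "r2", "g2", "b2", "r3", "g3", "b3")
  out
}

#' Moore-Penrose inverse of the extended design
#'
#' Computes \eqn{M = (S^*S)^{-1}S^*} semantics for the k x 9 extended
#' design S via singular value decomposition (numerically preferable to
#' forming the normal equations explicitly: cubed 8-bit intensities make
#' \eqn{S^*S} severely ill-conditioned).  The design must have full
#' column rank 9; numerical rank is judged against the tolerance
#' \code{rankTol} times the largest singular value.  Rank deficiency --
#' for example after removing too many distinct chips from the card --
#' raises a singular-design error naming the deficient rank rather than
#' returning an unusable transform.
#'
#' @param design k x 9 matrix from [extendDesign()].
#' @param rankTol relative singular value tolerance (default 1e-10).
#' @return the 9 x k pseudoinverse M, so that \code{M \%*\% design} is the
#'   9 x 9 identity (to numerical precision) for full-rank designs.
#' @export
designPseudoinverse <- function(design, rankTol = 1e-10) {
  design <- as.matrix(design)
  if (ncol(design) != 9L)
    ccStop("colorCard_invalid_input", "design must have 9 columns")
  if (!all(is.finite(design)))
    ccStop("colorCard_invalid_input", "design contains non-finite values")
  sv <- svd(design)
  keep <- sv$d > rankTol * sv$d[1]
  r <- sum(keep)
  if (r < 9L)
    ccStop("colorCard_singular_design",
           paste("extended chip design is rank deficient (numerical rank",
                 "%d < 9); the transform is incalculable -- provide more",
                 "distinct chip colors"), r)
  sv$v %*% (t(sv$u) / sv$d)
}

checkCorrespondence <- function(source, target) {
  if (nrow(chipValues(source)) != nrow(chipValues(target)) ||
      !identical(chipIds(source), chipIds(target)))
    ccStop("colorCard_correspondence",
           paste("source and target chips must be homologous: identical",
                 "chip ids in identical order"))
}

#' Fit the color standardization transform
#'
#' Regresses each target chip channel on the 9-column cubic design of the
#' source chips, yielding the three standardization vectors that map the
#' source color space onto the target's.  Fitting is done in double
#' precision on the native 0-255 scale through the SVD pseudoinverse of
#' the design.
#'
#' @param source,target [ChipColorMatrix-class] objects with identical
#'   chip ids in identical order (homologous sampling points).
#' @param rankTol passed to [designPseudoinverse()].
#' @return a [ColorTransform-class].
#' @examples
#' cc <- ChipColorMatrix(canonicalChipColors(), imageId = "ref")
#' tr <- fitColorTransform(cc, cc)    # identity transform
#' channelCoefficients(tr, "R")
#' @export
fitColorTransform <- function(source, target, rankTol = 1e-10) {
  checkCorrespondence(source, target)
  M <- designPseudoinverse(extendDesign(source), rankTol)
  co <- M %*% chipValues(target)
  dimnames(co) <- list(c("r", "g", "b", "r2", "g2", "b2", "r3", "g3", "b3"),
                       c("R", "G", "B"))
  new("ColorTransform", coefficients = co,
      sourceImageId = imageId(source), targetImageId = imageId(target),
      chipCount = nrow(chipValues(source)), solver = "svd-pseudoinverse")
}

applyCoefficients <- function(co, rgbMatrix) {
  ext <- cbind(rgbMatrix, rgbMatrix^2, rgbMatrix^3)
  ext %*% co
}

#' @rdname applyColorTransform
setMethod("applyColorTransform", signature(transform = "ColorTransform"),
          function(transform, x, bitDepth = c("8bit", "float")) {
  bitDepth <- match.arg(bitDepth)
  co <- transform@coefficients
  if (is.null(dim(x))) {
    if (length(x) != 3L || !all(is.finite(x)))
      ccStop("colorCard_invalid_input", "pixel must be a finite RGB 3-vector")
    out <- drop(applyCoefficients(co, rbind(x)))
    names(out) <- c("R", "G", "B")
    if (bitDepth == "8bit") out <- roundHalfUp(clip255(out))
    return(out)
  }
  stopifnotImage(x)
  d <- dim(x)
  px <- matrix(x, nrow = d[1] * d[2], ncol = 3L)
  out <- applyCoefficients(co, px)
  if (bitDepth == "8bit") out <- roundHalfUp(clip255(out))
  array(out, dim = d, dimnames = dimnames(x))
})

#' Fit the 9x9 color homography between two chip sets
#'
#' Extends the target chips to their quadratic and cubic terms exactly as
#' the source design, and regresses all nine extended target columns
#' (R, G, B, R^2, G^2, B^2, R^3, G^3, B^3, in that order) on the extended
#' source design.  The nine standardization vectors are stacked as the
#' rows of H.  When the two profiles are identical H is the 9x9 identity.
#'
#' @inheritParams fitColorTransform
#' @return a [ColorHomography-class]; see [deviance()] for the scalar
#'   deviance D = 1 - det(H).
#' @export
fitColorHomography <- function(source, target, rankTol = 1e-10) {
  checkCorrespondence(source, target)
  M <- designPseudoinverse(extendDesign(source), rankTol)
  H <- t(M %*% extendDesign(target))   # row i = M %*% (extended target col i)
  dimnames(H) <- list(c("R", "G", "B", "R2", "G2", "B2", "R3", "G3", "B3"),
                      colnames(extendDesign(target)))
  new("ColorHomography", values = H,
      sourceImageId = imageId(source), targetImageId = imageId(target))
}

#' Deviance of a homography matrix
#'
#' D = 1 - det(H): zero when the source already matches the target
#' profile, signed otherwise (dimmed sources typically give large
#' negative values, since the correction inflates intensities and
#' det(H) > 1).  \code{deviance()} on a [ColorHomography-class] computes
#' the same quantity; this function accepts a bare 9 x 9 matrix.
#'
#' @param h a [ColorHomography-class] or a numeric 9 x 9 matrix.
#' @return scalar deviance D.
#' @examples
#' devianceScore(diag(9))       # 0
#' devianceScore(2 * diag(9))   # 1 - 2^9 = -511
#' @export
devianceScore <- function(h) {
  if (is(h, "ColorHomography")) return(deviance(h))
  h <- as.matrix(h)
  if (!identical(dim(h), c(9L, 9L)) || !all(is.finite(h)))
    ccStop("colorCard_invalid_input", "expected a finite 9 x 9 matrix")
  1 - det(h)
}
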