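## Shape descriptor panel for binary plant masks.
##
## Conventions (pixel units throughout, 0-based coordinates, origin
## top-left, x rightward, y downward):
##  * components and contours are 8-connected;
##  * perimeter is the arc length of the outer contour of every
##    component (unit steps between orthogonal neighbors, sqrt(2) for
##    diagonal), summed over components, so salt-and-pepper noise
##    contributes like it does in the underlying imagery;
##  * the convex hull is taken over pixel corners, so hull area always
##    bounds pixel-count area from above and solidity lies in [0, 1];
##  * the ellipse is the one sharing the mask's second-order central
##    moments: axis lengths 4*sqrt(eigenvalues of the coordinate
##    covariance), orientation of the major axis in degrees.

maskCoords <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

contourLength <- function(points) {
  if (nrow(points) < 2L) return(0)
  d <- rbind(diff(points), points[1L, , drop = FALSE] -
                           points[nrow(points), , drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

maskPerimeter <- function(mask) {
  lab <- labels8(mask)
  sum(vapply(EBImage::ocontour(lab), contourLength, numeric(1)))
}

shoelace <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

#' Box-counting fractal dimension of a mask
#'
#' The mask is cropped to its bounding box and overlaid with dyadic grids
#' of box size 1, 2, 4, ... up to the padded (power-of-two) extent; the
#' dimension is the least-squares slope of log(occupied box count)
#' against log(1/box size).  A space-filling region approaches 2, a thin
#' curve 1, an isolated pixel 0.
#'
#' @param mask binary 0/1 matrix with at least one foreground pixel.
#' @return scalar box-counting dimension estimate.
#' @examples
#' fractalDimension(matrix(1L, 64, 64))   # ~2
#' @export
fractalDimension <- function(mask) {
  stopifnotMask(mask)
  xy <- maskCoords(mask)
  if (nrow(xy) == 0L)
    ccStop("colorCard_empty_object", "mask has no foreground pixels")
  xy[, 1] <- xy[, 1] - min(xy[, 1])
  xy[, 2] <- xy[, 2] - min(xy[, 2])
  extent <- max(max(xy[, 1]), max(xy[, 2])) + 1
  ## dyadic box sizes, capped at a quarter of the extent: larger boxes sit
  ## in the saturation regime (count -> 1) and bias the slope downward
  sizes <- 2^(0:30)
  sizes <- sizes[sizes <= extent / 4]
  if (length(sizes) < 2L) sizes <- c(1, 2)
  counts <- vapply(sizes, function(s) {
    length(unique(xy[, 1] %/% s + (max(xy[, 1]) %/% s + 1) *
                    (xy[, 2] %/% s)))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / sizes))
  unname(coef(fit)[2])
}

#' Measure the shape descriptor panel of a mask
#'
#' Computes the 19 morphometrics used to evaluate standardization: area,
#' convex hull area and vertex count, bounding-box width and height,
#' perimeter, circularity (4*pi*area/perimeter^2), solidity
#' (area/hull area), roundness (4*area/(pi*major_axis^2)), eccentricity,
#' aspect ratio (bounding-box width/height), box-counting fractal
#' dimension, center of mass, and the moment-matched ellipse (center,
#' major/minor axis, orientation angle in degrees).  All measures are
#' deterministic functions of the mask; units are pixels.
#'
#' @param mask binary 0/1 matrix with at least one foreground pixel.
#' @return a one-row data.frame with the 19 descriptors in a stable
#'   column order.
#' @examples
#' m <- matrix(0L, 20, 20); m[6:15, 4:13] <- 1L
#' measureShapes(m)[, c("area", "perimeter", "solidity")]
#' @export
measureShapes <- function(mask) {
  stopifnotMask(mask)
  xy <- maskCoords(mask)
  n <- nrow(xy)
  if (n == 0L)
    ccStop("colorCard_empty_object", "mask has no foreground pixels")

  area <- n
  width <- diff(range(xy[, 1])) + 1
  height <- diff(range(xy[, 2])) + 1

  ## hull over pixel corners: pixel (x, y) covers [x, x+1) x [y, y+1)
  corners <- unique(rbind(xy,
                          cbind(xy[, 1] + 1, xy[, 2]),
                          cbind(xy[, 1], xy[, 2] + 1),
                          xy + 1))
  hullIdx <- chull(corners)
  hull <- corners[hullIdx, , drop = FALSE]
  hullArea <- shoelace(hull)

  perim <- maskPerimeter(mask)

  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  mu20 <- mean((xy[, 1] - cx)^2)
  mu02 <- mean((xy[, 2] - cy)^2)
  mu11 <- mean((xy[, 1] - cx) * (xy[, 2] - cy))
  tr <- mu20 + mu02
  det2 <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det2, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  angle <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi

  data.frame(
    area = area,
    convex_hull_area = hullArea,
    convex_hull_vertices = length(hullIdx),
    width = width,
    height = height,
    perimeter = perim,
    circularity = if (perim > 0) 4 * pi * area / perim^2 else NA_real_,
    solidity = if (hullArea > 0) area / hullArea else NA_real_,
    roundness = if (major > 0) 4 * area / (pi * major^2) else NA_real_,
    eccentricity = ecc,
    aspect_ratio = width / height,
    fractal_dimension = fractalDimension(mask),
    center_of_mass_x = cx,
    center_of_mass_y = cy,
    ellipse_center_x = cx,
    ellipse_center_y = cy,
    ellipse_major_axis = major,
    ellipse_minor_axis = minor,
    ellipse_angle = angle
  )
}
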