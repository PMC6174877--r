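## Sampling the reference card: mean chip colors over inset ROIs, chip
## quality flags, and YAML layout round-trip.

insetROI <- function(roi, f) {
  dx <- roundHalfUp(roi[3] * f)
  dy <- roundHalfUp(roi[4] * f)
  c(roi[1] + dx, roi[2] + dy, roi[3] - 2 * dx, roi[4] - 2 * dy)
}

#' Sample the reference chips from an image
#'
#' Per chip and channel, the arithmetic mean of pixel intensities over
#' the chip's ROI shrunk on all sides by the layout's inset fraction
#' (default 0.25, avoiding chip borders and shadows).  Output rows are in
#' canonical card order (the layout's ROI order), carrying the layout's
#' chip ids, so source/target correspondence is enforced by ids rather
#' than by list position.
#'
#' @param image height x width x 3 array, 0-255 scale.
#' @param layout a [CardLayout-class].
#' @param imageId provenance label stored in the result.
#' @return a [ChipColorMatrix-class].
#' @examples
#' scene <- renderScene(sceneSpec())
#' chips <- sampleChips(scene$image, scene$layout, imageId = "reference")
#' @export
sampleChips <- function(image, layout, imageId = "") {
  stopifnotImage(image)
  stopifnot(is(layout, "CardLayout"))
  rois <- chipROIs(layout)
  h <- dim(image)[1]; w <- dim(image)[2]
  vals <- matrix(NA_real_, nrow(rois), 3L)
  for (i in seq_len(nrow(rois))) {
    r <- insetROI(rois[i, ], layout@insetFraction)
    if (r[3] < 1 || r[4] < 1)
      ccStop("colorCard_geometry", "chip '%s': ROI empty after inset",
             chipIds(layout)[i])
    if (r[1] < 0 || r[2] < 0 || r[1] + r[3] > w || r[2] + r[4] > h)
      ccStop("colorCard_geometry",
             "chip '%s': ROI [%d, %d, %d, %d] outside image bounds %dx%d",
             chipIds(layout)[i], r[1], r[2], r[3], r[4], w, h)
    ## 0-based half-open [x, x+w) x [y, y+h)  ->  1-based closed R indices
    xs <- (r[1] + 1):(r[1] + r[3])
    ys <- (r[2] + 1):(r[2] + r[4])
    vals[i, ] <- apply(image[ys, xs, , drop = FALSE], 3L, mean)
  }
  ChipColorMatrix(vals, chipIds = chipIds(layout), imageId = imageId)
}

#' Flag low-quality chip measurements
#'
#' Chips whose mean intensity reaches saturation (any channel mean >=
#' 254.5) are flagged; saturated chips remain fit-eligible but indicate
#' the polynomial is extrapolating at the top of the range.  The overall
#' report passes unless a chip was out of bounds (which [sampleChips()]
#' already raises as an error, so reports from sampled chips pass).
#'
#' @param chips a [ChipColorMatrix-class].
#' @return a list with elements \code{flags} (data.frame with columns
#'   \code{chipId}, \code{saturated}, \code{outOfBounds}) and \code{pass}.
#' @export
validateChips <- function(chips) {
  if (!is(chips, "ChipColorMatrix"))
    ccStop("colorCard_invalid_input", "expected a ChipColorMatrix")
  v <- chipValues(chips)
  flags <- data.frame(
    chipId = chipIds(chips),
    saturated = apply(v, 1L, function(x) any(x >= 254.5)),
    outOfBounds = FALSE,
    row.names = NULL, stringsAsFactors = FALSE)
  list(flags = flags, pass = !any(flags$outOfBounds))
}

#' Read/write a card layout as YAML
#'
#' The document stores the grid shape, the ordered chip ROI list
#' (0-based x, y, w, h rectangles) and the inset fraction.  Validation
#' errors name the offending field.
#'
#' @param path YAML file path.
#' @param layout a [CardLayout-class].
#' @return \code{readCardLayout()} a validated [CardLayout-class];
#'   \code{writeCardLayout()} the path, invisibly.
#' @export
readCardLayout <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("grid_rows", "grid_cols", "chip_rois"))
    if (is.null(doc[[field]]))
      ccStop("colorCard_config", "card layout %s: missing field '%s'",
             path, field)
  rois <- doc$chip_rois
  bad <- which(vapply(rois, function(r) length(unlist(r)) != 4L, logical(1)))
  if (length(bad))
    ccStop("colorCard_config",
           "card layout %s: chip_rois entry %d is not an (x, y, w, h) rectangle",
           path, bad[1])
  roiMat <- do.call(rbind, lapply(rois, function(r)
    as.numeric(unlist(r)[c("x", "y", "w", "h")])))
  if (any(is.na(roiMat)))
    ccStop("colorCard_config",
           "card layout %s: chip_rois entries need named x, y, w, h", path)
  CardLayout(roiMat,
             gridRows = doc$grid_rows, gridCols = doc$grid_cols,
             chipIds = if (is.null(doc$chip_ids)) NULL
                       else as.character(doc$chip_ids),
             insetFraction = if (is.null(doc$inset_fraction)) 0.25
                             else doc$inset_fraction)
}

#' @rdname readCardLayout
#' @export
writeCardLayout <- function(layout, path) {
  stopifnot(is(layout, "CardLayout"))
  rois <- chipROIs(layout)
  doc <- list(
    grid_rows = layout@gridRows,
    grid_cols = layout@gridCols,
    inset_fraction = layout@insetFraction,
    chip_ids = as.list(chipIds(layout)),
    chip_rois = lapply(seq_len(nrow(rois)), function(i)
      list(x = rois[i, 1], y = rois[i, 2], w = rois[i, 3], h = rois[i, 4])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read/write a threshold configuration as YAML
#'
#' @param cfg a [ThresholdConfig-class].
#' @param path YAML file path.
#' @return \code{readThresholdConfig()} a validated
#'   [ThresholdConfig-class]; \code{writeThresholdConfig()} the path,
#'   invisibly.
#' @export
readThresholdConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$bounds))
    ccStop("colorCard_config", "threshold config %s: missing 'bounds'", path)
  ThresholdConfig(lapply(doc$bounds, as.numeric),
                  keepLargestComponent = isTRUE(doc$keep_largest_component),
                  configId = if (is.null(doc$config_id)) "threshold"
                             else doc$config_id)
}

#' @rdname readThresholdConfig
#' @export
writeThresholdConfig <- function(cfg, path) {
  stopifnot(is(cfg, "ThresholdConfig"))
  yaml::write_yaml(list(config_id = cfg@configId,
                        keep_largest_component = cfg@keepLargestComponent,
                        bounds = cfg@bounds), path)
  invisible(path)
}
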