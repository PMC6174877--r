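## Batch orchestration: standardize a directory of images against a
## declared reference, score deviance, segment, measure shapes and hue
## pre/post, and emit diffable CSV tables.

fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

writeTable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmtNum(df[[j]])
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the standardization pipeline over an image directory
#'
#' For every image (lexicographic filename order): sample the card chips,
#' fit the transform and homography against the reference, record the
#' deviance, standardize the image, re-sample chips from the
#' standardized image and re-score its deviance, segment before and
#' after standardization, measure the shape panel on both masks, and
#' build hue histograms of both masked plants.  Per-image failures are
#' recorded in an errors table and the batch continues; an unreadable
#' reference is fatal.
#'
#' Outputs in \code{outputDir}: \code{deviance.csv} (pre/post deviance
#' and determinant per image), \code{shapes.csv} (one row per image and
#' phase), \code{hue.csv} (tidy image/phase/bin/percent),
#' \code{errors.csv}, and optionally standardized images and masks.
#' Numeric CSV cells are formatted to 6 significant digits so reruns are
#' byte-identical.
#'
#' @param inputDir directory of input images.
#' @param reference image id (file stem) of the declared reference.
#' @param layout a [CardLayout-class] or path to its YAML.
#' @param threshold a [ThresholdConfig-class] or path to its YAML, or
#'   NULL to skip segmentation, shapes and hue.
#' @param outputDir destination directory (created if needed).
#' @param pattern filename regexp for input images.
#' @param writeStandardized,writeMasks write per-image rasters.
#' @param bitDepth passed to [applyColorTransform()] for standardized
#'   output rasters.
#' @param hueBinWidth degrees per hue bin.
#' @return invisibly, a list of the result data.frames
#'   (\code{deviance}, \code{shapes}, \code{hue}, \code{errors}).
#' @export
runPipeline <- function(inputDir, reference, layout, threshold = NULL,
                        outputDir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        writeStandardized = FALSE, writeMasks = FALSE,
                        bitDepth = "8bit", hueBinWidth = 1) {
  if (is.character(layout)) layout <- readCardLayout(layout)
  if (is.character(threshold)) threshold <- readThresholdConfig(threshold)
  files <- sort(list.files(inputDir, pattern = pattern, ignore.case = TRUE))
  ids <- tools::file_path_sans_ext(files)
  if (anyDuplicated(ids))
    ccStop("colorCard_config", "duplicate image ids after stripping extensions")
  if (!reference %in% ids)
    ccStop("colorCard_config", "reference '%s' not found in %s",
           reference, inputDir)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)

  refImage <- readImageRGB(file.path(inputDir, files[ids == reference]))
  refChips <- sampleChips(refImage, layout, imageId = reference)

  devRows <- list(); shapeRows <- list(); hueRows <- list(); errRows <- list()
  for (i in seq_along(files)) {
    id <- ids[i]
    res <- tryCatch({
      img <- readImageRGB(file.path(inputDir, files[i]))
      chips <- sampleChips(img, layout, imageId = id)
      h <- fitColorHomography(chips, refChips)
      tr <- fitColorTransform(chips, refChips)
      std <- applyColorTransform(tr, img, bitDepth = "8bit")
      stdChips <- sampleChips(std, layout, imageId = paste0(id, ".std"))
      hPost <- fitColorHomography(stdChips, refChips)
      dPre <- deviance(h); dPost <- deviance(hPost)
      devRows[[id]] <- data.frame(
        image_id = id,
        deviance_pre = dPre, det_pre = 1 - dPre,
        deviance_post = dPost, det_post = 1 - dPost)
      if (writeStandardized)
        writeImageRGB(if (bitDepth == "8bit") std
                      else applyColorTransform(tr, img, bitDepth = "float"),
                      file.path(outputDir, paste0(id, "_std.png")))
      if (!is.null(threshold)) {
        for (phase in c("pre", "post")) {
          phImg <- if (phase == "pre") img else std
          mask <- thresholdSegment(phImg, threshold, imageId = id)
          if (writeMasks)
            writeMask(mask, file.path(outputDir,
                                      sprintf("%s_%s_mask.png", id, phase)))
          if (sum(mask) > 0L) {
            sh <- measureShapes(mask)
            shapeRows[[paste(id, phase)]] <-
              cbind(data.frame(image_id = id, phase = phase), sh)
            hh <- hueHistogram(maskedHues(phImg, mask),
                               binWidth = hueBinWidth, imageId = id)
            hueRows[[paste(id, phase)]] <- data.frame(
              image_id = id, phase = phase,
              bin_start_deg = hueBreaks(hh), percent = hh@percent)
          } else {
            errRows[[paste(id, phase)]] <- data.frame(
              image_id = id, step = paste0("segment_", phase),
              error = "empty mask: no pixels within threshold bounds")
          }
        }
      }
      NULL
    }, colorCard_error = function(e) e, error = function(e) e)
    if (!is.null(res))
      errRows[[id]] <- data.frame(image_id = id, step = "pipeline",
                                  error = conditionMessage(res))
  }

  out <- list(
    deviance = do.call(rbind, devRows),
    shapes = do.call(rbind, shapeRows),
    hue = do.call(rbind, hueRows),
    errors = if (length(errRows)) do.call(rbind, errRows) else
      data.frame(image_id = character(), step = character(),
                 error = character()))
  for (nm in names(out))
    if (!is.null(out[[nm]])) rownames(out[[nm]]) <- NULL
  writeTable(out$deviance, file.path(outputDir, "deviance.csv"))
  if (!is.null(out$shapes))
    writeTable(out$shapes, file.path(outputDir, "shapes.csv"))
  if (!is.null(out$hue))
    writeTable(out$hue, file.path(outputDir, "hue.csv"))
  writeTable(out$errors, file.path(outputDir, "errors.csv"))
  invisible(out)
}
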