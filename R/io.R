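## Raster and transform serialization.
##
## Images are numeric arrays height x width x 3 on the 0-255 scale
## everywhere inside the package; files store 8-bit channels.

#' Read an RGB image as a 0-255 array
#'
#' PNG and TIFF are read natively; other formats (e.g. JPEG) go through
#' \pkg{EBImage}.  Grayscale files are expanded to three identical
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path file path.
#' @return numeric height x width x 3 array, values in [0, 255].
#' @export
readImageRGB <- function(path) {
  if (!file.exists(path))
    ccStop("colorCard_format", "image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    ## EBImage stores width x height [x frames]; transpose into row-major
    x <- try(EBImage::imageData(EBImage::readImage(path)), silent = TRUE)
    if (inherits(x, "try-error"))
      ccStop("colorCard_format", "could not read image: %s", path)
    if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
  }
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L)
    ccStop("colorCard_format", "unsupported raster layout in %s", path)
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L)
    ccStop("colorCard_format", "expected a 3-channel image: %s", path)
  img * 255
}

#' Write a 0-255 RGB array as an 8-bit image file
#'
#' Values are clipped to [0, 255] and rounded half-up.  Format follows
#' the file extension (png or tif/tiff).
#'
#' @param image height x width x 3 array on the 0-255 scale.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeImageRGB <- function(image, path) {
  stopifnotImage(image)
  x <- roundHalfUp(clip255(image)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(x, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  } else {
    ccStop("colorCard_format", "unsupported output format: .%s", ext)
  }
  invisible(path)
}

#' Read/write binary masks as 8-bit PNG (0/255)
#'
#' @param mask binary 0/1 matrix.
#' @param path file path.
#' @return \code{readMask()} a 0/1 integer matrix; \code{writeMask()} the
#'   path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnotMask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(x > 0.5), nrow(x), ncol(x))
}

#' Serialize a fitted transform to JSON
#'
#' The JSON document carries the 3 x 9 coefficient table (written at full
#' double precision so the round-trip is bit-exact), chip count, source
#' and target image ids, and solver metadata.
#'
#' @param transform a [ColorTransform-class].
#' @param path destination JSON path.
#' @return \code{writeColorTransform()} the path invisibly;
#'   \code{readColorTransform()} the reconstructed
#'   [ColorTransform-class].
#' @examples
#' cc <- ChipColorMatrix(canonicalChipColors(), imageId = "ref")
#' tr <- fitColorTransform(cc, cc)
#' f <- tempfile(fileext = ".json")
#' writeColorTransform(tr, f)
#' tr2 <- readColorTransform(f)
#' stopifnot(identical(tr@coefficients, tr2@coefficients))
#' @export
writeColorTransform <- function(transform, path) {
  stopifnot(is(transform, "ColorTransform"))
  co <- transform@coefficients
  doc <- list(
    format = "colorCard-transform",
    version = 1L,
    source_image_id = transform@sourceImageId,
    target_image_id = transform@targetImageId,
    chip_count = transform@chipCount,
    solver = transform@solver,
    terms = rownames(co),
    coefficients = list(R = co[, "R"], G = co[, "G"], B = co[, "B"]))
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname writeColorTransform
#' @export
readColorTransform <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$format) || doc$format != "colorCard-transform")
    ccStop("colorCard_format", "not a colorCard transform document: %s", path)
  co <- cbind(R = doc$coefficients$R, G = doc$coefficients$G,
              B = doc$coefficients$B)
  rownames(co) <- doc$terms
  new("ColorTransform", coefficients = co,
      sourceImageId = doc$source_image_id,
      targetImageId = doc$target_image_id,
      chipCount = as.integer(doc$chip_count), solver = doc$solver)
}
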