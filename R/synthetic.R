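## Seeded synthetic scenes: a rendered 24-chip card plus a green "plant"
## disc on a uniform background, with parametric distortions emulating
## temperature-dependent light variation, and full ground truth.

#' Canonical 24-chip reference card colors
#'
#' The classic nominal sRGB values of a standard 4x6 24-patch reference
#' chart (dark skin through black, row-major).  These are fixture
#' constants for the synthetic generator -- a diverse, full-rank chip
#' palette -- not measurements of any physical card.
#'
#' @return 24 x 3 numeric matrix (columns R, G, B, 0-255).
#' @export
canonicalChipColors <- function() {
  m <- matrix(c(
    115,  82,  68,   194, 150, 130,    98, 122, 157,    87, 108,  67,
    133, 128, 177,   103, 189, 170,   214, 126,  44,    80,  91, 166,
    193,  90,  99,    94,  60, 108,   157, 188,  64,   224, 163,  46,
     56,  61, 150,    70, 148,  73,   175,  54,  60,   231, 199,  31,
    187,  86, 149,     8, 133, 161,   243, 243, 242,   200, 200, 200,
    160, 160, 160,   122, 122, 121,    85,  85,  85,    52,  52,  52),
    ncol = 3L, byrow = TRUE)
  colnames(m) <- c("R", "G", "B")
  rownames(m) <- c("dark.skin", "light.skin", "blue.sky", "foliage",
                   "blue.flower", "bluish.green", "orange", "purplish.blue",
                   "moderate.red", "purple", "yellow.green", "orange.yellow",
                   "blue", "green", "red", "yellow", "magenta", "cyan",
                   "white", "neutral.8", "neutral.65", "neutral.5",
                   "neutral.35", "black")
  m
}

#' Specify a synthetic scene
#'
#' Defaults render a 256 x 192 frame with the 24-chip card in the upper
#' left (16 px chips, 4 px gaps), a radially shaded green plant disc on
#' the lower right, and a light gray background.  The plant color grades
#' from \code{plantColorCenter} to \code{plantColorEdge} so its hue
#' distribution has realistic within-plant spread.  Card and plant must
#' be disjoint and in bounds.
#'
#' @param width,height frame size in pixels.
#' @param cardOrigin length-2 c(x, y), 0-based top-left of the chip grid.
#' @param chipSize,chipGap chip edge length and gap, pixels.
#' @param chipColors k x 3 matrix of chip colors (defaults to
#'   [canonicalChipColors()]).
#' @param plantCenter length-2 c(x, y) disc center, 0-based pixels.
#' @param plantRadius disc radius in pixels.
#' @param plantColorCenter,plantColorEdge RGB of disc center and rim.
#' @param background background RGB.
#' @param seed integer recorded in the spec (rendering itself is
#'   deterministic; distortions draw their own noise).
#' @return a validated scene specification (list).
#' @export
sceneSpec <- function(width = 256, height = 192,
                      cardOrigin = c(8, 8), chipSize = 16, chipGap = 4,
                      chipColors = canonicalChipColors(),
                      plantCenter = c(185, 140), plantRadius = 30,
                      plantColorCenter = c(50, 140, 45),
                      plantColorEdge = c(90, 155, 40),
                      background = c(190, 190, 190), seed = 4242L) {
  spec <- list(width = width, height = height, cardOrigin = cardOrigin,
               chipSize = chipSize, chipGap = chipGap,
               chipColors = as.matrix(chipColors),
               plantCenter = plantCenter, plantRadius = plantRadius,
               plantColorCenter = plantColorCenter,
               plantColorEdge = plantColorEdge,
               background = background, seed = as.integer(seed))
  nChips <- nrow(spec$chipColors)
  if (nChips != 24L)
    ccStop("colorCard_config", "scene expects 24 chip colors, got %d", nChips)
  cardW <- 6 * chipSize + 5 * chipGap
  cardH <- 4 * chipSize + 3 * chipGap
  if (cardOrigin[1] + cardW > width || cardOrigin[2] + cardH > height)
    ccStop("colorCard_geometry", "card extends past the frame")
  if (plantCenter[1] + plantRadius >= width ||
      plantCenter[2] + plantRadius >= height ||
      plantCenter[1] - plantRadius < 0 || plantCenter[2] - plantRadius < 0)
    ccStop("colorCard_geometry", "plant disc extends past the frame")
  ## disjointness: card bounding box vs disc bounding box
  if (plantCenter[1] - plantRadius <= cardOrigin[1] + cardW &&
      plantCenter[1] + plantRadius >= cardOrigin[1] &&
      plantCenter[2] - plantRadius <= cardOrigin[2] + cardH &&
      plantCenter[2] + plantRadius >= cardOrigin[2])
    ccStop("colorCard_geometry", "card and plant regions overlap")
  spec
}

#' Render a synthetic scene with ground truth
#'
#' Deterministic given the spec: chips are uniform at their ground-truth
#' colors, the plant disc contains every pixel whose center lies within
#' the radius, and the returned mask is exactly the disc.
#'
#' @param spec from [sceneSpec()].
#' @return list with \code{image} (height x width x 3, 0-255),
#'   \code{mask} (ground-truth 0/1 matrix), \code{chips} (ground-truth
#'   [ChipColorMatrix-class]), \code{layout} (a [CardLayout-class] whose
#'   ROIs locate the rendered chips).
#' @export
renderScene <- function(spec) {
  w <- spec$width; h <- spec$height
  img <- array(rep(spec$background, each = h * w), dim = c(h, w, 3L))

  rois <- matrix(0, 24L, 4L)
  k <- 0L
  for (row in 0:3) for (col in 0:5) {
    k <- k + 1L
    x <- spec$cardOrigin[1] + col * (spec$chipSize + spec$chipGap)
    y <- spec$cardOrigin[2] + row * (spec$chipSize + spec$chipGap)
    rois[k, ] <- c(x, y, spec$chipSize, spec$chipSize)
    for (ch in 1:3)
      img[(y + 1):(y + spec$chipSize), (x + 1):(x + spec$chipSize), ch] <-
        spec$chipColors[k, ch]
  }

  ## plant: radially shaded disc (pixel-center rasterization)
  xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
  yg <- matrix(0:(h - 1), h, w)
  dist <- sqrt((xg - spec$plantCenter[1])^2 + (yg - spec$plantCenter[2])^2)
  inside <- dist <= spec$plantRadius
  frac <- pmin(dist / spec$plantRadius, 1)
  for (ch in 1:3) {
    plane <- img[, , ch]
    shade <- spec$plantColorCenter[ch] +
      (spec$plantColorEdge[ch] - spec$plantColorCenter[ch]) * frac
    plane[inside] <- shade[inside]
    img[, , ch] <- plane
  }

  layout <- CardLayout(rois, gridRows = 4L, gridCols = 6L,
                       insetFraction = 0.25)
  list(image = img,
       mask = matrix(as.integer(inside), h, w),
       chips = ChipColorMatrix(spec$chipColors,
                               chipIds = chipIds(layout),
                               imageId = "ground-truth"),
       layout = layout)
}

#' Specify a parametric image distortion
#'
#' Emulates temperature-dependent light variation: per channel, the
#' normalized intensity v/255 is scaled by \code{brightnessScale}, raised
#' to that channel's gamma and rescaled to 0-255; an optional full cubic
#' cross-channel polynomial (9 coefficients per channel, same term order
#' as [extendDesign()]) is then applied, followed by additive Gaussian
#' noise truncated at the channel bounds.  The identity spec
#' (scale 1, gammas 1, no polynomial, sd 0) is a no-op.
#'
#' @param brightnessScale global multiplicative factor (> 0).
#' @param gamma length-3 per-channel exponents (> 0).
#' @param polynomial optional 9 x 3 coefficient matrix, or NULL.
#' @param noiseSd Gaussian noise standard deviation (>= 0), 0-255 scale.
#' @param seed integer seed controlling the noise draw.
#' @return a validated distortion specification (list).
#' @export
distortionSpec <- function(brightnessScale = 1, gamma = c(1, 1, 1),
                           polynomial = NULL, noiseSd = 0, seed = 4242L) {
  if (brightnessScale <= 0 || any(gamma <= 0) || noiseSd < 0)
    ccStop("colorCard_config",
           "brightnessScale and gamma must be > 0, noiseSd >= 0")
  if (!is.null(polynomial)) {
    polynomial <- as.matrix(polynomial)
    if (!identical(dim(polynomial), c(9L, 3L)))
      ccStop("colorCard_config", "polynomial must be a 9 x 3 matrix")
  }
  list(brightnessScale = brightnessScale, gamma = as.numeric(gamma),
       polynomial = polynomial, noiseSd = noiseSd, seed = as.integer(seed))
}

#' Apply a parametric distortion to an image
#'
#' @param image height x width x 3 array, 0-255 scale.
#' @param d from [distortionSpec()].
#' @return distorted 8-bit image (clipped, rounded half-up).
#' @examples
#' img <- array(127.5, dim = c(1, 1, 3))
#' distortImage(img, distortionSpec(gamma = c(2, 2, 2)))[1, 1, ]  # 64
#' @export
distortImage <- function(image, d) {
  stopifnotImage(image)
  out <- image
  for (ch in 1:3)
    out[, , ch] <- 255 * (d$brightnessScale * out[, , ch] / 255)^d$gamma[ch]
  if (!is.null(d$polynomial)) {
    dm <- dim(out)
    px <- matrix(out, ncol = 3L)
    out <- array(applyCoefficients(d$polynomial, px), dim = dm)
  }
  if (d$noiseSd > 0) {
    rs <- withSeed(d$seed, rnorm(length(out), sd = d$noiseSd))
    out <- out + array(rs, dim = dim(out))
  }
  roundHalfUp(clip255(out))
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a reference/distorted scene pair with truths
#'
#' @param scene from [sceneSpec()].
#' @param d from [distortionSpec()].
#' @return list \code{reference}, \code{distorted} (images) and
#'   \code{truth} (mask, chips, layout, and both specs).
#' @export
makeScenePair <- function(scene, d) {
  ref <- renderScene(scene)
  distorted <- distortImage(ref$image, d)
  list(reference = ref$image, distorted = distorted,
       truth = list(mask = ref$mask, chips = ref$chips,
                    layout = ref$layout, scene = scene, distortion = d))
}

#' Diurnal distortion family
#'
#' A seeded family of n distortion specs emulating day/night temperature
#' cycling of the light source: "day" images get a mild dimming
#' (brightness scale uniform in [0.80, 0.90]) with near-neutral channel
#' gammas (1.02, 1, 0.98); "night" images a strong one (scale in
#' [0.50, 0.60]) with a colder cast (gammas 1.10, 1, 0.92).  Additive
#' noise sd is 1.5 intensity units throughout.  Per-channel gamma is what
#' makes hue shift with temperature -- a uniform brightness scale alone
#' leaves hue unchanged.
#'
#' @param n number of specs (alternating day/night phases).
#' @param seed integer seed for the scale draws and the per-image noise
#'   seeds.
#' @return list of n elements, each \code{list(phase, spec)} with phase
#'   \code{"day"} or \code{"night"}.
#' @export
diurnalDistortionFamily <- function(n = 20, seed = 4242L) {
  phases <- rep(c("day", "night"), length.out = n)
  scales <- withSeed(seed, {
    s <- numeric(n)
    for (i in seq_len(n))
      s[i] <- if (phases[i] == "day") runif(1, 0.80, 0.90)
              else runif(1, 0.50, 0.60)
    s
  })
  lapply(seq_len(n), function(i) {
    g <- if (phases[i] == "day") c(1.02, 1.00, 0.98) else c(1.10, 1.00, 0.92)
    list(phase = phases[i],
         spec = distortionSpec(brightnessScale = scales[i], gamma = g,
                               noiseSd = 1.5, seed = seed + i))
  })
}

#' Write a simulated image set to disk
#'
#' Renders the reference scene and n distorted variants (the
#' [diurnalDistortionFamily()]), writing PNG images, the card layout
#' YAML, a default plant threshold YAML, and a truths JSON (per-image
#' phase and distortion parameters, ground-truth plant area and chip
#' colors).  The directory is directly consumable by [runPipeline()].
#'
#' @param dir output directory (created if needed).
#' @param n number of distorted images.
#' @param seed integer seed.
#' @param scene from [sceneSpec()].
#' @return invisibly, the truths list.
#' @export
simulateImageSet <- function(dir, n = 20, seed = 4242L, scene = sceneSpec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- renderScene(scene)
  writeImageRGB(ref$image, file.path(dir, "reference.png"))
  writeCardLayout(ref$layout, file.path(dir, "layout.yaml"))
  writeThresholdConfig(defaultPlantThreshold(),
                       file.path(dir, "threshold.yaml"))
  fam <- diurnalDistortionFamily(n, seed)
  images <- list()
  for (i in seq_len(n)) {
    id <- sprintf("scene_%02d", i)
    img <- distortImage(ref$image, fam[[i]]$spec)
    writeImageRGB(img, file.path(dir, paste0(id, ".png")))
    s <- fam[[i]]$spec
    images[[id]] <- list(phase = fam[[i]]$phase,
                         brightness_scale = s$brightnessScale,
                         gamma = s$gamma, noise_sd = s$noiseSd,
                         seed = s$seed)
  }
  truths <- list(reference = "reference", seed = seed,
                 plant_area = sum(ref$mask),
                 chip_colors = unname(chipValues(ref$chips)),
                 images = images)
  writeLines(jsonlite::toJSON(truths, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "truths.json"))
  writeMask(ref$mask, file.path(dir, "truth_mask.png"))
  invisible(truths)
}

#' Default plant threshold for the synthetic scenes
#'
#' Bounds bracketing the synthetic plant's green (R 25-115, G 120-185,
#' B 15-65) with wide margins against the rendering noise while excluding
#' the background and every card chip.
#'
#' @return a [ThresholdConfig-class].
#' @export
defaultPlantThreshold <- function() {
  ThresholdConfig(list(r = c(25, 115), g = c(120, 185), b = c(15, 65)),
                  configId = "synthetic-plant")
}
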