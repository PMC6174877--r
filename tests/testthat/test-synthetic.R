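test_that("scene rendering is deterministic with exact ground truth", {
  spec <- sceneSpec()
  a <- renderScene(spec); b <- renderScene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # chips render uniformly at their ground-truth colors
  chips <- sampleChips(a$image, a$layout)
  expect_equal(unname(chipValues(chips)), unname(chipValues(a$chips)))
  # plant mask equals brute-force disc rasterization
  oracle <- discMask(spec$plantRadius, size = max(spec$width, spec$height),
                     cx = spec$plantCenter[1], cy = spec$plantCenter[2])
  oracle <- oracle[seq_len(spec$height), seq_len(spec$width)]
  expect_identical(a$mask, oracle)
})

test_that("invalid scene geometry is rejected", {
  expect_error(sceneSpec(plantCenter = c(60, 40)),
               class = "colorCard_geometry")      # overlaps the card
  expect_error(sceneSpec(plantCenter = c(250, 150)),
               class = "colorCard_geometry")      # out of frame
})

test_that("distortion arithmetic and determinism", {
  img <- uniformImage(c(127.5, 127.5, 127.5), 4, 4)
  # identity spec is a no-op (up to 8-bit rounding of the input)
  id <- distortionSpec()
  expect_equal(distortImage(img, id), floor(img + 0.5), ignore_attr = TRUE)
  # 255 * (127.5/255)^2 = 63.75 -> 64 in 8-bit
  g2 <- distortionSpec(gamma = c(2, 2, 2))
  expect_true(all(distortImage(img, g2) == 64))
  # seeded noise is reproducible
  nz <- distortionSpec(noiseSd = 3, seed = 123)
  expect_identical(distortImage(img, nz), distortImage(img, nz))
  expect_false(identical(distortImage(img, nz),
                         distortImage(img, distortionSpec(noiseSd = 3,
                                                          seed = 124))))
  expect_error(distortionSpec(brightnessScale = 0),
               class = "colorCard_config")
})

test_that("an identity distortion pair has zero deviance", {
  pair <- makeScenePair(sceneSpec(), distortionSpec())
  layout <- pair$truth$layout
  ref <- sampleChips(pair$reference, layout, "ref")
  dst <- sampleChips(pair$distorted, layout, "dst")
  expect_lt(abs(deviance(fitColorHomography(dst, ref))), 1e-6)
})

test_that("gamma distortions are undone to within one intensity unit", {
  pair <- makeScenePair(sceneSpec(),
                        distortionSpec(brightnessScale = 0.9,
                                       gamma = c(1.08, 1, 0.94)))
  layout <- pair$truth$layout
  ref <- sampleChips(pair$reference, layout, "ref")
  dst <- sampleChips(pair$distorted, layout, "dst")
  tr <- fitColorTransform(dst, ref)
  std <- applyColorTransform(tr, pair$distorted)
  stdChips <- sampleChips(std, layout, "std")
  expect_lte(max(abs(chipValues(stdChips) - chipValues(ref))), 1)
})

test_that("halved brightness breaks segmentation until standardized", {
  pair <- makeScenePair(sceneSpec(), distortionSpec(brightnessScale = 0.5))
  cfg <- defaultPlantThreshold()
  truth <- pair$truth$mask
  maskDark <- thresholdSegment(pair$distorted, cfg)
  expect_gt(sum(maskDark != truth), 0)

  layout <- pair$truth$layout
  tr <- fitColorTransform(sampleChips(pair$distorted, layout, "d"),
                          sampleChips(pair$reference, layout, "r"))
  maskStd <- thresholdSegment(applyColorTransform(tr, pair$distorted), cfg)
  areaErr <- abs(sum(maskStd) - sum(truth)) / sum(truth)
  expect_lt(areaErr, 0.01)
})

test_that("the diurnal family stays inside its documented parameter bands", {
  fam <- diurnalDistortionFamily(20, seed = 77)
  phases <- vapply(fam, `[[`, character(1), "phase")
  scales <- vapply(fam, function(f) f$spec$brightnessScale, numeric(1))
  expect_identical(sum(phases == "day"), 10L)
  expect_true(all(scales[phases == "day"] >= 0.80 &
                  scales[phases == "day"] <= 0.90))
  expect_true(all(scales[phases == "night"] >= 0.50 &
                  scales[phases == "night"] <= 0.60))
  expect_identical(diurnalDistortionFamily(5, seed = 77)[[1]]$spec,
                   fam[[1]]$spec)
})

test_that("a simulated image set round-trips through disk", {
  dir <- file.path(tempdir(), "simset-test")
  unlink(dir, recursive = TRUE)
  truths <- simulateImageSet(dir, n = 2, seed = 5)
  expect_true(file.exists(file.path(dir, "reference.png")))
  expect_true(file.exists(file.path(dir, "scene_02.png")))
  layout <- readCardLayout(file.path(dir, "layout.yaml"))
  ref <- readImageRGB(file.path(dir, "reference.png"))
  chips <- sampleChips(ref, layout)
  expect_equal(unname(chipValues(chips)), truths$chip_colors)
  mask <- readMask(file.path(dir, "truth_mask.png"))
  expect_identical(sum(mask), as.integer(truths$plant_area))
})
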