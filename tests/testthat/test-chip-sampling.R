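test_that("chip sampling averages the inset ROI in layout order", {
  # 2 x 5 grid of 8x8 chips so the matrix has the required >= 9 rows
  img <- array(0, dim = c(30, 60, 3))
  rois <- matrix(0, 10, 4)
  cols <- matrix(runif(30, 20, 230), 10, 3)
  k <- 0
  for (r in 0:1) for (cl in 0:4) {
    k <- k + 1
    x <- 2 + cl * 11; y <- 3 + r * 12
    rois[k, ] <- c(x, y, 8, 8)
    for (ch in 1:3) img[(y + 1):(y + 8), (x + 1):(x + 8), ch] <- cols[k, ch]
  }
  layout <- CardLayout(rois, gridRows = 2, gridCols = 5, insetFraction = 0.25)
  chips <- sampleChips(img, layout, imageId = "flat")
  expect_equal(unname(chipValues(chips)), unname(cols))
  expect_identical(chipIds(chips), chipIds(layout))

  # mean of a half/half ROI: chip 1 gets R 100 on the left, 200 on the right
  img2 <- img
  x <- 2; y <- 3
  img2[(y + 1):(y + 8), (x + 1):(x + 4), 1] <- 100
  img2[(y + 1):(y + 8), (x + 5):(x + 8), 1] <- 200
  chips2 <- sampleChips(img2, layout)
  expect_equal(unname(chipValues(chips2)[1, 1]), 150)
})

gridROIs <- function(rows, cols, x0, y0, size, gap) {
  out <- matrix(0, rows * cols, 4)
  k <- 0
  for (r in 0:(rows - 1)) for (cl in 0:(cols - 1)) {
    k <- k + 1
    out[k, ] <- c(x0 + cl * (size + gap), y0 + r * (size + gap), size, size)
  }
  out
}

test_that("the inset excludes chip borders", {
  img <- array(120, dim = c(60, 60, 3))
  rois <- gridROIs(3, 3, 2, 2, 12, 4)
  # darken the leading border column of every chip: inside the ROI but
  # outside the inset core
  for (k in seq_len(nrow(rois)))
    img[(rois[k, 2] + 1):(rois[k, 2] + 12), rois[k, 1] + 1, ] <- 0
  layout <- CardLayout(rois, gridRows = 3, gridCols = 3, insetFraction = 0.25)
  chips <- sampleChips(img, layout)
  expect_equal(unname(chipValues(chips)), matrix(120, 9, 3))
})

test_that("out-of-bounds and degenerate ROIs are geometry errors", {
  img <- array(100, dim = c(16, 16, 3))
  bad <- CardLayout(gridROIs(3, 3, 2, 2, 10, 2), gridRows = 3, gridCols = 3,
                    insetFraction = 0)   # grid extends to x = 36 > 16
  expect_error(sampleChips(img, bad), class = "colorCard_geometry")
  tiny <- CardLayout(gridROIs(3, 3, 0, 0, 2, 3), gridRows = 3, gridCols = 3,
                     insetFraction = 0.49)
  expect_error(sampleChips(img, tiny), class = "colorCard_geometry")
})

test_that("overlapping chip ROIs are rejected at layout construction", {
  expect_error(CardLayout(matrix(c(4, 4, 12, 12), 9, 4, byrow = TRUE),
                          gridRows = 3, gridCols = 3),
               "overlap after inset")
})

test_that("sampling a rendered card recovers ground truth exactly", {
  scene <- renderScene(sceneSpec())
  chips <- sampleChips(scene$image, scene$layout, imageId = "ref")
  expect_equal(unname(chipValues(chips)),
               unname(chipValues(scene$chips)))
})

test_that("chip quality report flags saturation without failing", {
  vals <- canonicalChipColors()
  vals[19, ] <- c(255, 255, 255)
  rep <- validateChips(ChipColorMatrix(vals, imageId = "x"))
  expect_true(rep$pass)
  expect_identical(which(rep$flags$saturated), 19L)
  expect_error(validateChips(matrix(0, 0, 3)),
               class = "colorCard_invalid_input")
})

test_that("card layout YAML round-trips and validates on load", {
  scene <- renderScene(sceneSpec())
  f <- tempfile(fileext = ".yaml")
  writeCardLayout(scene$layout, f)
  lay2 <- readCardLayout(f)
  expect_equal(chipROIs(lay2), chipROIs(scene$layout), ignore_attr = TRUE)
  expect_identical(chipIds(lay2), chipIds(scene$layout))
  expect_equal(lay2@insetFraction, scene$layout@insetFraction)

  writeLines("grid_rows: 4\ngrid_cols: 6\n", f)
  expect_error(readCardLayout(f), class = "colorCard_config")
  writeLines(c("grid_rows: 4", "grid_cols: 6", "chip_rois:",
               "- {x: 1, y: 1}"), f)
  err <- expect_error(readCardLayout(f), class = "colorCard_config")
  expect_match(conditionMessage(err), "entry 1")
})

test_that("threshold config YAML round-trips", {
  cfg <- ThresholdConfig(list(g = c(120, 185), h = c(80, 160)),
                         keepLargestComponent = TRUE, configId = "t1")
  f <- tempfile(fileext = ".yaml")
  writeThresholdConfig(cfg, f)
  cfg2 <- readThresholdConfig(f)
  expect_equal(cfg2@bounds, cfg@bounds)
  expect_true(cfg2@keepLargestComponent)
  expect_identical(cfg2@configId, "t1")
})
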