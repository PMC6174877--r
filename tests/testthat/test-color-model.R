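test_that("extendDesign builds linear, quadratic and cubic columns", {
  d <- extendDesign(rbind(c(2, 3, 4), c(0, 0, 0), c(1, 1, 1)))
  expect_equal(unname(d[1, ]), c(2, 3, 4, 4, 9, 16, 8, 27, 64))
  expect_equal(unname(d[2, ]), rep(0, 9))
  expect_equal(unname(d[3, ]), rep(1, 9))
  expect_error(extendDesign(rbind(c(1, NaN, 2))), class = "colorCard_invalid_input")
})

test_that("pseudoinverse satisfies M S = I and matches the plain inverse", {
  for (seed in 1:5) {
    S <- extendDesign(chipValues(randomChips(seed)))
    M <- designPseudoinverse(S)
    expect_equal(M %*% S, diag(9), ignore_attr = TRUE, tolerance = 1e-6)
  }
  # square full-rank design: pseudoinverse is the ordinary inverse
  set.seed(11)
  S9 <- extendDesign(matrix(runif(27, 10, 245), 9, 3))
  expect_equal(designPseudoinverse(S9), solve(S9), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("rank-deficient chip sets are rejected, naming the rank", {
  # 24 rows but only 8 distinct colors -> rank <= 8
  set.seed(3)
  base <- matrix(runif(24, 10, 245), 8, 3)
  chips <- ChipColorMatrix(base[rep(1:8, 3), ], imageId = "degenerate")
  err <- expect_error(designPseudoinverse(extendDesign(chips)),
                      class = "colorCard_singular_design")
  expect_match(conditionMessage(err), "rank 8")
  expect_error(fitColorTransform(chips, chips),
               class = "colorCard_singular_design")
})

test_that("regressing a chip set on itself yields the identity transform", {
  chips <- ChipColorMatrix(canonicalChipColors(), imageId = "ref")
  tr <- fitColorTransform(chips, chips)
  expect_equal(unname(channelCoefficients(tr, "R")),
               c(1, rep(0, 8)), tolerance = 1e-6)
  expect_equal(unname(channelCoefficients(tr, "G")),
               c(0, 1, rep(0, 7)), tolerance = 1e-6)
  expect_equal(unname(channelCoefficients(tr, "B")),
               c(0, 0, 1, rep(0, 6)), tolerance = 1e-6)
  # and the transform is the identity map on the chip colors themselves
  std <- applyColorTransform(tr, array(chipValues(chips), c(24, 1, 3)),
                             bitDepth = "float")
  expect_equal(matrix(std, 24, 3), unname(chipValues(chips)),
               tolerance = 1e-8)
})

test_that("a target generated by a known cubic polynomial is recovered", {
  chips <- randomChips(21, "src")
  gen <- cbind(R = c(0.9, 0.02, 0, 1e-4, 0, 0, -2e-7, 0, 0),
               G = c(0.05, 0.85, 0, 0, 2e-4, 0, 0, -1e-7, 0),
               B = c(0, 0.03, 0.92, 0, 0, 1e-4, 0, 0, -3e-7))
  tgtVals <- extendDesign(chips) %*% gen
  tgt <- ChipColorMatrix(tgtVals, chipIds = chipIds(chips), imageId = "tgt")
  tr <- fitColorTransform(chips, tgt)
  expect_lt(max(abs(tr@coefficients - gen)), 1e-6)
  # exact fit: standardized chip colors equal the target chip colors
  std <- applyColorTransform(tr, array(chipValues(chips), c(24, 1, 3)),
                             bitDepth = "float")
  expect_equal(matrix(std, 24, 3), unname(tgtVals), tolerance = 1e-6)
})

test_that("fitted coefficients match an independent least-squares oracle", {
  for (seed in 1:20) {
    src <- randomChips(seed, "s")
    tgt <- ChipColorMatrix(chipValues(randomChips(seed + 1000)),
                           chipIds(src), "t")
    tr <- fitColorTransform(src, tgt)
    oracle <- lsOracle(src, chipValues(tgt))
    expect_equal(unname(tr@coefficients), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("pixel application follows the polynomial, with clipping", {
  chips <- ChipColorMatrix(canonicalChipColors(), imageId = "ref")
  idTr <- fitColorTransform(chips, chips)
  expect_equal(unname(applyColorTransform(idTr, c(100, 200, 40))),
               c(100, 200, 40))
  halving <- idTr
  halving@coefficients <- rbind(0.5 * diag(3), matrix(0, 6, 3))
  colnames(halving@coefficients) <- c("R", "G", "B")
  expect_equal(unname(applyColorTransform(halving, c(100, 200, 40))),
               c(50, 100, 20))
  doubling <- halving
  doubling@coefficients <- rbind(2 * diag(3), matrix(0, 6, 3))
  colnames(doubling@coefficients) <- c("R", "G", "B")
  expect_equal(unname(applyColorTransform(doubling, c(200, 0, 0))),
               c(255, 0, 0))   # 400 clipped to 255
  expect_equal(unname(applyColorTransform(doubling, c(200, 0, 0),
                                          bitDepth = "float")),
               c(400, 0, 0))   # float mode preserves the excursion
})

test_that("image application is pixelwise and preserves dimensions", {
  chips <- ChipColorMatrix(canonicalChipColors(), imageId = "ref")
  idTr <- fitColorTransform(chips, chips)
  img <- uniformImage(c(100, 200, 40), 6, 9)
  expect_identical(dim(applyColorTransform(idTr, img)), dim(img))
  expect_equal(applyColorTransform(idTr, img), img, ignore_attr = TRUE)
  halving <- idTr
  halving@coefficients <- rbind(0.5 * diag(3), matrix(0, 6, 3))
  colnames(halving@coefficients) <- c("R", "G", "B")
  expect_equal(unique(as.vector(applyColorTransform(halving, img)[, , 1])), 50)
  expect_error(applyColorTransform(idTr, array(0, c(4, 4, 2))),
               class = "colorCard_format")
})

test_that("homography of identical profiles is the identity matrix", {
  for (seed in c(1, 7)) {
    chips <- randomChips(seed)
    h <- fitColorHomography(chips, chips)
    expect_equal(homographyMatrix(h), diag(9), ignore_attr = TRUE,
                 tolerance = 1e-6)
    expect_lt(abs(deviance(h)), 1e-6)
  }
})

test_that("homography is invariant to a consistent chip reordering", {
  src <- randomChips(5, "s")
  tgt <- ChipColorMatrix(chipValues(randomChips(6)), chipIds(src), "t")
  h1 <- fitColorHomography(src, tgt)
  set.seed(99); perm <- sample(24)
  srcP <- ChipColorMatrix(chipValues(src)[perm, ], chipIds(src)[perm], "s")
  tgtP <- ChipColorMatrix(chipValues(tgt)[perm, ], chipIds(tgt)[perm], "t")
  h2 <- fitColorHomography(srcP, tgtP)
  expect_equal(homographyMatrix(h1), homographyMatrix(h2), tolerance = 1e-8)
  expect_equal(deviance(h1), deviance(h2), tolerance = 1e-8)
})

test_that("homography rows match nine independent regressions", {
  src <- randomChips(31, "s")
  tgt <- ChipColorMatrix(chipValues(randomChips(32)), chipIds(src), "t")
  h <- fitColorHomography(src, tgt)
  oracle <- t(lsOracle(src, extendDesign(tgt)))
  expect_equal(unname(homographyMatrix(h)), unname(oracle), tolerance = 1e-8)
})

test_that("mismatched chip ids are a correspondence error", {
  src <- randomChips(1, "s")
  tgt <- ChipColorMatrix(chipValues(randomChips(2)),
                         chipIds = rev(chipIds(src)), imageId = "t")
  expect_error(fitColorTransform(src, tgt), class = "colorCard_correspondence")
  expect_error(fitColorHomography(src, tgt), class = "colorCard_correspondence")
})

test_that("deviance is 1 - det(H)", {
  expect_identical(devianceScore(diag(9)), 0)
  expect_equal(devianceScore(2 * diag(9)), 1 - 2^9)
  src <- randomChips(41, "s")
  dim2 <- ChipColorMatrix(0.6 * chipValues(src), chipIds(src), "dim")
  h <- fitColorHomography(dim2, src)
  expect_equal(deviance(h), 1 - detOracle(homographyMatrix(h)),
               tolerance = 1e-6 * max(1, abs(deviance(h))))
})

test_that("deviance magnitude grows as brightness drops", {
  ref <- ChipColorMatrix(canonicalChipColors(), imageId = "ref")
  dev <- vapply(c(1, 0.9, 0.8, 0.7, 0.6, 0.5), function(s) {
    dimmed <- ChipColorMatrix(s * chipValues(ref), chipIds(ref), "dim")
    deviance(fitColorHomography(dimmed, ref))
  }, numeric(1))
  expect_lt(abs(dev[1]), 1e-6)
  expect_gt(abs(dev[6]), abs(dev[2]))   # |D| at 0.5 exceeds |D| at 0.9
  expect_true(all(diff(abs(dev)) > 0))  # and in fact grows monotonically
})

test_that("transform JSON serialization round-trips bit-exactly", {
  src <- randomChips(51, "s")
  tgt <- ChipColorMatrix(chipValues(randomChips(52)), chipIds(src), "t")
  tr <- fitColorTransform(src, tgt)
  f <- tempfile(fileext = ".json")
  writeColorTransform(tr, f)
  tr2 <- readColorTransform(f)
  expect_identical(tr2@coefficients, tr@coefficients)
  expect_identical(tr2@sourceImageId, tr@sourceImageId)
  expect_identical(tr2@chipCount, tr@chipCount)
})
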