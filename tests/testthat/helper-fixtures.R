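# Programmatic fixtures and independent oracles shared across tests.

# random full-rank 24-chip matrix on the 0-255 scale
randomChips <- function(seed, imageId = "random") {
  set.seed(seed)
  ChipColorMatrix(matrix(runif(72, 5, 250), 24, 3), imageId = imageId)
}

# independent least-squares oracle: QR via lm.fit (the package path is SVD)
lsOracle <- function(sourceChips, targetColumns) {
  ext <- cbind(chipValues(sourceChips), chipValues(sourceChips)^2,
               chipValues(sourceChips)^3)
  stats::lm.fit(ext, targetColumns)$coefficients
}

# independent determinant oracle: product of eigenvalues
detOracle <- function(m) {
  Re(prod(eigen(m, only.values = TRUE)$values))
}

# disc mask by brute-force pixel-center rasterization
discMask <- function(radius, size = 2 * radius + 9,
                     cx = (size - 1) / 2, cy = (size - 1) / 2) {
  m <- matrix(0L, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    if ((j - 1 - cx)^2 + (i - 1 - cy)^2 <= radius^2) m[i, j] <- 1L
  }
  m
}

# uniform color image
uniformImage <- function(rgb, h = 8, w = 8) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}
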