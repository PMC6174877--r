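## Internal helpers shared across modules.

ccStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "colorCard_error")))
}

## round-half-up (base round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

stopifnotImage <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    ccStop("colorCard_format",
           "expected a height x width x 3 RGB array, got dimensions [%s]",
           paste(dim(image), collapse = ", "))
  if (!all(is.finite(image)))
    ccStop("colorCard_invalid_input", "image contains non-finite values")
  invisible(image)
}

stopifnotMask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    ccStop("colorCard_invalid_input",
           "expected a binary height x width matrix of 0/1 values")
  invisible(mask)
}

## 8-connected component labeling. EBImage::bwlabel is 4-connected, so
## labels that touch only diagonally are merged with a small union-find
## pass over the (few) 4-connected labels.
labels8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]),  as.vector(lab[-1, -nc])))  # down-left
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}
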