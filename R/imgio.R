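# Image input/output and array plumbing: TIFF stacks, focus selection,
# tile stitching, z-score normalization and tile/untile bookkeeping for
# classifier input.

#' Read a multi-page TIFF as a TimeLapse
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param calibration a [Calibration-class] attached to the result.
#' @return A [TimeLapse-class]; pixel values as stored (0..1 for integer
#'   TIFFs as read by the tiff package).
#' @export
readTimeLapse <- function(path, calibration = colonytrack::calibration()) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra channels
    p
  })
  timeLapse(pages, calibration = calibration)
}

#' Write a TimeLapse to a 16-bit multi-page TIFF
#'
#' Frames are linearly rescaled to the stack's global range before 16-bit
#' quantization; the range is not stored (images, unlike labels, are only
#' consumed after z-score normalization).
#'
#' @param x a [TimeLapse-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTimeLapse <- function(x, path) {
  fr <- frames(x)
  lo <- min(vapply(fr, min, 0)); hi <- max(vapply(fr, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  fr <- lapply(fr, function(f) (f - lo) / scale)
  tiff::writeTIFF(fr, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read / write integer label stacks as TIFF
#'
#' Label masks (instance or class labels) are stored as 32-bit float TIFF
#' pages holding `label / 2^16`: dyadic fractions that float32 represents
#' exactly for labels up to 65535, within the [0, 1] range the TIFF writer
#' expects.
#'
#' @param path file path.
#' @return `readLabelStack`: a list of integer matrices.
#' @export
readLabelStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    m <- round(p * 65536)
    storage.mode(m) <- "integer"
    m
  })
}

#' @rdname readLabelStack
#' @param labels a list of integer matrices (or a single matrix).
#' @export
writeLabelStack <- function(labels, path) {
  if (is.matrix(labels)) labels <- list(labels)
  stopifnot(all(vapply(labels, function(m) max(m) < 65536, TRUE)))
  pages <- lapply(labels, function(m) m / 65536)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Select the sharpest plane of a z-stack
#'
#' Sharpness is scored by the variance of the discrete Laplacian; the
#' in-focus plane of a phase-contrast z-stack maximizes it.
#'
#' @param zStack list of 2-D matrices of identical shape.
#' @return The selected plane with attribute `"index"` (1-based plane index).
#' @examples
#' img <- matrix(rnorm(64^2), 64)
#' sharp <- selectBestFocus(list(0.5 * img, img))
#' attr(sharp, "index")  # 2
#' @export
selectBestFocus <- function(zStack) {
  if (is.matrix(zStack)) zStack <- list(zStack)
  if (length(zStack) < 1L) stop("empty z-stack")
  d <- dim(zStack[[1L]])
  if (!all(vapply(zStack, function(p) identical(dim(p), d), logical(1))))
    stop("all z-planes must share one shape")
  score <- vapply(zStack, laplacianVariance, 0)
  i <- which.max(score)
  out <- zStack[[i]]
  attr(out, "index") <- i
  attr(out, "score") <- score
  out
}

laplacianVariance <- function(m) {
  lap <- 4 * m -
    shiftMatrix(m, 1L, 0L, fill = NA) - shiftMatrix(m, -1L, 0L, fill = NA) -
    shiftMatrix(m, 0L, 1L, fill = NA) - shiftMatrix(m, 0L, -1L, fill = NA)
  var(as.vector(lap), na.rm = TRUE)
}

#' Stitch a grid of fields of view into one mosaic
#'
#' Tiles are placed at their nominal stage offsets (no registration
#' refinement); in overlap strips the output pixel is the mean of all
#' contributing tiles. With tile size `s` and overlap fraction `f`, the step
#' between neighbors is `round(s * (1 - f))` pixels per axis.
#'
#' @param tiles a list-of-lists (rows of tiles) or a matrix-like list with
#'   `dim` attribute; all tiles must share one shape.
#' @param overlapFraction fraction of the linear tile size shared by
#'   neighboring tiles, in [0, 0.5) (default 0.10).
#' @return The stitched 2-D matrix.
#' @export
stitchGrid <- function(tiles, overlapFraction = 0.10) {
  if (is.matrix(tiles)) tiles <- list(list(tiles))
  if (!is.list(tiles[[1L]])) tiles <- list(tiles)
  if (overlapFraction < 0 || overlapFraction >= 0.5)
    stop("overlapFraction must lie in [0, 0.5)")
  nrows <- length(tiles)
  ncols <- unique(vapply(tiles, length, 0L))
  if (length(ncols) != 1L) stop("ragged tile grid")
  d <- dim(tiles[[1L]][[1L]])
  for (r in seq_len(nrows)) for (c in seq_len(ncols))
    if (!identical(dim(tiles[[r]][[c]]), d)) stop("all tiles must share one shape")
  stepR <- round(d[1L] * (1 - overlapFraction))
  stepC <- round(d[2L] * (1 - overlapFraction))
  H <- stepR * (nrows - 1L) + d[1L]
  W <- stepC * (ncols - 1L) + d[2L]
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (r in seq_len(nrows)) for (c in seq_len(ncols)) {
    rs <- (r - 1L) * stepR + seq_len(d[1L])
    cs <- (c - 1L) * stepC + seq_len(d[2L])
    acc[rs, cs] <- acc[rs, cs] + tiles[[r]][[c]]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  acc / cnt
}

#' Z-score normalize an image
#'
#' Standard pre-processing before classification: subtract the mean and
#' divide by the standard deviation over all pixels.
#'
#' @param image numeric matrix (or array) with more than one pixel.
#' @return Array of the same shape with mean 0 and SD 1.
#' @export
zscoreNormalize <- function(image) {
  v <- as.vector(image)
  if (length(v) < 2L) stop("need more than one pixel")
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop("constant image: zero variance")
  (image - mean(v)) / s
}

#' Tile an array for classifier input, and reassemble
#'
#' `tileImage` cuts a 2-D or 3-D array into tiles of `tileShape` on a regular
#' grid anchored at the origin; edge tiles are completed by reflect padding.
#' `untileImage` inverts the operation exactly on the original extent.
#'
#' @param x 2-D matrix or 3-D array.
#' @param tileShape integer vector, one entry per dimension of `x`.
#' @return `tileImage`: list with `tiles` (list of arrays) and `layout`
#'   (origin indices and original dimension, consumed by `untileImage`).
#' @examples
#' t <- tileImage(matrix(1:9e4, 300), c(256, 256))
#' length(t$tiles)  # 4
#' identical(untileImage(t$tiles, t$layout), matrix(1:9e4, 300))
#' @export
tileImage <- function(x, tileShape) {
  d <- dim(x)
  if (length(d) != length(tileShape))
    stop("tileShape must have one entry per dimension of x")
  if (any(tileShape < 1L)) stop("tile dimensions must be >= 1")
  nT <- pmax(1L, ceiling(d / tileShape))
  padded <- reflectPadTo(x, nT * tileShape)
  starts <- lapply(seq_along(d), function(k)
    (seq_len(nT[k]) - 1L) * tileShape[k] + 1L)
  grid <- expand.grid(lapply(rev(starts), identity))[, rev(seq_along(d)), drop = FALSE]
  tiles <- lapply(seq_len(nrow(grid)), function(i) {
    idx <- lapply(seq_along(d), function(k)
      grid[i, k] + seq_len(tileShape[k]) - 1L)
    do.call(`[`, c(list(padded), idx, list(drop = FALSE)))
  })
  tiles <- lapply(tiles, function(t) { dim(t) <- tileShape; t })
  list(tiles = tiles,
       layout = list(dim = d, paddedDim = nT * tileShape,
                     tileShape = tileShape, origins = as.matrix(grid)))
}

#' @rdname tileImage
#' @param tiles list of arrays from `tileImage`.
#' @param layout the `layout` record from `tileImage`.
#' @export
untileImage <- function(tiles, layout) {
  d <- layout$dim
  ts <- layout$tileShape
  out <- array(vector(typeof(tiles[[1L]]), 1L), dim = layout$paddedDim)
  for (i in seq_along(tiles)) {
    idx <- lapply(seq_along(d), function(k)
      layout$origins[i, k] + seq_len(ts[k]) - 1L)
    out <- do.call(`[<-`, c(list(out), idx, list(tiles[[i]])))
  }
  idx <- lapply(d, seq_len)
  out <- do.call(`[`, c(list(out), idx, list(drop = FALSE)))
  dim(out) <- d
  out
}

# Reflect-pad an array up to target dimensions (appends mirrored content).
reflectPadTo <- function(x, target) {
  d <- dim(x)
  for (k in seq_along(d)) {
    if (target[k] <= d[k]) next
    need <- target[k] - d[k]
    n <- dim(x)[k]
    src <- rev(seq_len(n))[seq_len(min(need, n))]
    if (length(src) < need) src <- rep_len(src, need)  # tiny inputs
    idx <- lapply(dim(x), seq_len)
    idx[[k]] <- src
    mirror <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    x <- abindAlong(x, mirror, k)
  }
  x
}

abindAlong <- function(a, b, along) {
  da <- dim(a); db <- dim(b)
  perm <- c(setdiff(seq_along(da), along), along)
  ap <- aperm(a, perm); bp <- aperm(b, perm)
  dim(ap) <- c(prod(da[perm[-length(perm)]]), da[along])
  dim(bp) <- c(prod(db[perm[-length(perm)]]), db[along])
  m <- cbind(ap, bp)
  dnew <- c(da[perm[-length(perm)]], da[along] + db[along])
  dim(m) <- dnew
  aperm(m, order(c(perm)))
}
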