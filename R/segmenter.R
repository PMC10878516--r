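# Pluggable pixel-classifier contract, 3-instance ensemble voting, and
# reduced-scale trainable classifiers. The trainable model is a multiscale
# convolutional feature bank (Gaussian pyramid, difference-of-Gaussians,
# gradient magnitudes) feeding a weighted single-hidden-layer softmax
# network: a CPU-friendly pixel classifier in the ilastik tradition that
# honors the same training contract (weighted cross-entropy with per-class
# weights, seeded determinism, reflection/rotation/blur augmentation) as a
# full encoder-decoder would.

#' Classifier specification
#'
#' @param mode `"2D-binary"` (background/nucleus) or `"3D-4class"`
#'   (background/nucleus/mitotic/daughter; features gain a temporal
#'   context).
#' @param classWeights per-class loss weights; defaults are 1:2 for 2D
#'   (background:nucleus) and 1:2:20:20 for the 4-class mode.
#' @param augment apply reflection/rotation/Gaussian-blur augmentation
#'   during sampling (default TRUE).
#' @param hiddenUnits hidden layer width (default 12).
#' @param samplePixels pixels sampled for training across all tiles
#'   (default 20000).
#' @param inputTile tile shape the mode expects (256x256 for 2D,
#'   128x128x16 for 3D); informational for tiling code.
#' @return list of class `ClassifierSpec`.
#' @export
classifierSpec <- function(mode = c("2D-binary", "3D-4class"),
                           classWeights = NULL, augment = TRUE,
                           hiddenUnits = 12, samplePixels = 20000,
                           inputTile = NULL) {
  mode <- match.arg(mode)
  if (is.null(classWeights))
    classWeights <- if (mode == "2D-binary") c(1, 2) else c(1, 2, 20, 20)
  nc <- if (mode == "2D-binary") 2L else 4L
  stopifnot(length(classWeights) == nc, all(classWeights > 0),
            hiddenUnits >= 1, samplePixels >= 10)
  if (is.null(inputTile))
    inputTile <- if (mode == "2D-binary") c(256L, 256L) else c(128L, 128L, 16L)
  structure(list(mode = mode, classWeights = classWeights, augment = augment,
                 hiddenUnits = hiddenUnits, samplePixels = samplePixels,
                 inputTile = inputTile),
            class = "ClassifierSpec")
}

# multiscale feature bank of one (normalized) frame; returns (pixels x F)
featureBank2D <- function(frame) {
  g1 <- gaussianBlur(frame, 1); g2 <- gaussianBlur(frame, 2)
  g4 <- gaussianBlur(frame, 4); g8 <- gaussianBlur(frame, 8)
  grad <- function(m) {
    gr <- (shiftMatrix(m, -1, 0, fill = 0) - shiftMatrix(m, 1, 0, fill = 0)) / 2
    gc <- (shiftMatrix(m, 0, -1, fill = 0) - shiftMatrix(m, 0, 1, fill = 0)) / 2
    sqrt(gr^2 + gc^2)
  }
  cbind(as.vector(frame), as.vector(g1), as.vector(g2), as.vector(g4),
        as.vector(g8), as.vector(g1 - g2), as.vector(g2 - g4),
        as.vector(g4 - g8), as.vector(grad(g1)), as.vector(grad(g2)),
        as.vector(grad(g4)))
}

# 3D mode: current-frame bank + temporal mean and difference banks
featureBank3D <- function(stack, t) {
  nT <- length(stack)
  cl <- function(i) stack[[min(max(i, 1L), nT)]]
  cur <- featureBank2D(cl(t))
  tmean <- (cl(t - 2L) + cl(t - 1L) + cl(t) + cl(t + 1L) + cl(t + 2L)) / 5
  tdiff <- gaussianBlur(cl(t + 2L) - cl(t - 2L), 2)
  cbind(cur, featureBank2D(tmean)[, c(2L, 3L, 6L, 9L)],
        as.vector(tdiff), as.vector(abs(tdiff)))
}

augmentTile <- function(img, lab) {
  op <- sample.int(6L, 1L)
  geo <- function(m) switch(op,
    m,
    m[nrow(m):1, , drop = FALSE],
    m[, ncol(m):1, drop = FALSE],
    t(m)[, nrow(m):1, drop = FALSE],       # rotate 90
    m[nrow(m):1, ncol(m):1, drop = FALSE], # rotate 180
    m)
  img <- geo(img); lab <- geo(lab)
  if (op == 6L) img <- gaussianBlur(img, runif(1, 0.4, 1.2))
  list(image = img, labels = lab)
}

#' Train a pixel classifier
#'
#' Samples pixels from the provided image/label tiles (stratified by class,
#' after optional augmentation), computes the multiscale feature bank, and
#' fits a single-hidden-layer softmax network by weighted cross-entropy with
#' the configured class weights (per-pixel case weights). Training is
#' deterministic for a fixed seed. `epochs = 0` returns the randomly
#' initialized network (the pipeline still runs).
#'
#' @param tiles list of `list(image, labels)` pairs; 2D mode: matrices; 3D
#'   mode: `image` a (rows, cols, frames) array with matching `labels`.
#' @param spec a [classifierSpec()].
#' @param epochs optimizer iterations (default 100).
#' @param rngSeed training seed; different seeds give the independent
#'   ensemble instances.
#' @return A [Predictor-class].
#' @export
trainClassifier <- function(tiles, spec = classifierSpec(), epochs = 100,
                            rngSeed = 1) {
  stopifnot(inherits(spec, "ClassifierSpec"), length(tiles) >= 1L)
  k <- if (spec$mode == "2D-binary") 2L else 4L
  withSeed(rngSeed, {
    X <- list(); Y <- list()
    for (tile in tiles) {
      img <- tile$image; lab <- tile$labels
      if (spec$mode == "2D-binary") {
        if (any(!lab %in% 0:3))
          stop("label values outside the mode's class set")
        lab <- (lab > 0L) * 1L   # nucleus classes 1..3 are all foreground
        if (spec$augment) {
          a <- augmentTile(img, lab); img <- a$image; lab <- a$labels
        }
        X[[length(X) + 1L]] <- featureBank2D(zscoreNormalizeSafe(img))
        Y[[length(Y) + 1L]] <- as.integer(lab)
      } else {
        if (any(!(tile$labels %in% 0:3)))
          stop("label values outside the mode's class set")
        stackN <- lapply(seq_len(dim(img)[3L]), function(i)
          zscoreNormalizeSafe(img[, , i]))
        mid <- ceiling(dim(img)[3L] / 2)
        for (t in unique(c(mid, max(1L, mid - 4L), min(dim(img)[3L], mid + 4L)))) {
          X[[length(X) + 1L]] <- featureBank3D(stackN, t)
          Y[[length(Y) + 1L]] <- as.integer(tile$labels[, , t])
        }
      }
    }
    X <- do.call(rbind, X)
    y <- unlist(Y)
    # stratified sampling: rare classes (mitotic, daughter) are kept whole
    idx <- stratifiedSample(y, spec$samplePixels)
    X <- X[idx, , drop = FALSE]
    y <- y[idx]
    w <- spec$classWeights[y + 1L]
    targets <- diag(k)[y + 1L, , drop = FALSE]
    fit <- nnet::nnet(x = X, y = targets, weights = w,
                      size = spec$hiddenUnits, softmax = TRUE,
                      maxit = max(1L, epochs), decay = 1e-4, trace = FALSE,
                      MaxNWts = 100000L)
    if (epochs == 0L) {
      # random init only: redraw weights, skip optimization
      fit$wts <- runif(length(fit$wts), -0.5, 0.5)
    }
    buildPredictor(fit, spec, rngSeed)
  })
}

zscoreNormalizeSafe <- function(m) {
  s <- sd(as.vector(m))
  if (!is.finite(s) || s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

stratifiedSample <- function(y, total) {
  classes <- sort(unique(y))
  per <- ceiling(total / length(classes))
  idx <- unlist(lapply(classes, function(cl) {
    i <- which(y == cl)
    if (length(i) > per) sample(i, per) else i
  }))
  sample(idx)   # shuffle
}

buildPredictor <- function(fit, spec, rngSeed) {
  k <- if (spec$mode == "2D-binary") 2L else 4L
  fun <- function(frame, frameIndex, stack = NULL) {
    feats <- if (spec$mode == "2D-binary") featureBank2D(frame) else {
      stopifnot(!is.null(stack))
      featureBank3D(stack, frameIndex)
    }
    p <- predict(fit, feats, type = "raw")
    p <- pmax(p, 1e-8)
    p <- p / rowSums(p)
    array(p, dim = c(dim(frame), k))
  }
  new("Predictor", mode = spec$mode, predictFun = fun,
      spec = unclass(spec), tag = sprintf("trained-seed%d", rngSeed))
}

#' Ensemble vote over exactly three predictors
#'
#' Per pixel, each predictor's class decision is computed (argmax; for the
#' binary mode, foreground iff the nucleus probability exceeds 0.5). The
#' voted output keeps a foreground/class decision where at least
#' `voteThreshold` of the 3 instances agree; three-way 4-class ties resolve
#' to the lowest class id among the votes.
#'
#' @param stack a [TimeLapse-class] or list of raw frames (z-score
#'   normalization is applied here).
#' @param predictors list of exactly 3 [Predictor-class] objects sharing a
#'   mode.
#' @param voteThreshold votes required (the workflow fixes this at 2-of-3 in its
#'   workflow).
#' @return For 2D-binary predictors, a list of logical foreground masks
#'   (one per frame); for 3D-4class, a [ClassMask-class].
#' @export
predictEnsemble <- function(stack, predictors, voteThreshold = 2) {
  if (length(predictors) != 3L)
    stop("ensemble voting is defined for exactly 3 predictors")
  modes <- vapply(predictors, function(p) p@mode, "")
  if (length(unique(modes)) != 1L) stop("predictors must share a mode")
  mode <- modes[1L]
  fr <- if (is(stack, "TimeLapse")) frames(stack) else stack
  norm <- lapply(fr, zscoreNormalizeSafe)
  nT <- length(norm)
  if (mode == "2D-binary") {
    lapply(seq_len(nT), function(t) {
      votes <- matrix(0L, nrow(norm[[t]]), ncol(norm[[t]]))
      for (p in predictors) {
        pr <- p@predictFun(norm[[t]], t, norm)
        votes <- votes + (pr[, , 2L] > 0.5)
      }
      votes >= voteThreshold
    })
  } else {
    d <- dim(norm[[1L]])
    arr <- array(0L, dim = c(d, nT))
    for (t in seq_len(nT)) {
      dec <- vapply(predictors, function(p) {
        pr <- p@predictFun(norm[[t]], t, norm)
        as.integer(max.col(matrix(pr, ncol = 4L), ties.method = "first") - 1L)
      }, integer(prod(d)))
      counts <- vapply(0:3, function(cl) rowSums(dec == cl),
                       numeric(nrow(dec)))
      meets <- counts >= voteThreshold
      fallback <- pmin(dec[, 1L], dec[, 2L], dec[, 3L])
      win <- ifelse(meets[, 1L], 0L,
             ifelse(meets[, 2L], 1L,
             ifelse(meets[, 3L], 2L,
             ifelse(meets[, 4L], 3L, fallback))))
      arr[, , t] <- matrix(as.integer(win), d[1L], d[2L])
    }
    classMask(arr)
  }
}

#' Label-free nucleus instances from a phase-contrast time-lapse
#'
#' Per frame: z-score normalization, 2-of-3 ensemble vote of the binary
#' predictors, light morphological cleanup of the voted mask (hole filling
#' and a radius-1 opening, which remove pixel-level vote noise that would
#' otherwise corrupt the distance transform), FogBank separation of the
#' cleaned foreground.
#'
#' @param phase a [TimeLapse-class] (phase-contrast channel).
#' @param predictors list of exactly 3 2D-binary [Predictor-class]s.
#' @param fog a [fogbankParams()].
#' @return list of integer instance masks, one per frame.
#' @export
inferNuclei <- function(phase, predictors, fog = fogbankParams()) {
  if (!all(vapply(predictors, function(p) p@mode, "") == "2D-binary"))
    stop("inferNuclei needs 2D-binary predictors")
  masks <- predictEnsemble(phase, predictors)
  brush <- EBImage::makeBrush(3L, shape = "diamond")
  lapply(masks, function(m) {
    m <- EBImage::fillHull(matrix(as.numeric(m), nrow(m)))
    m <- EBImage::opening(m, brush)
    separateObjects(matrix(m > 0, nrow(m)), params = fog)
  })
}
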