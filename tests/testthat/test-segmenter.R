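makeBinaryTiles <- function(sim, frameIdx) {
  ph <- frames(sim$phase)
  lapply(frameIdx, function(t)
    list(image = ph[[t]],
         labels = (classArray(sim$truth$classes)[, , t] > 0L) * 1L))
}

test_that("ensemble voting is a permutation-invariant 2-of-3 majority", {
  sim <- smallNoisySim()
  preds <- lapply(1:3, function(s) oracleClassifier(sim$truth, 0.1, s))
  stack <- list(frames(sim$phase)[[3]])
  wrap <- function(p) new("Predictor", mode = p@mode,
                          predictFun = function(fr, i, st = NULL)
                            p@predictFun(fr, 3), spec = list(), tag = p@tag)
  w <- lapply(preds, wrap)
  v1 <- predictEnsemble(stack, w)[[1]]
  v2 <- predictEnsemble(stack, w[c(3, 1, 2)])[[1]]
  expect_identical(v1, v2)

  # identical predictors: vote equals the single-predictor mask
  vSame <- predictEnsemble(stack, list(w[[1]], w[[1]], w[[1]]))[[1]]
  single <- preds[[1]]@predictFun(NULL, 3)[, , 2] > 0.5
  expect_identical(vSame, single)

  # A, A, B at every pixel: A's decision wins
  vAAB <- predictEnsemble(stack, list(w[[1]], w[[1]], w[[2]]))[[1]]
  expect_identical(vAAB, single)

  # voted foreground between intersection and union of individuals
  masks <- lapply(preds, function(p) p@predictFun(NULL, 3)[, , 2] > 0.5)
  voted <- predictEnsemble(stack, w)[[1]]
  expect_true(all(voted[masks[[1]] & masks[[2]] & masks[[3]]]))
  expect_true(!any(voted[!(masks[[1]] | masks[[2]] | masks[[3]])]))

  expect_error(predictEnsemble(stack, w[1:2]), "exactly 3")
})

test_that("4-class votes resolve ties toward the lower class id", {
  mk <- function(cls) {
    arr <- array(0.05, dim = c(2, 2, 4))
    for (i in 1:2) for (j in 1:2) arr[i, j, cls[i, j] + 1L] <- 0.85
    new("Predictor", mode = "3D-4class",
        predictFun = function(fr, t, st = NULL) arr, spec = list(), tag = "t")
  }
  p1 <- mk(matrix(c(1L, 2L, 3L, 0L), 2))
  p2 <- mk(matrix(c(1L, 2L, 1L, 2L), 2))
  p3 <- mk(matrix(c(1L, 3L, 2L, 1L), 2))
  out <- classArray(predictEnsemble(list(matrix(rnorm(4), 2)),
                                    list(p1, p2, p3)))[, , 1]
  expect_identical(out[1, 1], 1L)  # unanimous
  expect_identical(out[2, 1], 2L)  # majority 2
  expect_identical(out[1, 2], 1L)  # three-way tie 3/1/2 -> lowest
  expect_identical(out[2, 2], 0L)  # three-way tie 0/2/1 -> lowest
})

test_that("training is seeded, validates labels, and supports epoch 0", {
  sim <- smallNoisySim()
  tiles <- makeBinaryTiles(sim, 1:6)
  spec <- classifierSpec("2D-binary", hiddenUnits = 6, samplePixels = 3000)

  pA <- trainClassifier(tiles, spec, epochs = 15, rngSeed = 3)
  pB <- trainClassifier(tiles, spec, epochs = 15, rngSeed = 3)
  fr <- zscoreNormalize(frames(sim$phase)[[7]])
  expect_identical(pA@predictFun(fr, 7), pB@predictFun(fr, 7))

  p0 <- trainClassifier(tiles, spec, epochs = 0, rngSeed = 1)
  pr <- p0@predictFun(fr, 7)
  expect_equal(range(apply(pr, c(1, 2), sum)), c(1, 1), tolerance = 1e-5)

  bad <- tiles
  bad[[1]]$labels[1, 1] <- 7L
  expect_error(trainClassifier(bad, spec, epochs = 1), "class set")
})

test_that("raising the nucleus class weight raises foreground recall", {
  sim <- smallNoisySim()
  tiles <- makeBinaryTiles(sim, 1:6)
  val <- 8:10
  truthFg <- lapply(val, function(t) classArray(sim$truth$classes)[, , t] > 0L)
  recallAt <- function(wFg) {
    spec <- classifierSpec("2D-binary", classWeights = c(1, wFg),
                           hiddenUnits = 6, samplePixels = 3000,
                           augment = FALSE)
    p <- trainClassifier(tiles, spec, epochs = 25, rngSeed = 5)
    hits <- tot <- 0
    for (k in seq_along(val)) {
      fr <- zscoreNormalize(frames(sim$phase)[[val[k]]])
      fg <- p@predictFun(fr, val[k])[, , 2] > 0.5
      hits <- hits + sum(fg & truthFg[[k]])
      tot <- tot + sum(truthFg[[k]])
    }
    hits / tot
  }
  expect_gte(recallAt(4), recallAt(1))
})

test_that("4-class training runs on spatiotemporal tiles", {
  sim <- cachedFixture("stack16c", {
    simulateTimeLapse(simulationConfig(nCellsInitial = 10, nFrames = 16,
                                       imageShape = c(96, 96), rngSeed = 6))
  })
  img <- array(0, dim = c(96, 96, 16))
  for (t in 1:16) img[, , t] <- frames(sim$phase)[[t]]
  tiles <- list(list(image = img, labels = classArray(sim$truth$classes)))
  spec <- classifierSpec("3D-4class", hiddenUnits = 6, samplePixels = 4000)
  p <- trainClassifier(tiles, spec, epochs = 10, rngSeed = 2)
  norm <- lapply(1:16, function(t) zscoreNormalize(frames(sim$phase)[[t]]))
  pr <- p@predictFun(norm[[8]], 8, norm)
  expect_identical(dim(pr), c(96L, 96L, 4L))
  expect_equal(range(apply(pr, c(1, 2), sum)), c(1, 1), tolerance = 1e-5)
})

test_that("inferNuclei turns voted masks into instances", {
  sim <- smallNoisySim()
  preds <- lapply(1:3, function(s) oracleClassifier(sim$truth, 0, s))
  inst <- inferNuclei(timeLapse(frames(sim$phase)[1:5],
                                calibration = calibration()), preds)
  for (f in 1:5) {
    # perfect masks up to transiently overlapping (merged) nucleus pairs
    nTruth <- length(setdiff(unique(as.vector(sim$truth$instances[[f]])), 0L))
    expect_lte(abs(max(inst[[f]]) - nTruth), ceiling(0.1 * nTruth))
  }
  # an empty frame yields zero instances
  blankTruth <- sim$truth
  blankTruth$classes <- classMask(array(0L, dim = c(64, 64, 1)))
  pb <- lapply(1:3, function(s) oracleClassifier(blankTruth, 0, s))
  instB <- inferNuclei(timeLapse(matrix(rnorm(64^2), 64)), pb)
  expect_identical(max(instB[[1]]), 0L)
})
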