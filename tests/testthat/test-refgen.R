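test_that("segmentNuclei recovers well-separated noise-free nuclei", {
  sim <- simulateTimeLapse(simulationConfig(nCellsInitial = 5, nFrames = 1,
                                            imageShape = c(128, 128),
                                            noiseSd = 0, rngSeed = 9))
  inst <- segmentNuclei(frames(sim$fluor)[[1]])
  truthStats <- colonytrack:::objectStats(sim$truth$instances[[1]])
  segStats <- colonytrack:::objectStats(inst)
  expect_identical(nrow(segStats), nrow(truthStats))
  m <- matchObjects(sim$truth$instances[[1]], inst)
  expect_identical(m@FP + m@FN, 0L)
  expect_true(all(m@pairs$distance < 1))

  blank <- matrix(0, 64, 64)
  expect_identical(max(segmentNuclei(blank)), 0L)
})

test_that("overlapping nuclei split when separable, merge when coincident", {
  body <- function(centers) {
    m <- matrix(0, 64, 64)
    for (i in seq_len(nrow(centers)))
      m <- m + 0.6 * ellipseMask(c(64, 64), centers[i, , drop = FALSE], 7, 5)
    m
  }
  apart <- segmentNuclei(body(rbind(c(32, 24), c(32, 38))))
  expect_identical(max(apart), 2L)
  coincident <- segmentNuclei(body(rbind(c(32, 31), c(32, 32))))
  expect_identical(max(coincident), 1L)   # the documented merge failure mode
})

test_that("detectCondensed flags exactly the condensing instances", {
  sim <- smallCleanSim()
  cls <- classArray(sim$truth$classes)
  f2 <- which(apply(cls == 2L, 3, any))
  skip_if(length(f2) == 0)
  f <- f2[ceiling(length(f2) / 2)]
  inst <- sim$truth$instances[[f]]
  flagged <- detectCondensed(frames(sim$fluor)[[f]], inst)
  truth2 <- setdiff(unique(inst[cls[, , f] == 2L]), 0L)
  expect_setequal(flagged, truth2)

  # no condensing cells -> empty set
  f1 <- which(!apply(cls >= 2L, 3, any))[1]
  skip_if(is.na(f1))
  expect_length(detectCondensed(frames(sim$fluor)[[f1]],
                                sim$truth$instances[[f1]]), 0)

  # all cells condensing -> all ids (constructed frame: body + bright core)
  fr <- matrix(0, 80, 80)
  labs <- matrix(0L, 80, 80)
  for (i in 1:3) {
    ctr <- cbind(20 + 20 * (i - 1), 25 + 15 * (i - 1))
    m <- ellipseMask(c(80, 80), ctr, 7, 5)
    fr <- fr + 0.6 * m + 1.2 * ellipseMask(c(80, 80), ctr, 3, 2)
    labs[m > 0L] <- i
  }
  expect_setequal(detectCondensed(fr, labs), 1:3)
})

test_that("linkDaughters records true splits and ignores non-splits", {
  # frame A: one flagged mother + a bystander; frame B: two daughters +
  # bystander moved slightly
  instA <- ellipseLabels(c(80, 80), rbind(c(40, 30), c(40, 60)), c(7, 7), c(5, 5))
  instB <- ellipseLabels(c(80, 80), rbind(c(34, 30), c(46, 30), c(41, 60)),
                         c(4.5, 4.5, 7), c(4, 4, 5))
  ev <- linkDaughters(list(instA, instB), list(1L, integer()))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$frame, 2L)
  expect_identical(ev$mother, 1L)
  expect_setequal(c(ev$daughter1, ev$daughter2), c(1L, 2L))

  # flagged object that does not split -> no event
  ev0 <- linkDaughters(list(instA, instA), list(1L, integer()))
  expect_identical(nrow(ev0), 0L)

  # two simultaneous distant divisions -> two events, correctly paired
  mA <- ellipseLabels(c(120, 120), rbind(c(30, 30), c(90, 90)), 7, 5)
  mB <- ellipseLabels(c(120, 120),
                      rbind(c(24, 30), c(36, 30), c(84, 90), c(96, 90)),
                      4.5, 4)
  ev2 <- linkDaughters(list(mA, mB), list(c(1L, 2L), integer()))
  expect_identical(nrow(ev2), 2L)
  expect_setequal(ev2$mother, c(1L, 2L))
  d1 <- ev2[ev2$mother == 1L, ]
  expect_setequal(c(d1$daughter1, d1$daughter2), c(1L, 2L))
  d2 <- ev2[ev2$mother == 2L, ]
  expect_setequal(c(d2$daughter1, d2$daughter2), c(3L, 4L))
})

test_that("buildClassMasks paints the configured windows and nothing else", {
  # 20-frame stack, one static nucleus dividing at frame 10
  shape <- c(60, 60)
  inst <- vector("list", 20)
  for (t in 1:9) inst[[t]] <- ellipseLabels(shape, cbind(30, 30), 7, 5)
  for (t in 10:20) inst[[t]] <- ellipseLabels(shape,
                                              rbind(c(24, 30), c(36, 30)),
                                              4.5, 4)
  events <- data.frame(frame = 10L, mother = 1L, daughter1 = 1L,
                       daughter2 = 2L, row = 30, col = 30)
  cm <- classArray(buildClassMasks(inst, events))
  for (t in 1:20) {
    cl <- unique(as.vector(cm[, , t]))
    if (t %in% 5:9) expect_setequal(cl, c(0L, 2L))
    else if (t %in% 10:12) expect_setequal(cl, c(0L, 3L))
    else expect_setequal(cl, c(0L, 1L))
  }

  noEv <- buildClassMasks(inst, events[0, ])
  expect_true(all(classArray(noEv) %in% 0:1))
})

test_that("annotation-derived class masks agree voxelwise with the truth windows", {
  # Apply the window/chaining logic to truth instances with chain-detected
  # events: isolates the class-mask construction from segmentation-mask
  # geometry (the per-object erosion shrinks segmented instances, which the
  # voxelwise comparison would conflate with window errors).
  sim <- smallCleanSim()
  skip_if(nrow(sim$truth$events) == 0)
  ev <- sim$truth$events[, c("frame", "mother", "daughter1", "daughter2",
                             "row", "col")]
  cm <- classArray(buildClassMasks(sim$truth$instances, ev))
  truth <- classArray(sim$truth$classes)
  for (cl in 1:3) {
    inter <- sum(cm == cl & truth == cl)
    union <- sum(cm == cl | truth == cl)
    if (union > 0) expect_gte(inter / union, 0.95)
  }
})

test_that("training tiles keep geometry and class values", {
  sim <- cachedFixture("tinyStack16", {
    simulateTimeLapse(simulationConfig(nCellsInitial = 8, nFrames = 16,
                                       imageShape = c(128, 128), rngSeed = 2))
  })
  cm <- sim$truth$classes
  t2 <- makeTrainingTiles(sim$phase, cm, mode = "2D", tileShape = c(128L, 128L))
  expect_length(t2, 16L)
  expect_true(all(vapply(t2, function(p) all(p$labels %in% 0:3), TRUE)))

  t3 <- makeTrainingTiles(sim$phase, cm, mode = "3D",
                          tileShape = c(64L, 64L, 16L))
  expect_length(t3, 4L)
  expect_identical(dim(t3[[1]]$image), c(64L, 64L, 16L))
  expect_true(all(vapply(t3, function(p) all(p$labels %in% 0:3), TRUE)))

  short <- timeLapse(frames(sim$phase)[1:8])
  cmShort <- classMask(classArray(cm)[, , 1:8])
  expect_error(makeTrainingTiles(short, cmShort, mode = "3D"), "16 frames")
})
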