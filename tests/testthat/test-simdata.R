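test_that("identical seeds give bit-identical simulations", {
  cfg <- simulationConfig(nCellsInitial = 12, nFrames = 15, rngSeed = 7)
  a <- simulateTimeLapse(cfg)
  b <- simulateTimeLapse(cfg)
  expect_identical(frames(a$fluor), frames(b$fluor))
  expect_identical(frames(a$phase), frames(b$phase))
  expect_identical(a$truth$tracks, b$truth$tracks)
  expect_identical(a$truth$instances, b$truth$instances)
})

test_that("noise-free rendering thresholds exactly to the truth foreground", {
  s0 <- simulateTimeLapse(simulationConfig(nCellsInitial = 10, nFrames = 1,
                                           noiseSd = 0, rngSeed = 3))
  expect_identical(frames(s0$fluor)[[1]] > 0, s0$truth$instances[[1]] > 0L)
})

test_that("track conservation: each division removes one mother, adds two daughters", {
  sim <- smallCleanSim()
  truth <- sim$truth
  nInit <- length(unique(truth$tracks$track_id[truth$tracks$frame == 1]))
  for (f in c(30, 60, 90)) {
    nDiv <- sum(truth$events$frame <= f)
    nNow <- length(unique(truth$tracks$track_id[truth$tracks$frame == f]))
    expect_identical(nNow, nInit + nDiv)
  }
})

test_that("class windows have the configured temporal widths", {
  sim <- smallCleanSim()
  cls <- classArray(sim$truth$classes)
  ev <- sim$truth$events
  skip_if(nrow(ev) == 0)
  for (i in seq_len(nrow(ev))) {
    f <- ev$frame[i]
    # mother is class 2 in exactly the 5 frames preceding the division
    momFrames <- vapply(max(1, f - 6):(f - 1), function(t) {
      sel <- sim$truth$instances[[t]] == ev$mother[i]
      any(sel) && max(cls[, , t][sel]) == 2L
    }, TRUE)
    expect_identical(sum(momFrames), min(5L, f - 1L))
    # each daughter is class 3 in exactly the 3 frames from the division
    for (d in c(ev$daughter1[i], ev$daughter2[i])) {
      dFrames <- vapply(f:min(dim(cls)[3], f + 4), function(t) {
        sel <- sim$truth$instances[[t]] == d
        any(sel) && max(cls[, , t][sel]) == 3L
      }, TRUE)
      expect_identical(sum(dFrames), min(3L, dim(cls)[3] - f + 1L))
    }
  }
})

test_that("edge cells move more than interior cells when configured so", {
  sim <- smallCleanSim()
  tr <- sim$truth$tracks
  ctr <- c(mean(tr$row[tr$frame == 1]), mean(tr$col[tr$frame == 1]))
  disp <- do.call(rbind, lapply(split(tr, tr$track_id), function(d) {
    d <- d[order(d$frame), ]
    if (nrow(d) < 10) return(NULL)
    data.frame(step = sqrt(diff(d$row)^2 + diff(d$col)^2),
               dCtr = sqrt((d$row[-1] - ctr[1])^2 + (d$col[-1] - ctr[2])^2))
  }))
  edge <- disp$step[disp$dCtr > quantile(disp$dCtr, 0.75)]
  interior <- disp$step[disp$dCtr < quantile(disp$dCtr, 0.25)]
  expect_gt(sd(edge), sd(interior))
})

test_that("empirical censored interdivision mean matches the Monte-Carlo oracle", {
  # Frozen from an independent scalar simulation of the same birth/division
  # process (50 starting cells, truncated-normal lifetimes mean 15 h / sd
  # 3 h / lower bound 9 h, ages uniform at start, 24-h observation window):
  # expected mean of completed daughter lifetimes 14.19 h, run-to-run SD of
  # that mean 0.33 h. Right-censoring pulls the naive mean below the 15-h
  # distribution mean, which the oracle accounts for.
  sim <- cachedFixture("interdivSim", {
    simulateTimeLapse(simulationConfig(nCellsInitial = 50, nFrames = 721,
                                       noiseSd = 0, rngSeed = 21),
                      render = FALSE)
  })
  lg <- sim$truth$lineage
  birth <- c(stats::setNames(lg$frame, lg$daughter1),
             stats::setNames(lg$frame, lg$daughter2))
  own <- stats::setNames(lg$frame, lg$parent)
  done <- intersect(names(birth), names(own))
  lifetimes <- (own[done] - birth[done]) / 30   # hours at 2-min frames
  expect_gt(length(lifetimes), 5)
  expect_lt(abs(mean(lifetimes) - 14.19), 2 * 0.33)
})

test_that("oracle classifiers corrupt exactly the configured pixel fraction", {
  sim <- smallNoisySim()
  truth <- sim$truth
  arr <- classArray(truth$classes)

  p0 <- oracleClassifier(truth, flipRate = 0, rngSeed = 1, mode = "3D-4class")
  pr <- p0@predictFun(NULL, 5)
  dec <- apply(pr, c(1, 2), which.max) - 1L
  expect_identical(as.integer(dec), as.integer(arr[, , 5]))

  p1 <- oracleClassifier(truth, flipRate = 0.1, rngSeed = 2, mode = "3D-4class")
  dis <- mean({
    pr1 <- p1@predictFun(NULL, 5)
    (apply(pr1, c(1, 2), which.max) - 1L) != arr[, , 5]
  })
  n <- length(arr[, , 5])
  expect_lt(abs(dis - 0.1), 4 * sqrt(0.1 * 0.9 / n))
  # reproducible: same oracle, same frame, same corruption
  pr1b <- p1@predictFun(NULL, 5)
  expect_identical(pr1b, p1@predictFun(NULL, 5))
})

test_that("2-of-3 voting beats every individual oracle", {
  sim <- smallNoisySim()
  truth <- sim$truth
  arr <- (classArray(truth$classes)[, , 10] > 0L)
  preds <- lapply(1:3, function(s) oracleClassifier(truth, 0.1, s))
  indivErr <- vapply(preds, function(p) {
    pr <- p@predictFun(NULL, 10)
    mean((pr[, , 2] > 0.5) != arr)
  }, 0)
  voted <- predictEnsemble(list(frames(sim$phase)[[10]]),
                           lapply(preds, function(p) {
                             # rewire oracles to answer for frame 10 when
                             # queried for frame 1 of the 1-frame stack
                             new("Predictor", mode = p@mode,
                                 predictFun = function(fr, i, st = NULL)
                                   p@predictFun(fr, 10), spec = list(),
                                 tag = p@tag)
                           }))
  votedErr <- mean(voted[[1]] != arr)
  expect_true(all(votedErr < indivErr))
})

test_that("population simulator grows at the configured doubling time", {
  p <- simulatePopulation(nInitial = 2000, nFrames = 360, mode = "hazard",
                          doublingTimeH = 15, rngSeed = 4)
  # exponential fit over the whole series
  tH <- seq_len(360) / 30
  fit <- lm(log(p$counts) ~ tH)
  expect_lt(abs(log(2) / coef(fit)[2] - 15), 0.75)  # within 5%

  pa <- simulatePopulation(nInitial = 800, nFrames = 1440, mode = "age",
                           rngSeed = 5)
  cohort <- pa$lifetimesH[pa$lifetimeBirthFrames <= 1440 - 24 * 30]
  aTr <- (9 - 15) / 3
  truncMean <- 15 + 3 * dnorm(aTr) / (1 - pnorm(aTr))
  expect_lt(abs(mean(cohort) - truncMean), 2 * sd(cohort) / sqrt(length(cohort)) + 0.15)
})

test_that("a too-small image refuses the requested cell count", {
  expect_error(simulateTimeLapse(simulationConfig(nCellsInitial = 500,
                                                  nFrames = 1,
                                                  imageShape = c(48, 48),
                                                  rngSeed = 1)),
               "too small")
})
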