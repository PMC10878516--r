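test_that("matchObjects counts TP/FP/FN under the distance gate", {
  lab <- ellipseLabels(c(80, 80), rbind(c(20, 20), c(20, 60), c(60, 40)), 7, 5)
  m <- matchObjects(lab, lab)
  expect_identical(m@TP, 3L)
  expect_identical(m@FP + m@FN, 0L)
  expect_true(all(m@pairs$iou == 1))

  # 3 reference objects; test has 2 coincident and 1 shifted by 20 px
  ref <- ellipseLabels(c(100, 100), rbind(c(20, 20), c(20, 60), c(70, 40)), 7, 5)
  tst <- ellipseLabels(c(100, 100), rbind(c(20, 20), c(20, 60), c(70, 60)), 7, 5)
  m2 <- matchObjects(ref, tst)
  expect_identical(m2@TP, 2L)
  expect_identical(m2@FP, 1L)
  expect_identical(m2@FN, 1L)

  # role swap exchanges FP and FN, keeps TP
  m3 <- matchObjects(tst, ref)
  expect_identical(m3@TP, m2@TP)
  expect_identical(m3@FP, m2@FN)
  expect_identical(m3@FN, m2@FP)
})

test_that("matchObjects equals exhaustive matching on random centroid frames", {
  set.seed(11)
  cfgM <- matchConfig()
  for (rep in 1:25) {
    nR <- sample(2:5, 1); nT <- sample(2:5, 1)
    ref <- data.frame(id = seq_len(nR), area = 1L,
                      row = runif(nR, 5, 95), col = runif(nR, 5, 95))
    tst <- data.frame(id = seq_len(nT), area = 1L,
                      row = runif(nT, 5, 95), col = runif(nT, 5, 95))
    m <- matchObjects(ref, tst, cfgM)
    d <- sqrt(outer(ref$row, tst$row, "-")^2 + outer(ref$col, tst$col, "-")^2)
    cost <- d / cfgM$maxDistance + 1
    bf <- bruteForceMatch(cost, d > cfgM$maxDistance)
    expect_identical(m@TP, nrow(bf))
    if (nrow(bf)) {
      got <- m@pairs[order(m@pairs$ref), ]
      expect_equal(sum(cost[cbind(got$ref, got$test)]),
                   sum(cost[cbind(bf$row, bf$col)]), tolerance = 1e-9)
    }
  }
})

test_that("detection scores reproduce the worked mitosis-evaluation example", {
  m <- new("MatchResult", TP = 3164L, FP = 796L, FN = 1840L,
           pairs = data.frame(ref = seq_len(3164), test = seq_len(3164),
                              distance = 0, iou = 1))
  sc <- detectionScores(m)
  expect_equal(sc$F1, 2 * 3164 / (2 * 3164 + 1840 + 796))
  expect_equal(sc$F1, 0.70, tolerance = 0.01)
  expect_equal(sc$fractionAdditional, 796 / (3164 + 1840))
  expect_equal(sc$fractionMissing, 1840 / (3164 + 1840))

  one <- new("MatchResult", TP = 1L, FP = 0L, FN = 0L,
             pairs = data.frame(ref = 1L, test = 1L, distance = 0, iou = 1))
  expect_equal(detectionScores(one)$F1, 1)
  none <- new("MatchResult", TP = 0L, FP = 5L, FN = 5L,
              pairs = data.frame(ref = integer(), test = integer(),
                                 distance = numeric(), iou = numeric()))
  expect_equal(detectionScores(none)$F1, 0)
  zero <- new("MatchResult", TP = 0L, FP = 0L, FN = 0L,
              pairs = data.frame(ref = integer(), test = integer(),
                                 distance = numeric(), iou = numeric()))
  expect_error(detectionScores(zero), "undefined")

  # F1 identity with precision/recall on random counts
  set.seed(12)
  for (i in 1:10) {
    tp <- sample(1:500, 1); fp <- sample(0:200, 1); fn <- sample(0:200, 1)
    mm <- new("MatchResult", TP = tp, FP = fp, FN = fn,
              pairs = data.frame(ref = seq_len(tp), test = seq_len(tp),
                                 distance = 0, iou = 1))
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    expect_equal(detectionScores(mm)$F1, 2 * p * r / (p + r))
  }
})

test_that("mitosis matching enforces both spatial and temporal gates", {
  ev <- data.frame(row = c(10, 50, 90), col = c(10, 50, 90),
                   frame = c(5, 20, 40))
  m <- matchMitoses(ev, ev)
  expect_identical(m@TP, 3L)

  late <- ev; late$frame <- late$frame + 7
  m2 <- matchMitoses(ev, late)
  expect_identical(m2@TP, 0L)
  expect_identical(m2@FP, 3L)

  far <- ev; far$row <- far$row + 16
  expect_identical(matchMitoses(ev, far)@TP, 0L)

  # a detector dropping 30% of many events: recall near 0.7
  set.seed(13)
  n <- 400
  refBig <- data.frame(row = runif(n, 0, 5000), col = runif(n, 0, 5000),
                       frame = sample(1:500, n, TRUE))
  keep <- runif(n) > 0.3
  m3 <- matchMitoses(refBig, refBig[keep, ])
  recall <- m3@TP / n
  expect_lt(abs(recall - 0.7), 4 * sqrt(0.3 * 0.7 / n))
})

test_that("linkage errors count test-id changes along reference tracks", {
  fr <- 1:100
  ref <- data.frame(track_id = 1L, frame = fr, row = 50, col = 50 + 0.1 * fr)
  tst <- ref
  tst$track_id <- ifelse(fr <= 60, 101L, 102L)   # one id swap mid-track
  r <- linkageErrorRate(ref, tst)
  expect_identical(r$errors, 1L)
  expect_equal(r$rate, 0.01)

  same <- linkageErrorRate(ref, transform(ref, track_id = 7L))
  expect_identical(same$errors, 0L)
})

test_that("interdivision times convert lineage spans to hours", {
  lg <- data.frame(parent = c(1L, 2L), daughter1 = c(2L, 4L),
                   daughter2 = c(3L, 5L), frame = c(0L, 450L))
  ts <- new("TrackSet",
            tracks = data.frame(track_id = 1:5, frame = 1L, row = 0, col = 0,
                                area = 1L, parent_id = NA_integer_),
            lineage = lg)
  it <- interdivisionTimes(ts, calibration())
  expect_equal(it$hours, 15)
  expect_identical(it$nAbove, 1L)
  expect_identical(it$nBelow, 0L)

  empty <- new("TrackSet",
               tracks = data.frame(track_id = 1L, frame = 1L, row = 0, col = 0,
                                   area = 1L, parent_id = NA_integer_),
               lineage = lg[0, ])
  expect_length(interdivisionTimes(empty)$hours, 0)
})

test_that("doubling-time formulas invert exactly on closed-form inputs", {
  # N doubles over 15 h (450 frames at 2 min): DT = 15 h in every window
  counts <- round(100 * 2^(seq(0, 450) / 450))
  dt <- doublingTimeCounts(counts, windowFrames = 450)
  expect_equal(dt[1], 15, tolerance = 0.01)

  # mitosis count equal to the starting count over 1 h: DT = 1 h
  expect_equal(doublingTimeMitoses(100, 100, windowHours = 1), 1)
  # no growth -> NA marker, not an error
  expect_true(is.na(doublingTimeCounts(rep(50, 40), windowFrames = 30)[1]))
  expect_true(is.na(doublingTimeMitoses(100, 0, 1)))
  expect_error(doublingTimeMitoses(0, 5, 1), "positive")
})

test_that("mitosis rate windows count events and smooth as configured", {
  counts <- rep(100L, 120)
  expect_true(all(mitosisRate(integer(), counts) == 0))

  set.seed(14)
  evF <- sample(1:120, 300, TRUE)
  r30 <- mitosisRate(evF, counts, windowMinutes = 30, smoothFrames = 1)
  r60 <- mitosisRate(evF, counts, windowMinutes = 60, smoothFrames = 1)
  # doubling the window roughly doubles the raw counts
  overlap <- seq_len(min(length(r30), length(r60)))
  expect_lt(abs(mean(r60[overlap]) / mean(r30[overlap]) - 2), 0.3)
})

test_that("MSD matches closed forms and the random-walk expectation", {
  cal <- calibration(pixelArea = 0.406, frameInterval = 2)
  H <- 30
  still <- data.frame(track_id = 1L, frame = 1:60, row = 40, col = 40)
  expect_true(all(msd(still, cal)$msd == 0))

  v <- 0.5
  line <- data.frame(track_id = 1L, frame = 1:60, row = 40 + v * (1:60),
                     col = 10)
  got <- msd(line, cal)$msd[1]
  expect_equal(got, v^2 * mean((1:H)^2) * 0.406, tolerance = 1e-9)

  set.seed(15)
  sig <- 0.8
  walks <- do.call(rbind, lapply(1:60, function(id)
    data.frame(track_id = id, frame = 1:90,
               row = cumsum(rnorm(90, 0, sig)),
               col = cumsum(rnorm(90, 0, sig)))))
  mw <- msd(walks, cal)
  expected <- 2 * sig^2 * mean(1:H) * 0.406
  expect_lt(abs(mean(mw$msd) / expected - 1), 0.15)
})

test_that("edge-distance profiles recover geometry and flat metrics", {
  # a filled circular colony of nuclei; probe cells sit at known radii
  shape <- c(160, 160)
  ctr <- c(80, 80)
  grid <- expand.grid(r = seq(20, 140, 11), c = seq(20, 140, 11))
  keep <- sqrt((grid$r - ctr[1])^2 + (grid$c - ctr[2])^2) <= 60
  centers <- as.matrix(grid[keep, ])
  inst <- ellipseLabels(shape, centers, 5)
  radii <- c(0, 22, 44, 55)
  probes <- cbind(ctr[1] + radii, ctr[2])
  # colony spans to radius ~65; distance from edge ~ 65 - radius
  ms <- data.frame(frame = 1L, row = probes[, 1], col = probes[, 2],
                   value = 1)
  prof <- edgeDistanceProfile(list(inst), ms, calibration(1, 2),
                              binWidthUm = 10)
  expect_identical(sum(prof$n), 4)
  # uniform metric -> flat profile
  expect_true(all(prof$mean == 1))
  # probes closer to the colony center are farther from its edge
  dists <- vapply(seq_len(4), function(i) {
    pr <- edgeDistanceProfile(list(inst),
                              ms[i, , drop = FALSE], calibration(1, 2),
                              binWidthUm = 1)
    pr$bin[1]
  }, 0)
  expect_true(all(diff(dists) < 0))
})
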