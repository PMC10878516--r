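# Shared fixtures and independent oracles for the test suite.

# --- geometric fixtures -----------------------------------------------------

# binary mask with filled ellipses; centers: matrix (row, col), axes (a, b),
# theta per object
ellipseMask <- function(shape, centers, a, b = a, theta = 0) {
  m <- matrix(0L, shape[1L], shape[2L])
  a <- rep_len(a, nrow(centers)); b <- rep_len(b, nrow(centers))
  theta <- rep_len(theta, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    rows <- pmax(1, floor(centers[i, 1] - a[i])):pmin(shape[1], ceiling(centers[i, 1] + a[i]))
    cols <- pmax(1, floor(centers[i, 2] - a[i])):pmin(shape[2], ceiling(centers[i, 2] + a[i]))
    g <- expand.grid(r = rows, c = cols)
    dr <- g$r - centers[i, 1]; dc <- g$c - centers[i, 2]
    u <- dr * cos(theta[i]) + dc * sin(theta[i])
    v <- -dr * sin(theta[i]) + dc * cos(theta[i])
    inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
    m[cbind(g$r[inside], g$c[inside])] <- 1L
  }
  m
}

# labeled version: each ellipse its own label
ellipseLabels <- function(shape, centers, a, b = a, theta = 0) {
  out <- matrix(0L, shape[1L], shape[2L])
  for (i in seq_len(nrow(centers))) {
    m <- ellipseMask(shape, centers[i, , drop = FALSE],
                     rep_len(a, nrow(centers))[i], rep_len(b, nrow(centers))[i],
                     rep_len(theta, nrow(centers))[i])
    out[m > 0L & out == 0L] <- i
  }
  out
}

# --- brute-force assignment oracle -----------------------------------------

# exhaustive minimum-cost one-to-one matching with forbidden pairs;
# maximizes cardinality first, then minimizes total cost (mirrors the
# big-M construction). Feasible for <= 6 x 6.
bruteForceMatch <- function(cost, forbid = NULL) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (is.null(forbid)) forbid <- matrix(FALSE, nr, nc)
  best <- NULL; bestKey <- c(-1, Inf)
  cols <- seq_len(nc)
  subsets <- function(k) if (k == 0L) list(integer()) else utils::combn(cols, k, simplify = FALSE)
  for (k in seq(min(nr, nc), 0L)) {
    rowsets <- if (k == 0L) list(integer()) else utils::combn(seq_len(nr), k, simplify = FALSE)
    for (rs in rowsets) for (cs in subsets(k)) {
      if (k == 0L) {
        perms <- list(integer())
      } else {
        perms <- permutationsOf(cs)
      }
      for (p in perms) {
        ok <- k == 0L || all(!forbid[cbind(rs, p)])
        if (!ok) next
        tc <- if (k == 0L) 0 else sum(cost[cbind(rs, p)])
        key <- c(k, tc)
        if (key[1] > bestKey[1] ||
            (key[1] == bestKey[1] && key[2] < bestKey[2] - 1e-12)) {
          bestKey <- key
          best <- if (k == 0L) data.frame(row = integer(), col = integer())
                  else data.frame(row = rs, col = p)
        }
      }
    }
    if (!is.null(best) && bestKey[1] == k) break  # max cardinality found
  }
  best[order(best$row), , drop = FALSE]
}

permutationsOf <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutationsOf(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# --- cached simulations (heavy fixtures computed once per test run) ---------

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# moderate noise-free simulation with a handful of divisions
smallCleanSim <- function() cachedFixture("smallCleanSim", {
  simulateTimeLapse(simulationConfig(nCellsInitial = 25, nFrames = 90,
                                     noiseSd = 0, rngSeed = 11))
})

# same, with default noise (for oracle-classifier tests)
smallNoisySim <- function() cachedFixture("smallNoisySim", {
  simulateTimeLapse(simulationConfig(nCellsInitial = 25, nFrames = 50,
                                     rngSeed = 11))
})

# pooled detection scores over frames
pooledScores <- function(refList, testList, frames = seq_along(refList)) {
  tp <- fp <- fn <- 0L
  for (f in frames) {
    m <- matchObjects(refList[[f]], testList[[f]])
    tp <- tp + m@TP; fp <- fp + m@FP; fn <- fn + m@FN
  }
  list(F1 = 2 * tp / (2 * tp + fn + fp), TP = tp, FP = fp, FN = fn)
}

truthCountsPerFrame <- function(truth, nFrames) {
  vapply(seq_len(nFrames), function(f)
    length(unique(truth$tracks$track_id[truth$tracks$frame == f])), 0L)
}

# --- parameter-sweep fixture ------------------------------------------------
# Frames of paper-scale touching nucleus pairs plus singles, small genuine
# objects (debris-scale nuclei, in the reference) and sub-nucleus specks
# (not in the reference). Low minimum sizes keep the specks (false
# positives), high minimum sizes drop the small genuine objects (false
# negatives), so the F1 surface peaks at intermediate minimum sizes.
makeSweepFixture <- function(seed = 1, nFrames = 3) {
  set.seed(seed)
  masks <- list(); refs <- list()
  for (f in seq_len(nFrames)) {
    shape <- c(200, 200)
    ref <- matrix(0L, shape[1], shape[2])
    nid <- 0L
    add <- function(centers, a, b = a, theta = 0) {
      for (i in seq_len(nrow(centers))) {
        m <- ellipseMask(shape, centers[i, , drop = FALSE], a, b, theta)
        nid <<- nid + 1L
        ref[m > 0L & ref == 0L] <<- nid
      }
    }
    # six touching pairs on a grid
    anchors <- expand.grid(r = c(35, 100, 165), c = c(45, 145))
    for (k in seq_len(nrow(anchors)))
      add(rbind(c(anchors$r[k], anchors$c[k]),
                c(anchors$r[k], anchors$c[k] + 15)), 8)
    # four isolated singles
    add(cbind(c(35, 100, 165, 100), c(95, 95, 95, 190)), 8)
    # three small genuine objects (area ~13 px)
    add(cbind(c(65, 135, 20), c(20, 190, 160)), 2)
    mask <- (ref > 0L) * 1L
    # specks of area 4..8, placed in free corners
    sp <- cbind(r = sample(seq(8, 192, 4), 8), c = sample(seq(8, 192, 4), 8))
    for (i in seq_len(nrow(sp))) {
      box <- mask[max(1, sp[i, 1] - 12):min(200, sp[i, 1] + 12),
                  max(1, sp[i, 2] - 12):min(200, sp[i, 2] + 12)]
      if (any(box > 0)) next
      n <- sample(4:8, 1)
      px <- cbind(sp[i, 1] + c(0, 1, 0, 1, 2, 2, 0, 1)[1:n],
                  sp[i, 2] + c(0, 0, 1, 1, 0, 1, 2, 2)[1:n])
      mask[px] <- 1L
    }
    masks[[f]] <- mask
    refs[[f]] <- ref
  }
  list(masks = masks, refs = refs)
}
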