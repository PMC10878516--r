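# Synthetic paired fluorescence/phase-like time-lapses with complete ground
# truth. The generator emulates the statistical structure the pipeline
# assumes: elliptical nuclei packed in colonies imaged at 2-minute
# intervals, Brownian-like motion that is stronger at colony edges,
# truncated-normal interdivision times (median ~15 h, plausibility band
# 9-24 h), a condensed-DNA brightening during the frames preceding division,
# two daughter nuclei afterwards, and additive Gaussian background noise.
# The phase-like channel is a deterministic edge-enhanced low-contrast
# rendering of the same scene plus its own noise.

#' Configuration of the synthetic time-lapse generator
#'
#' Defaults are the generator's study conditions; see the methods vignette
#' for the rationale behind each value.
#'
#' @param nCellsInitial number of cells at frame 1.
#' @param nFrames number of frames.
#' @param frameIntervalMin minutes per frame (default 2).
#' @param imageShape c(rows, cols) in pixels.
#' @param nucleusRadii c(min, max) semi-axis lengths in pixels.
#' @param motilitySigmaEdge per-frame, per-axis displacement SD (px) at the
#'   colony edge.
#' @param motilitySigmaInterior same, deep inside the colony.
#' @param interdivisionMeanH,interdivisionSdH mean and SD (hours) of the
#'   truncated-normal interdivision time (defaults 15 and 3).
#' @param interdivisionMinH lower truncation bound in hours (default 9, the
#'   lower edge of the biologically plausible band).
#' @param condensationFramesBefore frames of condensed-DNA brightening
#'   before division (default 5).
#' @param daughterFramesAfter frames a newborn nucleus is flagged as a
#'   daughter (default 3).
#' @param noiseSd additive Gaussian noise SD in intensity units (nucleus
#'   body renders at 0.6, condensed core at 1.2).
#' @param deathRate per-cell, per-frame removal probability (default 0);
#'   nonzero values let count-based and mitosis-based growth estimates
#'   diverge.
#' @param nColonies number of colony clusters.
#' @param rngSeed integer seed fixing all randomness.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nCellsInitial = 50, nFrames = 360,
                             frameIntervalMin = 2,
                             imageShape = c(256, 256),
                             nucleusRadii = c(4, 7),
                             motilitySigmaEdge = 1.0,
                             motilitySigmaInterior = 0.4,
                             interdivisionMeanH = 15,
                             interdivisionSdH = 3,
                             interdivisionMinH = 9,
                             condensationFramesBefore = 5,
                             daughterFramesAfter = 3,
                             noiseSd = 0.02,
                             deathRate = 0,
                             nColonies = 1,
                             rngSeed = 1) {
  stopifnot(nCellsInitial >= 1, nFrames >= 1, frameIntervalMin > 0,
            length(imageShape) == 2L, all(imageShape >= 32),
            length(nucleusRadii) == 2L, nucleusRadii[1L] >= 1,
            nucleusRadii[2L] >= nucleusRadii[1L],
            motilitySigmaEdge >= 0, motilitySigmaInterior >= 0,
            interdivisionMeanH >= 9, interdivisionMeanH <= 24,
            interdivisionSdH > 0, interdivisionMinH > 0,
            condensationFramesBefore >= 1, daughterFramesAfter >= 1,
            noiseSd >= 0, deathRate >= 0, deathRate < 1, nColonies >= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

# truncated normal (lower bound only), in hours
rtruncnormLower <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# pixel set of an ellipse; returns cbind(idx, d2) with d2 the normalized
# squared elliptical radius (<= 1 inside)
ellipsePixels <- function(row, col, a, b, theta, shape) {
  rmax <- ceiling(max(a, b))
  rs <- max(1L, floor(row - rmax)):min(shape[1L], ceiling(row + rmax))
  cs <- max(1L, floor(col - rmax)):min(shape[2L], ceiling(col + rmax))
  if (length(rs) == 0L || length(cs) == 0L) return(NULL)
  g <- expand.grid(r = rs, c = cs)
  dr <- g$r - row; dc <- g$c - col
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  d2 <- (u / a)^2 + (v / b)^2
  keep <- d2 <= 1
  if (!any(keep)) return(NULL)
  cbind(idx = (g$c[keep] - 1L) * shape[1L] + g$r[keep], d2 = d2[keep])
}

#' Simulate a paired fluorescence / phase-like time-lapse with ground truth
#'
#' @param config a [simulationConfig()].
#' @param render if `FALSE`, skip image rendering and return truth only
#'   (fast path for population-scale statistics).
#' @return list with elements `fluor` and `phase` ([TimeLapse-class]; `NULL`
#'   when `render = FALSE`) and `truth`, a list with:
#'   \describe{
#'     \item{instances}{per-frame integer instance masks, label = track id}
#'     \item{classes}{a [ClassMask-class] over (rows, cols, frames)}
#'     \item{tracks}{data.frame track_id, frame, row, col, class, parent_id}
#'     \item{lineage}{data.frame parent, daughter1, daughter2, frame}
#'     \item{events}{data.frame event_id, row, col, frame (division events)}
#'     \item{config}{the configuration used}
#'   }
#' @export
simulateTimeLapse <- function(config = simulationConfig(), render = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$rngSeed, simulateTimeLapseImpl(config, render))
}

simulateTimeLapseImpl <- function(cfg, render) {
  shape <- cfg$imageShape
  fph <- 60 / cfg$frameIntervalMin          # frames per hour
  margin <- cfg$nucleusRadii[2L] + 2

  # --- colony layout and initial placement (non-overlapping at birth) ----
  colR <- sqrt(cfg$nCellsInitial / cfg$nColonies) *
    mean(cfg$nucleusRadii) * 1.9 + 8
  if (2 * (colR + margin) > min(shape) * 1.05 && cfg$nColonies == 1 &&
      cfg$nCellsInitial * pi * mean(cfg$nucleusRadii)^2 * 4 > prod(shape))
    stop("image too small to place the requested number of cells")
  centers <- cbind(
    row = runif(cfg$nColonies, margin + colR * 0.7, shape[1L] - margin - colR * 0.7),
    col = runif(cfg$nColonies, margin + colR * 0.7, shape[2L] - margin - colR * 0.7))
  if (cfg$nColonies == 1)
    centers <- cbind(row = shape[1L] / 2, col = shape[2L] / 2)

  cells <- data.frame(id = integer(), colony = integer(), row = numeric(),
                      col = numeric(), a = numeric(), b = numeric(),
                      theta = numeric(), birth = integer(), divFrame = integer(),
                      parent = integer())
  nextId <- 1L
  for (i in seq_len(cfg$nCellsInitial)) {
    colony <- ((i - 1L) %% cfg$nColonies) + 1L
    placed <- FALSE
    for (try in 1:400) {
      rad <- runif(1, 0, colR) ; ang <- runif(1, 0, 2 * pi)
      r <- centers[colony, 1L] + rad * cos(ang)
      c <- centers[colony, 2L] + rad * sin(ang)
      r <- min(max(r, margin), shape[1L] - margin)
      c <- min(max(c, margin), shape[2L] - margin)
      ab <- sort(runif(2, cfg$nucleusRadii[1L], cfg$nucleusRadii[2L]),
                 decreasing = TRUE)
      if (nrow(cells) == 0L ||
          all((cells$row - r)^2 + (cells$col - c)^2 >
              (cells$a + ab[1L] + 0.5)^2)) {
        Ti <- rtruncnormLower(1, cfg$interdivisionMeanH, cfg$interdivisionSdH,
                              cfg$interdivisionMinH)
        age0 <- runif(1, 0, Ti)
        cells <- rbind(cells, data.frame(
          id = nextId, colony = colony, row = r, col = c,
          a = ab[1L], b = ab[2L], theta = runif(1, 0, pi),
          birth = 1L, divFrame = max(2L, as.integer(round((Ti - age0) * fph))),
          parent = NA_integer_))
        nextId <- nextId + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("image too small to place the requested number of cells")
  }

  trackRows <- vector("list", cfg$nFrames)
  events <- data.frame(event_id = integer(), row = numeric(), col = numeric(),
                       frame = integer(), mother = integer(),
                       daughter1 = integer(), daughter2 = integer(),
                       seed1_row = numeric(), seed1_col = numeric(),
                       seed2_row = numeric(), seed2_col = numeric())
  lineageRows <- list()
  instances <- vector("list", cfg$nFrames)
  classes <- array(0L, dim = c(shape, cfg$nFrames))
  sceneStore <- if (render) vector("list", cfg$nFrames) else NULL
  eventId <- 1L

  for (t in seq_len(cfg$nFrames)) {
    # --- divisions scheduled for this frame -----------------------------
    dividing <- which(cells$divFrame == t)
    for (k in dividing) {
      mother <- cells[k, ]
      # daughters start small-ish, just separated along the mother's axis
      dr <- c(cfg$nucleusRadii[1L],
              cfg$nucleusRadii[1L] + 0.5 * diff(cfg$nucleusRadii))
      d <- lapply(c(-1, 1), function(s) {
        ab <- sort(runif(2, dr[1L], dr[2L]), decreasing = TRUE)
        Ti <- rtruncnormLower(1, cfg$interdivisionMeanH, cfg$interdivisionSdH,
                              cfg$interdivisionMinH)
        off <- ab[1L] + 0.8
        data.frame(id = NA_integer_, colony = mother$colony,
                   row = min(max(mother$row + s * off * cos(mother$theta),
                                 margin), shape[1L] - margin),
                   col = min(max(mother$col + s * off * sin(mother$theta),
                                 margin), shape[2L] - margin),
                   a = ab[1L], b = ab[2L],
                   theta = mother$theta + runif(1, -0.3, 0.3),
                   birth = t, divFrame = t + as.integer(round(Ti * fph)),
                   parent = mother$id)
      })
      d[[1L]]$id <- nextId; d[[2L]]$id <- nextId + 1L
      nextId <- nextId + 2L
      events <- rbind(events, data.frame(
        event_id = eventId, row = mother$row, col = mother$col, frame = t,
        mother = mother$id, daughter1 = d[[1L]]$id, daughter2 = d[[2L]]$id,
        seed1_row = d[[1L]]$row, seed1_col = d[[1L]]$col,
        seed2_row = d[[2L]]$row, seed2_col = d[[2L]]$col))
      lineageRows[[length(lineageRows) + 1L]] <- data.frame(
        parent = mother$id, daughter1 = d[[1L]]$id, daughter2 = d[[2L]]$id,
        frame = t)
      eventId <- eventId + 1L
      cells <- rbind(cells, d[[1L]], d[[2L]])
    }
    if (length(dividing)) cells <- cells[-dividing, ]

    # --- random death ----------------------------------------------------
    if (cfg$deathRate > 0 && nrow(cells)) {
      die <- runif(nrow(cells)) < cfg$deathRate
      if (any(die)) cells <- cells[!die, ]
    }
    cells <- cells[order(cells$id), ]

    # --- motion: edge cells move more -----------------------------------
    if (nrow(cells)) {
      for (colony in unique(cells$colony)) {
        sel <- cells$colony == colony
        ctr <- c(mean(cells$row[sel]), mean(cells$col[sel]))
        dctr <- sqrt((cells$row[sel] - ctr[1L])^2 + (cells$col[sel] - ctr[2L])^2)
        rim <- max(dctr) + mean(cfg$nucleusRadii)
        dEdge <- pmax(0, rim - dctr)
        sig <- cfg$motilitySigmaInterior +
          (cfg$motilitySigmaEdge - cfg$motilitySigmaInterior) *
          exp(-dEdge / 20)
        n <- sum(sel)
        cells$row[sel] <- cells$row[sel] + rnorm(n, 0, sig)
        cells$col[sel] <- cells$col[sel] + rnorm(n, 0, sig)
      }
      cells$row <- pmin(pmax(cells$row, margin), shape[1L] - margin)
      cells$col <- pmin(pmax(cells$col, margin), shape[2L] - margin)
      # soft excluded volume: nuclei in a packed colony cannot interpenetrate
      # deeply; overlapping pairs relax apart (overlaps remain transient)
      for (pass in 1:2) {
        n <- nrow(cells)
        if (n < 2L) break
        dr <- outer(cells$row, cells$row, "-")
        dc <- outer(cells$col, cells$col, "-")
        dist <- sqrt(dr^2 + dc^2)
        rad <- (cells$a + cells$b) / 2
        # nuclei are separated by non-fluorescent cytoplasm: relax to just
        # beyond contact so the label image keeps inter-nucleus gaps
        minsep <- 1.05 * outer(rad, rad, "+")
        bad <- which(dist < minsep & upper.tri(dist), arr.ind = TRUE)
        if (nrow(bad) == 0L) break
        for (q in seq_len(nrow(bad))) {
          i <- bad[q, 1L]; j <- bad[q, 2L]
          v <- c(cells$row[j] - cells$row[i], cells$col[j] - cells$col[i])
          dn <- sqrt(sum(v^2))
          if (dn < 1e-6) v <- c(1, 0) else v <- v / dn
          push <- (minsep[i, j] - dn) / 2
          cells$row[i] <- cells$row[i] - v[1L] * push
          cells$col[i] <- cells$col[i] - v[2L] * push
          cells$row[j] <- cells$row[j] + v[1L] * push
          cells$col[j] <- cells$col[j] + v[2L] * push
        }
        cells$row <- pmin(pmax(cells$row, margin), shape[1L] - margin)
        cells$col <- pmin(pmax(cells$col, margin), shape[2L] - margin)
      }
    }

    # --- rasterize truth -------------------------------------------------
    inst <- matrix(0L, shape[1L], shape[2L])
    best <- matrix(Inf, shape[1L], shape[2L])
    cls <- matrix(0L, shape[1L], shape[2L])
    scene <- if (render) matrix(0, shape[1L], shape[2L]) else NULL
    cellClass <- rep(1L, nrow(cells))
    if (nrow(cells)) {
      toDiv <- cells$divFrame - t
      cellClass[toDiv >= 1L & toDiv <= cfg$condensationFramesBefore] <- 2L
      cellClass[!is.na(cells$parent) &
                t - cells$birth <= cfg$daughterFramesAfter - 1L] <- 3L
    }
    if (nrow(cells)) for (k in seq_len(nrow(cells))) {
      cc <- cells[k, ]
      px <- ellipsePixels(cc$row, cc$col, cc$a, cc$b, cc$theta, shape)
      if (is.null(px)) next
      idx <- px[, "idx"]; d2 <- px[, "d2"]
      win <- d2 < best[idx]
      ii <- idx[win]
      inst[ii] <- cc$id
      cls[ii] <- cellClass[k]
      best[ii] <- d2[win]
      if (render) {
        scene[idx] <- scene[idx] + 0.6
        if (cellClass[k] == 2L) {
          # condensation packs the chromatin into ~1/5 the area; conserved
          # fluorophore mass makes the core ~3x the interphase body level
          core <- ellipsePixels(cc$row, cc$col, cc$a * 0.45, cc$b * 0.45,
                                cc$theta, shape)
          if (!is.null(core))
            scene[core[, "idx"]] <- scene[core[, "idx"]] + 1.2
        }
      }
    }
    instances[[t]] <- inst
    classes[, , t] <- cls
    if (render) sceneStore[[t]] <- scene
    if (nrow(cells))
      trackRows[[t]] <- data.frame(track_id = cells$id, frame = t,
                                   row = cells$row, col = cells$col,
                                   class = cellClass,
                                   parent_id = cells$parent)
  }

  # --- render channels ----------------------------------------------------
  fluor <- phase <- NULL
  cal <- calibration(frameInterval = cfg$frameIntervalMin)
  if (render) {
    fluorFrames <- lapply(sceneStore, function(s)
      s + if (cfg$noiseSd > 0) matrix(rnorm(length(s), 0, cfg$noiseSd),
                                      nrow(s)) else 0)
    phaseFrames <- lapply(sceneStore, function(s) {
      sm <- gaussianBlur(s, 1)
      gradR <- (shiftMatrix(sm, -1, 0, fill = 0) - shiftMatrix(sm, 1, 0, fill = 0)) / 2
      gradC <- (shiftMatrix(sm, 0, -1, fill = 0) - shiftMatrix(sm, 0, 1, fill = 0)) / 2
      p <- 0.5 - 0.22 * sm + 0.55 * sqrt(gradR^2 + gradC^2)
      p + if (cfg$noiseSd > 0) matrix(rnorm(length(p), 0, cfg$noiseSd),
                                      nrow(p)) else 0
    })
    fluor <- timeLapse(fluorFrames, calibration = cal)
    phase <- timeLapse(phaseFrames, calibration = cal)
  }

  tracksDf <- do.call(rbind, trackRows)
  rownames(tracksDf) <- NULL
  lineageDf <- if (length(lineageRows)) do.call(rbind, lineageRows) else
    data.frame(parent = integer(), daughter1 = integer(),
               daughter2 = integer(), frame = integer())
  list(fluor = fluor, phase = phase,
       truth = list(instances = instances, classes = classMask(classes),
                    tracks = tracksDf, lineage = lineageDf, events = events,
                    config = cfg, calibration = cal))
}

# Gaussian blur via EBImage; kernel clamped to the image size so small
# frames can be filtered at large scales.
gaussianBlur <- function(m, sigma) {
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  maxOdd <- min(dim(m)) - 1L
  if (maxOdd %% 2L == 0L) maxOdd <- maxOdd - 1L
  radius <- min(radius, max(3L, maxOdd))
  f <- EBImage::gblur(matrix(as.numeric(m), nrow(m)), sigma = sigma,
                      radius = radius)
  matrix(as.numeric(f), nrow(m))
}

#' Ground-truth-driven oracle classifier
#'
#' Builds a [Predictor-class] whose output argmaxes to the simulation's true
#' class mask except at a reproducibly chosen `flipRate` fraction of pixels,
#' where a uniformly drawn wrong class is reported. This exercises ensemble
#' voting, post-processing and tracking without any training.
#'
#' @param truth the `truth` element of [simulateTimeLapse()].
#' @param flipRate per-pixel corruption probability in [0, 0.5).
#' @param rngSeed seed identifying the oracle instance.
#' @param mode `"2D-binary"` (nucleus vs background) or `"3D-4class"`.
#' @return A [Predictor-class].
#' @export
oracleClassifier <- function(truth, flipRate = 0, rngSeed = 1,
                             mode = c("2D-binary", "3D-4class")) {
  mode <- match.arg(mode)
  stopifnot(flipRate >= 0, flipRate < 0.5)
  arr <- classArray(truth$classes)
  k <- if (mode == "2D-binary") 2L else 4L
  force(rngSeed); force(flipRate)
  fun <- function(frame, frameIndex, stack = NULL) {
    cls <- arr[, , frameIndex]
    if (mode == "2D-binary") cls <- (cls > 0L) * 1L
    if (flipRate > 0) {
      cls <- withSeed(rngSeed * 131071 + frameIndex, {
        n <- length(cls)
        flip <- runif(n) < flipRate
        wrong <- (cls + sample.int(k - 1L, n, replace = TRUE)) %% k
        ifelse(flip, wrong, cls)
      })
      cls <- matrix(as.integer(cls), nrow(arr[, , frameIndex]))
    }
    probs <- array(0.15 / (k - 1L), dim = c(dim(cls), k))
    for (cl in 0:(k - 1L)) {
      sel <- cls == cl
      pk <- probs[, , cl + 1L]
      pk[sel] <- 0.85
      probs[, , cl + 1L] <- pk
    }
    probs
  }
  new("Predictor", mode = mode, predictFun = fun, spec = list(),
      tag = sprintf("oracle-seed%d-flip%.3g", rngSeed, flipRate))
}

#' Birth-death population simulator (no imaging)
#'
#' A lightweight companion to [simulateTimeLapse()] for population-scale
#' statistics: no images or positions, just per-frame cell counts, division
#' events and completed lifetimes.
#'
#' @param nInitial starting cell count.
#' @param nFrames frames to simulate.
#' @param frameIntervalMin minutes per frame.
#' @param mode `"hazard"`: every cell divides with constant per-frame
#'   probability `log(2) / (doublingTimeH * framesPerHour)`, giving exact
#'   exponential growth with the configured doubling time. `"age"`: each
#'   cell divides at a truncated-normal age (the [simulateTimeLapse()]
#'   interdivision model).
#' @param doublingTimeH doubling time in hours (hazard mode).
#' @param interdivisionMeanH,interdivisionSdH,interdivisionMinH age-mode
#'   lifetime distribution (hours).
#' @param deathRate per-cell per-frame death probability.
#' @param rngSeed seed.
#' @return list with `counts` (per-frame cell count), `mitoses` (divisions
#'   per frame), `deaths` (removals per frame), `lifetimesH` (completed
#'   interdivision times in hours; age mode only), `lifetimeBirthFrames`
#'   (birth frame of each completed lifetime, for cohort restriction in
#'   growing cultures where completed lifetimes are censor-biased) and the
#'   arguments.
#' @export
simulatePopulation <- function(nInitial = 1000, nFrames = 360,
                               frameIntervalMin = 2,
                               mode = c("hazard", "age"),
                               doublingTimeH = 15,
                               interdivisionMeanH = 15, interdivisionSdH = 3,
                               interdivisionMinH = 9,
                               deathRate = 0, rngSeed = 1) {
  mode <- match.arg(mode)
  fph <- 60 / frameIntervalMin
  withSeed(rngSeed, {
    counts <- integer(nFrames)
    mit <- integer(nFrames)
    dth <- integer(nFrames)
    lifetimes <- numeric()
    if (mode == "hazard") {
      p <- log(2) / (doublingTimeH * fph)
      n <- nInitial
      for (t in seq_len(nFrames)) {
        divs <- rbinom(1L, n, p)
        dies <- rbinom(1L, n - divs, deathRate)
        n <- n + divs - dies
        counts[t] <- n; mit[t] <- divs; dth[t] <- dies
      }
    } else {
      Ti <- rtruncnormLower(nInitial, interdivisionMeanH, interdivisionSdH,
                            interdivisionMinH)
      age <- runif(nInitial, 0, Ti)      # cells mid-cycle at start
      born <- rep(NA_real_, nInitial)    # birth frame (NA: pre-existing)
      birthFrames <- numeric()
      for (t in seq_len(nFrames)) {
        age <- age + 1 / fph
        div <- which(age >= Ti)
        mit[t] <- length(div)
        if (length(div)) {
          done <- !is.na(born[div])
          lifetimes <- c(lifetimes, (t - born[div][done]) / fph)
          birthFrames <- c(birthFrames, born[div][done])
          nd <- 2L * length(div)
          Ti <- c(Ti[-div], rtruncnormLower(nd, interdivisionMeanH,
                                            interdivisionSdH,
                                            interdivisionMinH))
          age <- c(age[-div], rep(0, nd))
          born <- c(born[-div], rep(t, nd))
        }
        if (deathRate > 0 && length(Ti)) {
          die <- runif(length(Ti)) < deathRate
          dth[t] <- sum(die)
          if (any(die)) { Ti <- Ti[!die]; age <- age[!die]; born <- born[!die] }
        }
        counts[t] <- length(Ti)
      }
    }
    if (mode == "hazard") birthFrames <- numeric()
    list(counts = counts, mitoses = mit, deaths = dth, lifetimesH = lifetimes,
         lifetimeBirthFrames = birthFrames,
         nInitial = nInitial, frameIntervalMin = frameIntervalMin,
         mode = mode, doublingTimeH = doublingTimeH, deathRate = deathRate)
  })
}
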