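# Assignment-based evaluation (detection, mitosis, tracking) and biological
# dynamics statistics (mitosis rates, doubling times, interdivision times,
# MSD, distance-from-colony-edge profiles).

#' Matching configuration
#'
#' @param maxDistance spatial gate in pixels between matched objects
#'   (default 15).
#' @param maxTimeOffset temporal gate in frames, used by [matchMitoses()]
#'   only (default 6).
#' @return list of class `MatchConfig`.
#' @export
matchConfig <- function(maxDistance = 15, maxTimeOffset = 6) {
  stopifnot(maxDistance > 0, maxTimeOffset > 0)
  structure(list(maxDistance = maxDistance, maxTimeOffset = maxTimeOffset),
            class = "MatchConfig")
}

#' Match test objects to reference objects in one frame
#'
#' Optimal one-to-one assignment between reference and test instance masks
#' under the cost `d / maxDistance + (1 - IoU)`, with pairs farther apart
#' than `maxDistance` forbidden. Unmatched test objects are counted as false
#' positives ("additional objects"), unmatched reference objects as false
#' negatives ("missing objects").
#'
#' @param reference,test integer instance label matrices of one shape, or
#'   data.frames with columns `id`, `row`, `col` (centroid-only matching,
#'   IoU taken as 0).
#' @param config a [matchConfig()].
#' @return A [MatchResult-class].
#' @export
matchObjects <- function(reference, test, config = matchConfig()) {
  if (is.matrix(reference) && is.matrix(test)) {
    if (!identical(dim(reference), dim(test)))
      stop("reference and test masks must share one shape")
    rs <- objectStats(reference)
    ts <- objectStats(test)
    ov <- labelOverlap(reference, test)
  } else {
    rs <- as.data.frame(reference); ts <- as.data.frame(test)
    rs$area <- rs$area %||% 1L; ts$area <- ts$area %||% 1L
    ov <- data.frame(a = integer(), b = integer(), n = integer())
  }
  nR <- nrow(rs); nT <- nrow(ts)
  if (nR == 0L || nT == 0L) {
    return(new("MatchResult", TP = 0L, FP = as.integer(nT),
               FN = as.integer(nR),
               pairs = data.frame(ref = integer(), test = integer(),
                                  distance = numeric(), iou = numeric())))
  }
  d <- sqrt(outer(rs$row, ts$row, "-")^2 + outer(rs$col, ts$col, "-")^2)
  iou <- matrix(0, nR, nT)
  if (nrow(ov)) {
    ia <- match(ov$a, rs$id); ib <- match(ov$b, ts$id)
    ok <- !is.na(ia) & !is.na(ib)
    inter <- ov$n[ok]
    un <- rs$area[ia[ok]] + ts$area[ib[ok]] - inter
    iou[cbind(ia[ok], ib[ok])] <- inter / un
  }
  cost <- d / config$maxDistance + (1 - iou)
  sol <- solveAssignment(cost, forbid = d > config$maxDistance)
  pairs <- data.frame(ref = rs$id[sol$row], test = ts$id[sol$col],
                      distance = d[cbind(sol$row, sol$col)],
                      iou = iou[cbind(sol$row, sol$col)])
  new("MatchResult", TP = nrow(pairs), FP = as.integer(nT - nrow(pairs)),
      FN = as.integer(nR - nrow(pairs)), pairs = pairs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detection scores from a match result
#'
#' `F1 = 2 TP / (2 TP + FN + FP)`; the fractions of additional and missing
#' objects are FP and FN normalized by the reference object count.
#'
#' @param m a [MatchResult-class].
#' @param referenceCount reference object count (defaults to TP + FN).
#' @return list with `F1`, `fractionAdditional`, `fractionMissing`, counts.
#' @examples
#' m <- new("MatchResult", TP = 3164L, FP = 796L, FN = 1840L,
#'          pairs = data.frame(ref = integer(3164), test = integer(3164),
#'                             distance = numeric(3164), iou = numeric(3164)))
#' detectionScores(m)$F1   # ~0.706, printed as 0.70-0.71
#' @export
detectionScores <- function(m, referenceCount = m@TP + m@FN) {
  if (m@TP + m@FP + m@FN == 0L)
    stop("no objects in either set: F1 undefined")
  if (referenceCount <= 0L)
    stop("reference count must be positive")
  list(F1 = 2 * m@TP / (2 * m@TP + m@FN + m@FP),
       fractionAdditional = m@FP / referenceCount,
       fractionMissing = m@FN / referenceCount,
       TP = m@TP, FP = m@FP, FN = m@FN)
}

#' Match mitosis events in space and time
#'
#' Linear sum assignment on spatial distance with a hard spatial gate
#' (`maxDistance`, default 15 px) and temporal gate (`maxTimeOffset`,
#' default 6 frames).
#'
#' @param reference,test data.frames with columns `row`, `col`, `frame`.
#' @param config a [matchConfig()].
#' @return A [MatchResult-class]; `pairs$ref`/`pairs$test` are row indices
#'   into the inputs.
#' @export
matchMitoses <- function(reference, test, config = matchConfig()) {
  nR <- nrow(reference); nT <- nrow(test)
  if (nR == 0L || nT == 0L)
    return(new("MatchResult", TP = 0L, FP = as.integer(nT),
               FN = as.integer(nR),
               pairs = data.frame(ref = integer(), test = integer(),
                                  distance = numeric(), iou = numeric())))
  d <- sqrt(outer(reference$row, test$row, "-")^2 +
            outer(reference$col, test$col, "-")^2)
  dt <- abs(outer(reference$frame, test$frame, "-"))
  forbid <- d > config$maxDistance | dt > config$maxTimeOffset
  sol <- solveAssignment(d, forbid = forbid)
  pairs <- data.frame(ref = sol$row, test = sol$col,
                      distance = d[cbind(sol$row, sol$col)],
                      iou = rep(0, nrow(sol)))
  new("MatchResult", TP = nrow(pairs), FP = as.integer(nT - nrow(pairs)),
      FN = as.integer(nR - nrow(pairs)), pairs = pairs)
}

#' Per-track linkage error rates
#'
#' Reference and test objects are paired frame by frame with a
#' centroid-distance assignment (gated at `maxDistance`). A linkage error is
#' a frame at which the test id paired to a persisting reference track
#' differs from the test id paired in the previous paired frame. The rate is
#' the error count divided by the track length (frames observed).
#'
#' @param referenceTracks,testTracks track data.frames with columns
#'   `track_id`, `frame`, `row`, `col` (see [TrackSet-class]), or
#'   `TrackSet`s.
#' @param config a [matchConfig()].
#' @return data.frame with `track_id`, `length`, `errors`, `rate`.
#' @export
linkageErrorRate <- function(referenceTracks, testTracks,
                             config = matchConfig()) {
  rt <- if (is(referenceTracks, "TrackSet")) tracks(referenceTracks) else referenceTracks
  tt <- if (is(testTracks, "TrackSet")) tracks(testTracks) else testTracks
  framesAll <- sort(unique(rt$frame))
  pairedId <- list()   # per frame: named vector ref id -> test id
  for (f in framesAll) {
    r <- rt[rt$frame == f, ]
    s <- tt[tt$frame == f, ]
    if (nrow(r) == 0L || nrow(s) == 0L) next
    d <- sqrt(outer(r$row, s$row, "-")^2 + outer(r$col, s$col, "-")^2)
    sol <- solveAssignment(d, forbid = d > config$maxDistance)
    v <- setNames(s$track_id[sol$col], r$track_id[sol$row])
    pairedId[[as.character(f)]] <- v
  }
  ids <- unique(rt$track_id)
  out <- lapply(ids, function(id) {
    fs <- sort(rt$frame[rt$track_id == id])
    seqIds <- vapply(fs, function(f) {
      v <- pairedId[[as.character(f)]]
      if (is.null(v)) NA_integer_ else
        if (as.character(id) %in% names(v)) unname(v[as.character(id)]) else NA_integer_
    }, 0L)
    obs <- seqIds[!is.na(seqIds)]       # unpaired frames skipped
    errs <- if (length(obs) >= 2L) sum(diff(obs) != 0L) else 0L
    data.frame(track_id = id, length = length(fs), errors = errs,
               rate = errs / length(fs))
  })
  do.call(rbind, out)
}

#' Interdivision times from a lineage
#'
#' For each track born at a division that itself divides, the interdivision
#' time is `(division frame - birth frame) * frameInterval`, in hours.
#'
#' @param trackset a [TrackSet-class] (or a list with `tracks`/`lineage`).
#' @param calibration a [Calibration-class].
#' @param plausibleMinH lower plausibility bound in hours (default 9).
#' @return list with `hours` (numeric vector), `nBelow` and `nAbove` the
#'   bound.
#' @export
interdivisionTimes <- function(trackset, calibration = colonytrack::calibration(),
                               plausibleMinH = 9) {
  lg <- if (is(trackset, "TrackSet")) lineage(trackset) else trackset$lineage
  if (is.null(lg) || nrow(lg) == 0L)
    return(list(hours = numeric(), nBelow = 0L, nAbove = 0L))
  birth <- setNames(rep(NA_real_, 0), character())
  bmap <- c(setNames(lg$frame, lg$daughter1), setNames(lg$frame, lg$daughter2))
  hrs <- numeric()
  for (i in seq_len(nrow(lg))) {
    p <- as.character(lg$parent[i])
    if (p %in% names(bmap)) {
      dt <- lg$frame[i] - bmap[[p]]
      hrs <- c(hrs, dt * frameInterval(calibration) / 60)
    }
  }
  list(hours = hrs, nBelow = sum(hrs < plausibleMinH),
       nAbove = sum(hrs >= plausibleMinH))
}

#' Doubling time from cell counts
#'
#' `DT = ln(2) / (ln(N_t / N_0) / t)` evaluated on sliding windows of
#' `windowFrames` frames; `t` is the window span in hours. Windows without
#' growth (ratio <= 1) yield `NA` (undefined, not an error).
#'
#' @param counts per-frame cell counts.
#' @param windowFrames window length in frames (default 30, i.e. 60 min at
#'   2-min frames).
#' @param calibration a [Calibration-class].
#' @return numeric vector of per-window doubling times in hours (one per
#'   window start).
#' @export
doublingTimeCounts <- function(counts, windowFrames = 30,
                               calibration = colonytrack::calibration()) {
  n <- length(counts)
  if (n <= windowFrames) return(numeric())
  tH <- windowFrames * frameInterval(calibration) / 60
  starts <- seq_len(n - windowFrames)
  vapply(starts, function(s) {
    n0 <- counts[s]; nt <- counts[s + windowFrames]
    if (n0 <= 0) stop("zero starting count in window")
    if (nt <= n0) return(NA_real_)
    log(2) / (log(nt / n0) / tH)
  }, 0)
}

#' Doubling time from counted mitoses
#'
#' `DT = ln(2) / (ln((N_0 + #mitoses) / N_0) / t)` per window: every counted
#' division adds one cell, so `N_0 + m` is the expected end-of-window count
#' in the absence of death.
#'
#' @param n0 cell count at each window start.
#' @param mitoses divisions within each window.
#' @param windowHours window span in hours.
#' @return numeric vector of doubling times in hours (`NA` where no growth).
#' @export
doublingTimeMitoses <- function(n0, mitoses, windowHours = 1) {
  stopifnot(length(n0) == length(mitoses))
  if (any(n0 <= 0)) stop("initial count must be positive")
  out <- log(2) / (log((n0 + mitoses) / n0) / windowHours)
  out[mitoses <= 0] <- NA_real_
  out
}

#' Smoothed mitosis-rate series
#'
#' Counts division events in a sliding window of `windowMinutes`, divides by
#' the chosen denominator (the initial cell count, or the cell count at the
#' window start), and applies a moving average.
#'
#' @param eventFrames frame indices of division events.
#' @param counts per-frame cell counts.
#' @param windowMinutes sliding window width in minutes (default 60).
#' @param denominator `"initial"` (divide by the first frame's count) or
#'   `"window"` (divide by the count at each window start).
#' @param smoothFrames moving-average width in frames (default 20).
#' @param calibration a [Calibration-class].
#' @return numeric vector, one rate per window start frame.
#' @export
mitosisRate <- function(eventFrames, counts, windowMinutes = 60,
                        denominator = c("initial", "window"),
                        smoothFrames = 20,
                        calibration = colonytrack::calibration()) {
  denominator <- match.arg(denominator)
  n <- length(counts)
  w <- max(1L, round(windowMinutes / frameInterval(calibration)))
  starts <- seq_len(max(1L, n - w + 1L))
  raw <- vapply(starts, function(s) {
    m <- sum(eventFrames >= s & eventFrames < s + w)
    den <- if (denominator == "initial") counts[1L] else counts[s]
    if (den <= 0) return(NA_real_)
    m / den
  }, 0)
  movingAverage(raw, smoothFrames)
}

movingAverage <- function(x, k) {
  if (k <= 1L || length(x) < 2L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - floor((k - 1) / 2)); hi <- min(n, i + ceiling((k - 1) / 2))
    mean(x[lo:hi], na.rm = TRUE)
  }, 0)
}

#' Per-cell mean squared displacement over a time horizon
#'
#' For each track and each start frame with the full horizon available,
#' `MSD(t0) = mean over lags 1..H of |x(t0 + lag) - x(t0)|^2`, converted to
#' um^2 via the pixel area.
#'
#' @param trackset a [TrackSet-class] or track data.frame.
#' @param calibration a [Calibration-class].
#' @param horizonMinutes averaging horizon (default 60 min).
#' @return data.frame with `track_id`, `frame` (start), `msd` (um^2).
#' @export
msd <- function(trackset, calibration = colonytrack::calibration(),
                horizonMinutes = 60) {
  tr <- if (is(trackset, "TrackSet")) tracks(trackset) else trackset
  H <- max(1L, round(horizonMinutes / frameInterval(calibration)))
  pa <- pixelArea(calibration)
  out <- lapply(split(tr, tr$track_id), function(d) {
    d <- d[order(d$frame), ]
    # require contiguous presence over the horizon
    full <- seq(min(d$frame), max(d$frame))
    if (!all(full %in% d$frame)) {
      d <- d[d$frame %in% full, ]
    }
    n <- nrow(d)
    if (n <= H) return(NULL)
    starts <- seq_len(n - H)
    ms <- vapply(starts, function(i) {
      lag <- seq_len(H)
      mean((d$row[i + lag] - d$row[i])^2 + (d$col[i + lag] - d$col[i])^2)
    }, 0)
    data.frame(track_id = d$track_id[1L], frame = d$frame[starts],
               msd = ms * pa)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(track_id = integer(), frame = integer(),
                                      msd = numeric())
  rownames(out) <- NULL
  out
}

#' Profile of a per-cell metric versus distance from the colony edge
#'
#' The colony mask of a frame is the morphological closing of the union of
#' nucleus masks (closing radius three median nucleus radii); each cell's
#' distance from the colony edge is the Euclidean distance transform value
#' at its centroid, converted to micrometers. The supplied metric values are
#' then averaged within distance bins.
#'
#' @param instanceMasks list of integer instance masks, one per frame.
#' @param metricSeries data.frame with `frame` and `value` plus `row`, `col`
#'   (pixel position of the cell the value belongs to).
#' @param calibration a [Calibration-class].
#' @param binWidthUm distance bin width in micrometers (default 25).
#' @return data.frame with `bin` (left edge, um), `mean`, `n`.
#' @export
edgeDistanceProfile <- function(instanceMasks, metricSeries,
                                calibration = colonytrack::calibration(),
                                binWidthUm = 25) {
  pxUm <- sqrt(pixelArea(calibration))
  dmaps <- list()
  getDmap <- function(f) {
    key <- as.character(f)
    if (!is.null(dmaps[[key]])) return(dmaps[[key]])
    lab <- instanceMasks[[f]]
    st <- objectStats(lab)
    rad <- if (nrow(st)) median(sqrt(st$area / pi)) else 3
    brush <- EBImage::makeBrush(2L * as.integer(ceiling(3 * rad)) + 1L,
                                shape = "disc")
    closed <- EBImage::closing(matrix(as.numeric(lab > 0L), nrow(lab)), brush)
    dm <- EBImage::distmap(matrix(as.numeric(closed > 0), nrow(lab)))
    dm <- matrix(as.numeric(dm), nrow(lab))
    dmaps[[key]] <<- dm
    dm
  }
  dist <- numeric(nrow(metricSeries))
  for (i in seq_len(nrow(metricSeries))) {
    f <- metricSeries$frame[i]
    dm <- getDmap(f)
    r <- min(max(round(metricSeries$row[i]), 1L), nrow(dm))
    c <- min(max(round(metricSeries$col[i]), 1L), ncol(dm))
    dist[i] <- dm[r, c] * pxUm
  }
  bins <- floor(dist / binWidthUm) * binWidthUm
  agg <- aggregate(metricSeries$value, by = list(bin = bins),
                   FUN = function(v) c(mean(v), length(v)))
  data.frame(bin = agg$bin, mean = agg$x[, 1L], n = agg$x[, 2L])
}

#' @importFrom stats aggregate
NULL
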