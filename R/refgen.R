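# Automated creation of 2-class and 4-class annotations from fluorescence
# stacks: the pipeline's substitute for manual labeling. Nuclei are found by
# a band-pass (difference of Gaussians) filter plus threshold and separated
# with FogBank; condensed DNA is found with a second, smaller-scale
# band-pass; daughters are identified by duplicating each condensed
# (class-2 candidate) object and pairing it against the next frame with a
# linear sum assignment.

#' Band-pass filter parameters
#'
#' Difference-of-Gaussians band-pass. Two presets are used in the pipeline:
#' the nucleus scale (`nucleusBandpass()`, sigmas 2 and 12 px) and the
#' condensed-DNA scale (`condensedBandpass()`, sigmas 1 and 4 px).
#'
#' @param lowSigma,highSigma Gaussian scales in pixels, `lowSigma < highSigma`.
#' @param thresholdMode `"otsu"` for automatic thresholding of the filter
#'   response, `"fixed"` to use `thresholdValue`.
#' @param thresholdValue intensity threshold when `thresholdMode = "fixed"`.
#' @return list of class `BandpassParams`.
#' @export
bandpassParams <- function(lowSigma, highSigma,
                           thresholdMode = c("otsu", "fixed"),
                           thresholdValue = NA_real_) {
  thresholdMode <- match.arg(thresholdMode)
  stopifnot(lowSigma > 0, highSigma > lowSigma)
  if (thresholdMode == "fixed") stopifnot(is.finite(thresholdValue))
  structure(list(lowSigma = lowSigma, highSigma = highSigma,
                 thresholdMode = thresholdMode,
                 thresholdValue = thresholdValue),
            class = "BandpassParams")
}

#' @rdname bandpassParams
#' @export
nucleusBandpass <- function(thresholdMode = "otsu", thresholdValue = NA_real_)
  bandpassParams(2, 12, thresholdMode, thresholdValue)

#' @rdname bandpassParams
#' @export
condensedBandpass <- function(thresholdMode = "fixed", thresholdValue = 0.8)
  bandpassParams(1, 4, thresholdMode, thresholdValue)

bandpassResponse <- function(frame, bp) {
  gaussianBlur(frame, bp$lowSigma) - gaussianBlur(frame, bp$highSigma)
}

bandpassThreshold <- function(resp, bp) {
  if (bp$thresholdMode == "fixed") return(bp$thresholdValue)
  rng <- range(resp)
  if (diff(rng) == 0) return(Inf)      # flat response: nothing above
  as.numeric(EBImage::otsu(matrix(resp, nrow(resp)), range = rng))
}

#' Annotation temporal windows
#'
#' @param framesBefore frames before division labeled class 2 (default 5).
#' @param framesAfter frames after division labeled class 3 (default 3).
#' @return list of class `AnnotationWindows`.
#' @export
annotationWindows <- function(framesBefore = 5, framesAfter = 3) {
  stopifnot(framesBefore >= 1, framesAfter >= 1)
  structure(list(framesBefore = framesBefore, framesAfter = framesAfter),
            class = "AnnotationWindows")
}

#' Segment nuclei in a fluorescence frame
#'
#' Pipeline: band-pass filter -> threshold -> FogBank separation (seeded on
#' the raw fluorescence intensity, whose inter-nucleus gaps survive where
#' band-pass smoothing bridges them) -> per-object binary erosion (disk of
#' radius 1). An all-background result is a valid empty mask.
#'
#' @param fluorFrame 2-D numeric matrix.
#' @param bp a [bandpassParams()] (default [nucleusBandpass()]).
#' @param fog a [fogbankParams()].
#' @return Integer instance label matrix.
#' @export
segmentNuclei <- function(fluorFrame, bp = nucleusBandpass(),
                          fog = fogbankParams()) {
  resp <- bandpassResponse(fluorFrame, bp)
  thr <- bandpassThreshold(resp, bp)
  mask <- resp > thr
  if (!any(mask)) return(matrix(0L, nrow(fluorFrame), ncol(fluorFrame)))
  # Seed surface: smoothed fluorescence (scale-normalized) so that true
  # inter-nucleus gaps separate seeds even when band-pass smoothing bridges
  # the mask, plus a small distance-transform term so equal-brightness
  # touching nuclei still seed separately.
  sm <- gaussianBlur(fluorFrame, 1)
  ref <- quantile(sm[mask], 0.99)
  if (ref <= 0) ref <- max(sm[mask])
  dt <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  surface <- sm / ref + 0.04 * matrix(as.numeric(dt), nrow(mask))
  labels <- separateObjects(mask, intensity = surface, params = fog)
  compactLabels(erodeLabelwise(labels, 1L))
}

# Per-object binary erosion by a disk of radius r (4-connectivity for r=1):
# a pixel survives iff the whole disk around it lies in the same label.
erodeLabelwise <- function(labels, r = 1L) {
  keep <- labels > 0L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2 & !(offs$dr == 0 & offs$dc == 0), ]
  for (i in seq_len(nrow(offs))) {
    s <- shiftMatrix(labels, offs$dr[i], offs$dc[i], fill = 0L)
    keep <- keep & s == labels
  }
  out <- labels
  out[!keep] <- 0L
  out
}

#' Flag instances containing condensed DNA
#'
#' An instance is flagged as a class-2 (mitotic) candidate iff the area of
#' the condensed-scale band-pass response above threshold inside the
#' instance lies between `minFraction` and `maxFraction` of the instance
#' area. Condensed DNA is a compact, bright minority of the nucleus; an
#' object whose area responds almost everywhere at the condensed scale is a
#' pair of overlapping nuclei, not a mitotic cell, hence the upper bound.
#'
#' @param fluorFrame the fluorescence frame.
#' @param instances integer instance labels from [segmentNuclei()].
#' @param bp a [bandpassParams()] (default [condensedBandpass()]).
#' @param minFraction response-area fraction required (default 0.10).
#' @param maxFraction response-area fraction above which the object is
#'   treated as an overlap artifact (default 0.9).
#' @return Integer vector of flagged instance ids (possibly empty).
#' @export
detectCondensed <- function(fluorFrame, instances, bp = condensedBandpass(),
                            minFraction = 0.10, maxFraction = 0.9) {
  if (!any(instances > 0L)) return(integer())
  resp <- bandpassResponse(fluorFrame, bp)
  thr <- bandpassThreshold(resp, bp)
  hot <- resp > thr
  ids <- sort(unique(instances[instances > 0L]))
  inside <- tabulate(factor(instances[hot & instances > 0L], levels = ids),
                     nbins = length(ids))
  area <- tabulate(factor(instances[instances > 0L], levels = ids),
                   nbins = length(ids))
  frac <- inside / area
  ids[frac >= minFraction & frac <= maxFraction]
}

#' Link daughters across consecutive frames
#'
#' Each flagged (class-2 candidate) object at frame `t0` is duplicated and a
#' linear sum assignment (cost = distance / gate + (1 - IoU), the same
#' combined cost used throughout the pipeline, gated at
#' `config$maxDistance`) pairs the objects of `t0` with those of `t1`. A
#' division is recorded iff the two copies of a flagged object map to two
#' distinct objects of `t1` *and* the two mapped objects straddle the
#' mother: their centroid midpoint must fall within `midpointGate` pixels of
#' the mother's centroid. (Without the symmetry check, a persisting mother
#' whose duplicate captures a neighboring nucleus would fake a division.)
#' Flags carry a short memory: an object chained (by nearest centroid) to an
#' object flagged within the last `flagMemory` frames counts as flagged, so
#' a transient flag dropout in the frame before division is tolerated.
#'
#' @param instanceSeries list of per-frame instance masks.
#' @param flaggedSeries list of per-frame flagged id vectors (from
#'   [detectCondensed()]).
#' @param config a [matchConfig()].
#' @param midpointGate max distance (px) between the mother centroid and the
#'   midpoint of the two mapped objects (default 4).
#' @param flagMemory frames a flag is propagated forward along identity
#'   chains (default 2).
#' @return data.frame with `frame` (the daughters' frame `t1`), `mother`
#'   (id at `t0`), `daughter1`, `daughter2` (ids at `t1`), `row`, `col`
#'   (mother centroid).
#' @export
linkDaughters <- function(instanceSeries, flaggedSeries,
                          config = matchConfig(), midpointGate = 4,
                          flagMemory = 2) {
  stopifnot(length(instanceSeries) == length(flaggedSeries))
  stats <- lapply(instanceSeries, objectStats)
  flagged <- propagateFlags(stats, flaggedSeries, flagMemory,
                            config$maxDistance)
  # native (unpropagated) flag run length per frame/object: how many
  # consecutive frames, ending at this one, the chained object was flagged
  flagRun <- function(t0, id) {
    run <- 0L
    f <- t0
    cur <- id
    while (f >= 1L && cur %in% flaggedSeries[[f]]) {
      run <- run + 1L
      if (f == 1L) break
      st0 <- stats[[f - 1L]]
      st <- stats[[f]]
      k <- match(cur, st$id)
      if (is.na(k) || nrow(st0) == 0L) break
      d <- sqrt((st0$row - st$row[k])^2 + (st0$col - st$col[k])^2)
      j <- which.min(d)
      if (d[j] > config$maxDistance) break
      cur <- st0$id[j]
      f <- f - 1L
    }
    run
  }
  out <- list()
  for (t0 in seq_len(length(instanceSeries) - 1L)) {
    s0 <- stats[[t0]]; s1 <- stats[[t0 + 1L]]
    if (nrow(s0) == 0L || nrow(s1) == 0L) next
    flg <- flagged[[t0]]
    dup <- c(seq_len(nrow(s0)), which(s0$id %in% flg))   # duplicated rows
    d <- sqrt(outer(s0$row[dup], s1$row, "-")^2 +
              outer(s0$col[dup], s1$col, "-")^2)
    ov <- labelOverlap(instanceSeries[[t0]], instanceSeries[[t0 + 1L]])
    iou <- matrix(0, nrow(s0), nrow(s1))
    if (nrow(ov)) {
      ia <- match(ov$a, s0$id); ib <- match(ov$b, s1$id)
      un <- s0$area[ia] + s1$area[ib] - ov$n
      iou[cbind(ia, ib)] <- ov$n / un
    }
    cost <- d / config$maxDistance + (1 - iou[dup, , drop = FALSE])
    sol <- solveAssignment(cost, forbid = d > config$maxDistance)
    for (id in intersect(flg, s0$id)) {
      rows <- which(s0$id[dup] == id)
      hits <- sol$col[sol$row %in% rows]
      k <- which(s0$id == id)
      if (length(hits) == 2L && hits[1L] != hits[2L]) {
        mid <- c(mean(s1$row[hits]), mean(s1$col[hits]))
        if (sqrt((mid[1L] - s0$row[k])^2 + (mid[2L] - s0$col[k])^2) >
            midpointGate) next
        out[[length(out) + 1L]] <- data.frame(
          frame = t0 + 1L, mother = id,
          daughter1 = s1$id[min(hits)], daughter2 = s1$id[max(hits)],
          row = s0$row[k], col = s0$col[k],
          daughterArea = sum(s1$area[hits]),
          flagRun = flagRun(t0, id))
      } else if (t0 + 2L <= length(instanceSeries)) {
        # daughters may be entangled with a neighbor at t1 and separate one
        # frame later: look ahead one frame, keep the event dated t1
        s2 <- stats[[t0 + 2L]]
        if (nrow(s2) < 2L) next
        d2 <- sqrt((s2$row - s0$row[k])^2 + (s2$col - s0$col[k])^2)
        cand <- which(d2 <= config$maxDistance)
        if (length(cand) < 2L) next
        prs <- utils::combn(cand, 2L)
        mids <- sqrt((colMeans(matrix(s2$row[prs], 2L)) - s0$row[k])^2 +
                     (colMeans(matrix(s2$col[prs], 2L)) - s0$col[k])^2)
        b <- which.min(mids)
        if (mids[b] > midpointGate) next
        hits2 <- prs[, b]
        out[[length(out) + 1L]] <- data.frame(
          frame = t0 + 1L, mother = id,
          daughter1 = s2$id[min(hits2)], daughter2 = s2$id[max(hits2)],
          row = s0$row[k], col = s0$col[k],
          daughterArea = sum(s2$area[hits2]),
          flagRun = flagRun(t0, id))
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), mother = integer(),
                      daughter1 = integer(), daughter2 = integer(),
                      row = numeric(), col = numeric(),
                      daughterArea = numeric(), flagRun = integer()))
  dedupeEvents(do.call(rbind, out))
}

# A nucleus cannot divide twice within minutes: events closer than distGate
# pixels and within frameGate frames of each other are re-detections of one
# division. Within such a cluster the event whose mother carries the
# longest run of consecutive condensation flags wins (condensation builds up
# over the frames before the true division; spurious early splits have
# short runs and post-division splits none); ties resolve to the smaller
# combined daughter area (daughters are newly formed, hence small), then to
# the earlier frame.
dedupeEvents <- function(ev, distGate = 6, frameGate = 8) {
  ev <- ev[order(ev$frame, ev$row, ev$col), , drop = FALSE]
  n <- nrow(ev)
  cluster <- integer(n)
  nxt <- 1L
  for (i in seq_len(n)) {
    hit <- which(cluster > 0L & ev$frame >= ev$frame[i] - frameGate &
                 sqrt((ev$row - ev$row[i])^2 + (ev$col - ev$col[i])^2) <= distGate)
    if (length(hit)) {
      cluster[i] <- cluster[hit[1L]]
    } else {
      cluster[i] <- nxt
      nxt <- nxt + 1L
    }
  }
  keep <- vapply(split(seq_len(n), cluster), function(ix) {
    ix[order(-ev$flagRun[ix], ev$daughterArea[ix], ev$frame[ix])][1L]
  }, 0L)
  out <- ev[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# forward-propagate condensation flags along nearest-centroid identity
# chains for up to `memory` frames
propagateFlags <- function(stats, flaggedSeries, memory, gate) {
  eff <- lapply(flaggedSeries, function(f) as.integer(f))
  if (memory <= 0L) return(eff)
  for (t in seq_len(length(stats) - 1L)) {
    st0 <- stats[[t]]; st1 <- stats[[t + 1L]]
    if (nrow(st0) == 0L || nrow(st1) == 0L) next
    # carry a flag age: ids flagged at t (age 0) or carried (age < memory)
    carried <- attr(eff[[t]], "age")
    age0 <- setNames(rep(0L, length(flaggedSeries[[t]])),
                     flaggedSeries[[t]])
    ages <- age0
    if (!is.null(carried))
      for (nm in names(carried))
        if (!nm %in% names(ages)) ages[nm] <- carried[[nm]]
    keep <- ages[ages < memory]
    if (length(keep) == 0L) next
    ids <- as.integer(names(keep))
    kk <- match(ids, st0$id)
    ok <- !is.na(kk)
    if (!any(ok)) next
    nxt <- integer(); nxtAge <- integer()
    for (j in which(ok)) {
      d <- sqrt((st1$row - st0$row[kk[j]])^2 + (st1$col - st0$col[kk[j]])^2)
      b <- which.min(d)
      if (d[b] <= gate) {
        nxt <- c(nxt, st1$id[b]); nxtAge <- c(nxtAge, keep[[j]] + 1L)
      }
    }
    if (length(nxt)) {
      add <- setdiff(nxt, eff[[t + 1L]])
      newFlags <- unique(c(eff[[t + 1L]], add))
      aget <- setNames(nxtAge, nxt)
      eff[[t + 1L]] <- newFlags
      attr(eff[[t + 1L]], "age") <- aget
    }
  }
  lapply(eff, function(f) { attributes(f) <- NULL; f })
}

# follow an object's identity to earlier/later frames by nearest centroid
# within the gate; returns list of (frame, id) pairs
chainObject <- function(stats, startFrame, startId, steps, gate) {
  out <- list()
  f <- startFrame
  st <- stats[[f]]
  k <- which(st$id == startId)
  if (length(k) == 0L) return(out)
  pos <- c(st$row[k], st$col[k])
  id <- startId
  dirn <- sign(steps)
  for (s in seq_len(abs(steps))) {
    f2 <- f + dirn
    if (f2 < 1L || f2 > length(stats)) break
    st2 <- stats[[f2]]
    if (nrow(st2) == 0L) break
    d <- sqrt((st2$row - pos[1L])^2 + (st2$col - pos[2L])^2)
    j <- which.min(d)
    if (d[j] > gate) break
    out[[length(out) + 1L]] <- c(frame = f2, id = st2$id[j])
    pos <- c(st2$row[j], st2$col[j])
    f <- f2
  }
  out
}

#' Build a 4-class mask from instances and division events
#'
#' The mother's pixels are class 2 in the `framesBefore` frames preceding
#' the division, each daughter's pixels class 3 in the `framesAfter` frames
#' from the division on; all other nucleus pixels are class 1. When event
#' windows overlap on a pixel, the later event wins. Mother identity is
#' chained backwards (and daughter identity forwards) by nearest centroid
#' within `config$maxDistance`.
#'
#' @param instanceSeries list of per-frame instance masks.
#' @param events data.frame as returned by [linkDaughters()] (or the truth
#'   `lineage` table renamed accordingly).
#' @param windows an [annotationWindows()].
#' @param config a [matchConfig()] (identity-chaining gate).
#' @return A [ClassMask-class] over (rows, cols, frames).
#' @export
buildClassMasks <- function(instanceSeries, events,
                            windows = annotationWindows(),
                            config = matchConfig()) {
  nT <- length(instanceSeries)
  d <- dim(instanceSeries[[1L]])
  arr <- array(0L, dim = c(d, nT))
  for (t in seq_len(nT)) arr[, , t] <- (instanceSeries[[t]] > 0L) * 1L
  if (nrow(events) == 0L) return(classMask(arr))
  stats <- lapply(instanceSeries, objectStats)
  events <- events[order(events$frame), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    tDiv <- ev$frame
    if (tDiv < 1L || tDiv > nT) {
      warning("division event outside the stack; clipped")
      next
    }
    # mother: frames tDiv-1 down to tDiv-framesBefore
    t0 <- tDiv - 1L
    if (t0 >= 1L) {
      paint <- function(frame, id, cls) {
        sl <- arr[, , frame]
        sl[instanceSeries[[frame]] == id] <- cls
        arr[, , frame] <<- sl
      }
      if (any(stats[[t0]]$id == ev$mother)) {
        paint(t0, ev$mother, 2L)
        back <- chainObject(stats, t0, ev$mother,
                            -(windows$framesBefore - 1L), config$maxDistance)
        for (b in back) paint(b[["frame"]], b[["id"]], 2L)
      }
      for (dId in c(ev$daughter1, ev$daughter2)) {
        if (!any(stats[[tDiv]]$id == dId)) next
        paint(tDiv, dId, 3L)
        fwd <- chainObject(stats, tDiv, dId, windows$framesAfter - 1L,
                           config$maxDistance)
        for (b in fwd) paint(b[["frame"]], b[["id"]], 3L)
      }
    }
  }
  classMask(arr)
}

#' Run the full annotation chain on a fluorescence time-lapse
#'
#' Convenience wrapper: [segmentNuclei()] per frame, [detectCondensed()],
#' [linkDaughters()], [buildClassMasks()].
#'
#' @param fluor a [TimeLapse-class] (fluorescence channel).
#' @param bpNucleus,bpCondensed band-pass presets.
#' @param fog a [fogbankParams()].
#' @param windows an [annotationWindows()].
#' @param config a [matchConfig()].
#' @return list with `instances` (per-frame label masks), `flagged`
#'   (per-frame id vectors), `events` (division table) and `classes`
#'   (a [ClassMask-class]).
#' @export
generateAnnotations <- function(fluor, bpNucleus = nucleusBandpass(),
                                bpCondensed = condensedBandpass(),
                                fog = fogbankParams(),
                                windows = annotationWindows(),
                                config = matchConfig()) {
  fr <- frames(fluor)
  instances <- lapply(fr, segmentNuclei, bp = bpNucleus, fog = fog)
  flagged <- lapply(seq_along(fr), function(t)
    detectCondensed(fr[[t]], instances[[t]], bp = bpCondensed))
  events <- linkDaughters(instances, flagged, config)
  classes <- buildClassMasks(instances, events, windows, config)
  list(instances = instances, flagged = flagged, events = events,
       classes = classes)
}

#' Cut image / class-mask pairs into training tiles
#'
#' 2D mode yields 256 x 256 image/label pairs per frame; 3D mode yields
#' 256 x 256 x 16 pairs (from which 128 x 128 x 16 crops are drawn at
#' training time).
#'
#' @param phase a [TimeLapse-class] (or list of frames).
#' @param classmask a [ClassMask-class] with matching geometry.
#' @param mode `"2D"` or `"3D"`.
#' @param tileShape overrides the default tile shape for the mode.
#' @return list of `list(image, labels)` pairs.
#' @export
makeTrainingTiles <- function(phase, classmask, mode = c("2D", "3D"),
                              tileShape = NULL) {
  mode <- match.arg(mode)
  fr <- if (is(phase, "TimeLapse")) frames(phase) else phase
  arr <- classArray(classmask)
  stopifnot(identical(dim(fr[[1L]]), dim(arr)[1:2]),
            length(fr) == dim(arr)[3L])
  if (mode == "2D") {
    ts <- tileShape %||% c(256L, 256L)
    out <- list()
    for (t in seq_along(fr)) {
      ti <- tileImage(fr[[t]], ts)
      tl <- tileImage(arr[, , t], ts)
      for (k in seq_along(ti$tiles))
        out[[length(out) + 1L]] <- list(image = ti$tiles[[k]],
                                        labels = tl$tiles[[k]],
                                        frame = t)
    }
    out
  } else {
    ts <- tileShape %||% c(256L, 256L, 16L)
    if (length(fr) < ts[3L])
      stop(sprintf("3D mode needs at least %d frames", ts[3L]))
    stack <- array(0, dim = c(dim(fr[[1L]]), length(fr)))
    for (t in seq_along(fr)) stack[, , t] <- fr[[t]]
    ti <- tileImage(stack, ts)
    tl <- tileImage(arr, ts)
    lapply(seq_along(ti$tiles), function(k)
      list(image = ti$tiles[[k]], labels = tl$tiles[[k]]))
  }
}
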