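# Frame-to-frame linking of nucleus instances by gated linear sum assignment
# on a combined overlap + centroid-distance cost, with a grace window for
# temporarily lost objects, merge-event bookkeeping, and lineage
# construction from mitosis events (dividing objects are taken out of the
# assignment and linked mother -> daughters explicitly).

#' Tracker configuration
#'
#' @param maxLinkDistance assignment gate in pixels (default 15).
#' @param graceFrames frames an unmatched object may coast before its track
#'   is lost (default 5).
#' @param wDist,wOverlap weights of the distance and (1 - IoU) cost terms
#'   (defaults 1 and 1; distance is scaled by the gate so both terms lie in
#'   [0, 1]).
#' @param minTrackFrames default span threshold of [filterTracks()]
#'   (default 5 frames, i.e. 10 minutes at 2-minute intervals).
#' @return list of class `TrackerConfig`.
#' @export
trackerConfig <- function(maxLinkDistance = 15, graceFrames = 5,
                          wDist = 1, wOverlap = 1, minTrackFrames = 5) {
  stopifnot(maxLinkDistance > 0, graceFrames >= 0, wDist >= 0, wOverlap >= 0,
            minTrackFrames >= 0)
  structure(list(maxLinkDistance = maxLinkDistance, graceFrames = graceFrames,
                 wDist = wDist, wOverlap = wOverlap,
                 minTrackFrames = minTrackFrames),
            class = "TrackerConfig")
}

#' Optimal links between two consecutive instance masks
#'
#' Cost of a candidate pair is
#' `wDist * d / maxLinkDistance + wOverlap * (1 - IoU)`; pairs beyond the
#' gate are forbidden; the assignment is the optimal one-to-one matching.
#'
#' @param prev,curr integer instance masks of one shape.
#' @param config a [trackerConfig()].
#' @return list with `pairs` (data.frame `prev_id`, `curr_id`),
#'   `unmatchedPrev`, `unmatchedCurr` (id vectors) and `merged` (ids of
#'   unmatched previous objects whose pixels fell >50% inside a matched
#'   current object).
#' @export
linkFrames <- function(prev, curr, config = trackerConfig()) {
  ps <- objectStats(prev)
  cs <- objectStats(curr)
  linkFramesStats(ps, cs, labelOverlap(prev, curr), config)
}

linkFramesStats <- function(ps, cs, ov, config) {
  if (nrow(ps) == 0L || nrow(cs) == 0L)
    return(list(pairs = data.frame(prev_id = integer(), curr_id = integer()),
                unmatchedPrev = ps$id, unmatchedCurr = cs$id,
                merged = integer()))
  d <- sqrt(outer(ps$row, cs$row, "-")^2 + outer(ps$col, cs$col, "-")^2)
  iou <- matrix(0, nrow(ps), nrow(cs))
  covPrev <- matrix(0, nrow(ps), nrow(cs))   # fraction of prev inside curr
  if (nrow(ov)) {
    ia <- match(ov$a, ps$id); ib <- match(ov$b, cs$id)
    ok <- !is.na(ia) & !is.na(ib)
    inter <- ov$n[ok]
    un <- ps$area[ia[ok]] + cs$area[ib[ok]] - inter
    iou[cbind(ia[ok], ib[ok])] <- inter / un
    covPrev[cbind(ia[ok], ib[ok])] <- inter / ps$area[ia[ok]]
  }
  cost <- config$wDist * d / config$maxLinkDistance +
    config$wOverlap * (1 - iou)
  sol <- solveAssignment(cost, forbid = d > config$maxLinkDistance)
  pairs <- data.frame(prev_id = ps$id[sol$row], curr_id = cs$id[sol$col])
  umPrev <- setdiff(ps$id, pairs$prev_id)
  umCurr <- setdiff(cs$id, pairs$curr_id)
  merged <- integer()
  if (length(umPrev)) {
    matchedCurr <- match(pairs$curr_id, cs$id)
    for (id in umPrev) {
      i <- match(id, ps$id)
      if (length(matchedCurr) && any(covPrev[i, matchedCurr] > 0.5))
        merged <- c(merged, id)
    }
  }
  list(pairs = pairs, unmatchedPrev = umPrev, unmatchedCurr = umCurr,
       merged = merged)
}

#' Track nucleus instances over time, with optional mitosis events
#'
#' Runs gated linear-sum-assignment linking frame by frame. Objects involved
#' in a division (the mother at its last frame, the daughters claimed by the
#' event's seed positions) are omitted from the assignment and connected
#' through the lineage instead. Unmatched previous objects coast for up to
#' `graceFrames` frames (a disappearing object that reappears nearby resumes
#' its track); unmatched current objects open new tracks. Track ids are
#' assigned in birth order (frame, then row, then col).
#'
#' @param instanceSeries list of integer instance masks, one per frame.
#' @param events optional division events: data.frame with `frame`,
#'   `seed1_row`, `seed1_col`, `seed2_row`, `seed2_col` (as from
#'   [extractEvents()]), and optionally `row`, `col` (mother position).
#' @param config a [trackerConfig()].
#' @return A [TrackSet-class].
#' @export
trackCells <- function(instanceSeries, events = NULL,
                       config = trackerConfig()) {
  nT <- length(instanceSeries)
  stats <- lapply(instanceSeries, objectStats)
  if (is.null(events))
    events <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                         seed1_row = numeric(), seed1_col = numeric(),
                         seed2_row = numeric(), seed2_col = numeric())
  if (nrow(events) && !("seed1_row" %in% names(events))) {
    # events carrying daughter instance ids (refgen style): derive seeds
    # from the daughters' centroids at the event frame
    for (s in 1:2) {
      events[[paste0("seed", s, "_row")]] <- NA_real_
      events[[paste0("seed", s, "_col")]] <- NA_real_
    }
    for (i in seq_len(nrow(events))) {
      st <- stats[[events$frame[i]]]
      for (s in 1:2) {
        k <- match(events[[paste0("daughter", s)]][i], st$id)
        if (!is.na(k)) {
          events[[paste0("seed", s, "_row")]][i] <- st$row[k]
          events[[paste0("seed", s, "_col")]][i] <- st$col[k]
        }
      }
    }
    events <- events[!is.na(events$seed1_row) & !is.na(events$seed2_row), ,
                     drop = FALSE]
  }

  nextTrack <- 1L
  # active track state: trackId, lastFrame, lastLabel, row, col, misses
  active <- data.frame(trackId = integer(), lastFrame = integer(),
                       lastLabel = integer(), row = numeric(),
                       col = numeric(), misses = integer(),
                       flag = character())
  rows <- list()
  lineageRows <- list()

  addEntry <- function(trackId, frame, st, label, parent = NA_integer_,
                       flag = "") {
    k <- match(label, st$id)
    rows[[length(rows) + 1L]] <<- data.frame(
      track_id = trackId, frame = frame, row = st$row[k], col = st$col[k],
      area = st$area[k], label = label, parent_id = parent, flags = flag)
  }

  # open tracks for every object of frame 1, in deterministic birth order
  st1 <- stats[[1L]]
  if (nrow(st1)) {
    ord <- order(st1$row, st1$col)
    for (k in ord) {
      addEntry(nextTrack, 1L, st1, st1$id[k])
      active <- rbind(active, data.frame(
        trackId = nextTrack, lastFrame = 1L, lastLabel = st1$id[k],
        row = st1$row[k], col = st1$col[k], misses = 0L, flag = ""))
      nextTrack <- nextTrack + 1L
    }
  }

  parentOf <- setNames(rep(NA_integer_, 0), character())

  for (t in seq_len(nT - 1L)) {
    tn <- t + 1L
    stN <- stats[[tn]]
    evHere <- events[events$frame == tn, , drop = FALSE]

    # --- claim daughters and close mothers for this frame's divisions ----
    claimedCurr <- integer()
    closedTracks <- integer()
    newDaughters <- list()
    if (nrow(evHere) && nrow(stN)) {
      for (e in seq_len(nrow(evHere))) {
        ev <- evHere[e, ]
        # mother track: active track nearest the event position
        motherTrack <- NA_integer_
        if (nrow(active)) {
          evPos <- if (!is.null(ev$row) && is.finite(ev$row))
            c(ev$row, ev$col) else
            c((ev$seed1_row + ev$seed2_row) / 2,
              (ev$seed1_col + ev$seed2_col) / 2)
          dm <- sqrt((active$row - evPos[1L])^2 + (active$col - evPos[2L])^2)
          j <- which.min(dm)
          if (length(j) && dm[j] <= config$maxLinkDistance)
            motherTrack <- active$trackId[j]
        }
        dIds <- integer()
        for (s in 1:2) {
          sr <- ev[[paste0("seed", s, "_row")]]
          sc <- ev[[paste0("seed", s, "_col")]]
          cand <- setdiff(stN$id, claimedCurr)
          if (length(cand) == 0L) break
          kk <- match(cand, stN$id)
          dd <- sqrt((stN$row[kk] - sr)^2 + (stN$col[kk] - sc)^2)
          j <- which.min(dd)
          if (dd[j] <= config$maxLinkDistance) {
            dIds <- c(dIds, cand[j])
            claimedCurr <- c(claimedCurr, cand[j])
          }
        }
        if (length(dIds) == 2L && !is.na(motherTrack)) {
          dTracks <- integer(2L)
          for (s in 1:2) {
            dTracks[s] <- nextTrack
            addEntry(nextTrack, tn, stN, dIds[s], parent = motherTrack)
            k <- match(dIds[s], stN$id)
            active <- rbind(active, data.frame(
              trackId = nextTrack, lastFrame = tn, lastLabel = dIds[s],
              row = stN$row[k], col = stN$col[k], misses = 0L, flag = ""))
            nextTrack <- nextTrack + 1L
          }
          lineageRows[[length(lineageRows) + 1L]] <- data.frame(
            parent = motherTrack, daughter1 = dTracks[1L],
            daughter2 = dTracks[2L], frame = tn)
          closedTracks <- c(closedTracks, motherTrack)
        } else claimedCurr <- setdiff(claimedCurr, dIds)
      }
    }
    if (length(closedTracks))
      active <- active[!active$trackId %in% closedTracks, ]

    # --- assignment over the remaining objects --------------------------
    stNrem <- stN[!stN$id %in% claimedCurr, , drop = FALSE]
    prevStats <- data.frame(id = active$trackId,
                            area = rep(1L, nrow(active)),
                            row = active$row, col = active$col)
    # pixel overlap between last-seen labels and current labels
    ov <- labelOverlap(remapToTracks(instanceSeries[[t]], active, t),
                       instanceSeries[[tn]])
    areas <- activeAreas(active, stats, t)
    prevStats$area <- areas
    lk <- linkFramesStats(prevStats, stNrem, ov, config)

    newActive <- active[0, ]
    if (nrow(lk$pairs)) for (i in seq_len(nrow(lk$pairs))) {
      trackId <- lk$pairs$prev_id[i]
      label <- lk$pairs$curr_id[i]
      addEntry(trackId, tn, stN, label)
      k <- match(label, stN$id)
      newActive <- rbind(newActive, data.frame(
        trackId = trackId, lastFrame = tn, lastLabel = label,
        row = stN$row[k], col = stN$col[k], misses = 0L, flag = ""))
    }
    # coasting / lost / merged
    for (id in lk$unmatchedPrev) {
      a <- active[active$trackId == id, ]
      if (id %in% lk$merged) next                      # merged: closed, flagged
      if (a$misses + 1L <= config$graceFrames) {
        a$misses <- a$misses + 1L
        newActive <- rbind(newActive, a)
      }
    }
    # new tracks for unclaimed, unmatched current objects (birth order)
    um <- lk$unmatchedCurr
    if (length(um)) {
      kk <- match(um, stN$id)
      ord <- kk[order(stN$row[kk], stN$col[kk])]
      for (k in ord) {
        addEntry(nextTrack, tn, stN, stN$id[k])
        newActive <- rbind(newActive, data.frame(
          trackId = nextTrack, lastFrame = tn, lastLabel = stN$id[k],
          row = stN$row[k], col = stN$col[k], misses = 0L, flag = ""))
        nextTrack <- nextTrack + 1L
      }
    }
    active <- newActive
  }

  tracksDf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), row = numeric(),
               col = numeric(), area = integer(), label = integer(),
               parent_id = integer(), flags = character())
  # propagate parent ids onto all rows of each track
  if (nrow(tracksDf)) {
    pmap <- tapply(tracksDf$parent_id, tracksDf$track_id,
                   function(v) v[which(!is.na(v))[1L]])
    tracksDf$parent_id <- as.integer(pmap[as.character(tracksDf$track_id)])
    tracksDf <- tracksDf[order(tracksDf$track_id, tracksDf$frame), ]
    rownames(tracksDf) <- NULL
  }
  lineageDf <- if (length(lineageRows)) do.call(rbind, lineageRows) else
    data.frame(parent = integer(), daughter1 = integer(),
               daughter2 = integer(), frame = integer())
  new("TrackSet", tracks = tracksDf, lineage = lineageDf)
}

# relabel the previous frame's mask with track ids of the active set
remapToTracks <- function(prevMask, active, t) {
  out <- matrix(0L, nrow(prevMask), ncol(prevMask))
  cur <- active[active$lastFrame == t, ]
  if (nrow(cur)) {
    m <- match(prevMask, cur$lastLabel)
    out[] <- ifelse(is.na(m), 0L, cur$trackId[m])
  }
  out
}

activeAreas <- function(active, stats, t) {
  vapply(seq_len(nrow(active)), function(i) {
    if (active$lastFrame[i] == t) {
      st <- stats[[t]]
      k <- match(active$lastLabel[i], st$id)
      if (!is.na(k)) return(st$area[k])
    }
    1L
  }, 0L)
}

#' Remove short tracks
#'
#' Tracks observed in fewer than `minTrackFrames` frames are removed;
#' filtering spurious short-lived objects makes per-frame counts match the
#' true cell count far more closely.
#'
#' @param trackset a [TrackSet-class].
#' @param minTrackFrames span threshold in frames (0 = identity).
#' @return A filtered [TrackSet-class].
#' @export
filterTracks <- function(trackset, minTrackFrames = 5) {
  tr <- tracks(trackset)
  if (nrow(tr) == 0L || minTrackFrames <= 0L) return(trackset)
  len <- table(tr$track_id)
  keep <- as.integer(names(len)[len >= minTrackFrames])
  tr <- tr[tr$track_id %in% keep, ]
  lg <- lineage(trackset)
  lg <- lg[lg$parent %in% keep & lg$daughter1 %in% keep &
           lg$daughter2 %in% keep, ]
  new("TrackSet", tracks = tr, lineage = lg)
}

#' Per-frame counts of tracked cells
#'
#' @param trackset a [TrackSet-class].
#' @param nFrames total number of frames (defaults to the maximum frame
#'   present).
#' @return integer vector of per-frame counts.
#' @export
trackCounts <- function(trackset, nFrames = NULL) {
  tr <- tracks(trackset)
  if (nrow(tr) == 0L) return(integer(nFrames %||% 0L))
  n <- nFrames %||% max(tr$frame)
  tabulate(tr$frame, nbins = n)
}

#' Export a lineage forest as newick text
#'
#' Each root's subtree is written as a newick string with branch lengths in
#' frames between divisions.
#'
#' @param trackset a [TrackSet-class].
#' @return character vector, one newick string per lineage root.
#' @export
lineageNewick <- function(trackset) {
  lg <- lineage(trackset)
  tr <- tracks(trackset)
  if (nrow(tr) == 0L) return(character())
  birth <- tapply(tr$frame, tr$track_id, min)
  death <- tapply(tr$frame, tr$track_id, max)
  kids <- split(data.frame(d1 = lg$daughter1, d2 = lg$daughter2),
                lg$parent)
  rec <- function(id) {
    k <- kids[[as.character(id)]]
    len <- death[[as.character(id)]] - birth[[as.character(id)]]
    if (is.null(k)) return(sprintf("%d:%d", id, len))
    sprintf("(%s,%s)%d:%d", rec(k$d1[1L]), rec(k$d2[1L]), id, len)
  }
  roots <- setdiff(unique(tr$track_id), c(lg$daughter1, lg$daughter2))
  vapply(roots, function(r) paste0(rec(r), ";"), "")
}
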