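# Conversion of 4-class spatiotemporal masks into filtered mitosis events:
# class 2 and 3 voxels are merged and connected-component labeled in
# (x, y, time) with 26-connectivity; components are filtered by volume and
# temporal persistence; each surviving component yields one event with a
# resolved division time and two daughter seed positions.

#' Mitosis event filter
#'
#' @param minVolume minimum 3-D voxel count, exclusive (default 300: a
#'   component must be *larger than* 300 voxels).
#' @param minPersistence minimum number of frames spanned (default 10).
#'   Ground-truth-style masks built with the default annotation windows span
#'   `framesBefore + framesAfter` frames; pass
#'   `eventFilter(minPersistence = framesBefore + framesAfter)` for those.
#' @return list of class `EventFilter`.
#' @export
eventFilter <- function(minVolume = 300, minPersistence = 10) {
  stopifnot(minVolume > 0, minPersistence > 0)
  structure(list(minVolume = minVolume, minPersistence = minPersistence),
            class = "EventFilter")
}

#' Extract mitosis events from a 4-class mask
#'
#' @param classmask a [ClassMask-class] over (rows, cols, frames).
#' @param filter an [eventFilter()].
#' @return data.frame with one row per event: `event_id`, `row`, `col`
#'   (mother centroid at the last mitotic frame), `frame` (resolved division
#'   time, 1-based), `seed1_row`, `seed1_col`, `seed2_row`, `seed2_col`
#'   (daughter seeds at the division frame), `volume`, `span`.
#' @export
extractEvents <- function(classmask, filter = eventFilter()) {
  arr <- classArray(classmask)
  sel <- which(arr == 2L | arr == 3L)
  empty <- data.frame(event_id = integer(), row = numeric(), col = numeric(),
                      frame = integer(), seed1_row = numeric(),
                      seed1_col = numeric(), seed2_row = numeric(),
                      seed2_col = numeric(), volume = integer(),
                      span = integer())
  if (length(sel) == 0L) return(empty)
  d <- dim(arr)
  r <- ((sel - 1L) %% d[1L]) + 1L
  c <- (((sel - 1L) %/% d[1L]) %% d[2L]) + 1L
  t <- ((sel - 1L) %/% (d[1L] * d[2L])) + 1L
  comp <- componentLabels3D(cbind(r, c, t))
  out <- list()
  evId <- 1L
  for (cid in sort(unique(comp))) {
    m <- comp == cid
    vol <- sum(m)
    fr <- t[m]
    span <- max(fr) - min(fr) + 1L
    if (vol <= filter$minVolume || span < filter$minPersistence) next
    vox <- data.frame(row = r[m], col = c[m], frame = fr,
                      cls = arr[sel[m]])
    tDiv <- resolveDivisionTime(vox)
    seeds <- seedDaughters(vox, tDiv)
    mother <- vox[vox$cls == 2L & vox$frame < tDiv, ]
    if (nrow(mother)) {
      lastF <- max(mother$frame)
      mom <- mother[mother$frame == lastF, ]
    } else mom <- vox[vox$frame == tDiv, ]
    out[[length(out) + 1L]] <- data.frame(
      event_id = evId, row = mean(mom$row), col = mean(mom$col),
      frame = tDiv,
      seed1_row = seeds[1L, 1L], seed1_col = seeds[1L, 2L],
      seed2_row = seeds[2L, 1L], seed2_col = seeds[2L, 2L],
      volume = vol, span = span)
    evId <- evId + 1L
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Resolve the division time of one spatiotemporal component
#'
#' The division time is the first frame at which the component's class-3
#' region consists of two (or more) 2-D 4-connected objects; if no split is
#' ever observed, it is the frame at which the class-2 2-D area is maximal
#' (earliest such frame on ties).
#'
#' @param vox data.frame of component voxels: `row`, `col`, `frame`, `cls`.
#' @return Integer frame index.
#' @export
resolveDivisionTime <- function(vox) {
  fr3 <- sort(unique(vox$frame[vox$cls == 3L]))
  for (f in fr3) {
    sub <- vox[vox$frame == f & vox$cls == 3L, ]
    if (countComponents2D(sub) >= 2L) return(f)
  }
  fr2 <- vox$frame[vox$cls == 2L]
  if (length(fr2)) {
    area <- table(fr2)
    return(as.integer(names(area)[which.max(area)]))  # earliest max
  }
  if (length(fr3)) return(fr3[1L])
  min(vox$frame)
}

countComponents2D <- function(sub) {
  if (nrow(sub) == 0L) return(0L)
  nr <- max(sub$row); nc <- max(sub$col)
  m <- matrix(0L, nr, nc)
  m[cbind(sub$row, sub$col)] <- 1L
  max(labelComponents(m))
}

#' Seed the two daughter positions of an event
#'
#' If two class-3 objects exist at the division frame, the seeds are their
#' centroids. Otherwise the seeds are placed at plus/minus half the major-
#' axis length from the mother's centroid along the mother's orientation.
#'
#' @param vox component voxels (`row`, `col`, `frame`, `cls`).
#' @param tDiv resolved division frame from [resolveDivisionTime()].
#' @return 2 x 2 matrix, one `(row, col)` seed per row.
#' @export
seedDaughters <- function(vox, tDiv) {
  sub3 <- vox[vox$frame == tDiv & vox$cls == 3L, ]
  if (nrow(sub3)) {
    nr <- max(sub3$row); nc <- max(sub3$col)
    m <- matrix(0L, nr, nc)
    m[cbind(sub3$row, sub3$col)] <- 1L
    lab <- labelComponents(m)
    st <- objectStats(lab)
    if (nrow(st) >= 2L) {
      st <- st[order(-st$area), ][1:2, ]
      return(cbind(st$row, st$col))
    }
  }
  # fallback: mother region (class 2 voxels at the last frame before tDiv,
  # or the whole component at tDiv)
  mother <- vox[vox$cls == 2L & vox$frame < tDiv, ]
  reg <- if (nrow(mother)) mother[mother$frame == max(mother$frame), ] else
    vox[vox$frame == tDiv, ]
  if (nrow(reg) <= 1L) {
    warning("degenerate mother region: coincident daughter seeds")
    p <- c(mean(reg$row), mean(reg$col))
    return(rbind(p, p, deparse.level = 0))
  }
  nr <- max(reg$row); nc <- max(reg$col)
  m <- matrix(0L, nr, nc)
  m[cbind(reg$row, reg$col)] <- 1L
  st <- objectStats(m)
  half <- st$major[1L] / 2
  dir <- c(cos(st$theta[1L]), sin(st$theta[1L]))
  ctr <- c(st$row[1L], st$col[1L])
  rbind(ctr + half * dir, ctr - half * dir, deparse.level = 0)
}
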