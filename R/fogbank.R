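# FogBank-style separation of touching objects. The algorithm follows the
# published idea of seed detection by descending distance/intensity levels
# followed by constrained region growing:
#   seeds  = plateau maxima of the (quantized) Euclidean distance transform
#            that survive erosion of the mask by a disk of radius erode_size;
#   growth = synchronized multi-source geodesic expansion of the seeds inside
#            the mask (ties resolved toward the lower seed label);
#   filter = objects below min_size merged into their largest touching
#            neighbor, or dropped when isolated.

#' FogBank parameters
#'
#' @param erodeSize structuring-element radius in pixels used for seed
#'   survival (default 2, center of the best-performing band 1-4).
#' @param minSize minimum object area in pixels (default 9, center of the
#'   best-performing band 8-10).
#' @return A validated list of class `FogbankParams`.
#' @export
fogbankParams <- function(erodeSize = 2, minSize = 9) {
  stopifnot(erodeSize >= 1, minSize >= 1)
  structure(list(erodeSize = erodeSize, minSize = minSize),
            class = "FogbankParams")
}

#' Separate touching objects in a binary mask
#'
#' Every foreground pixel receives exactly one positive label; touching
#' convex objects (nuclei) are split along the distance-transform valleys
#' between their seeds. When an `intensity` image is supplied, seeds are
#' taken from its maxima instead of the distance transform's (intensity-
#' guided variant); geometry of the growth is unchanged.
#'
#' @param mask binary (logical or 0/1) matrix.
#' @param intensity optional numeric matrix of the same shape guiding seed
#'   detection (e.g. a fluorescence image).
#' @param params a [fogbankParams()].
#' @return Integer instance label matrix, same shape as `mask`.
#' @export
separateObjects <- function(mask, intensity = NULL, params = fogbankParams()) {
  if (!is.null(intensity) && !identical(dim(intensity), dim(mask)))
    stop("intensity must have the same shape as mask")
  bin <- mask > 0
  if (!any(bin)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    return(out)
  }
  dt <- EBImage::distmap(matrix(as.numeric(bin), nrow(bin)))
  dt <- matrix(as.numeric(dt), nrow(bin))
  if (is.null(intensity)) {
    # seed surface: lightly smoothed distance transform, quantized in
    # erodeSize steps. Smoothing keeps 1-px boundary nicks from cutting a
    # ridge plateau; the step size means dips shallower than the erosion
    # element cannot split one, while true inter-object necks (wide and at
    # least one full level deep) still do.
    dts <- gaussianBlur(dt, 1)
    dts[!bin] <- 0
    qs <- ceiling(dts / max(1, params$erodeSize))
  } else {                           # intensity-guided variant: 32 levels
    rng <- range(intensity[bin])
    lev <- if (diff(rng) > 0) diff(rng) / 32 else 1
    qs <- pmax(1, ceiling((intensity - rng[1L]) / lev))
  }
  qs[!bin] <- 0
  seeds <- descendLevels(qs, dt, bin, params$erodeSize)
  # objects whose interior never survives the erosion seed themselves whole
  comp <- labelComponents(bin)
  seeded <- unique(comp[seeds > 0L])
  orphan <- bin & !matrix(comp %in% seeded, nrow(bin))
  if (any(orphan)) {
    extra <- labelComponents(orphan)
    extra[extra > 0L] <- extra[extra > 0L] + max(seeds)
    seeds <- seeds + extra
  }
  labels <- growSeeds(seeds, bin)
  enforceMinSize(labels, params$minSize)
}

# Seed detection by successive level descent: starting from the top
# quantized level, any connected component of {qs >= L} that contains no
# existing seed spawns a new one (its pixels at that level). Components that
# already hold a seed never split, so ridge/saddle plateaus between objects
# do not over-seed. Seeds are only created at depths exceeding erodeSize:
# objects thinner than the erosion element never seed themselves and are
# handled by the caller's orphan rule.
descendLevels <- function(qs, dt, bin, erodeSize) {
  seeds <- matrix(0L, nrow(bin), ncol(bin))
  nextSeed <- 1L
  top <- max(qs)
  if (top < 1) return(seeds)
  for (L in seq(top, 1L)) {
    reg <- qs >= L & bin
    comp <- labelComponents(reg)
    idx <- which(comp > 0L)
    if (length(idx) == 0L) next
    cid <- comp[idx]
    seeded <- unique(cid[seeds[idx] > 0L])
    keep <- !(cid %in% seeded)
    if (!any(keep)) next
    maxdt <- tapply(dt[idx[keep]], cid[keep], max)
    newIds <- as.integer(names(maxdt)[maxdt > erodeSize])
    if (length(newIds)) {
      hit <- keep & cid %in% newIds
      seeds[idx[hit]] <- nextSeed + match(cid[hit], newIds) - 1L
      nextSeed <- nextSeed + length(newIds)
    }
  }
  seeds
}

# Synchronized multi-source BFS: geodesic nearest-seed assignment within the
# mask; simultaneous arrivals resolve to the lower seed id.
growSeeds <- function(seeds, bin) {
  labels <- seeds
  labels[!bin] <- 0L
  repeat {
    cand <- matrix(Inf, nrow(labels), ncol(labels))
    for (k in seq_len(nrow(neighborOffsets8))) {
      s <- shiftMatrix(labels, neighborOffsets8[k, 1L], neighborOffsets8[k, 2L])
      s[s == 0L] <- Inf
      cand <- pmin(cand, s)
    }
    new <- bin & labels == 0L & is.finite(cand)
    if (!any(new)) break
    labels[new] <- as.integer(cand[new])
  }
  labels
}

# Merge sub-minimum objects into their largest touching neighbor; isolated
# small objects are dropped. Small objects are processed smallest-first
# within a pass; passes repeat until no sub-minimum object remains. Labels
# are then compacted to 1..n in order of first appearance (column-major),
# which makes the output deterministic.
enforceMinSize <- function(labels, minSize) {
  repeat {
    st <- objectStats(labels)
    small <- st$id[st$area < minSize]
    if (length(small) == 0L) break
    # adjacency via 8-neighbor shifts, one computation per pass
    adj <- list()
    for (k in seq_len(nrow(neighborOffsets8))) {
      s <- shiftMatrix(labels, neighborOffsets8[k, 1L], neighborOffsets8[k, 2L])
      sel <- labels > 0L & s > 0L & labels != s
      if (any(sel)) adj[[length(adj) + 1L]] <-
          unique(data.frame(a = labels[sel], b = s[sel]))
    }
    adj <- if (length(adj)) unique(do.call(rbind, adj)) else
      data.frame(a = integer(), b = integer())
    areaOf <- setNames(st$area, st$id)
    relabel <- setNames(st$id, st$id)   # current label of each original id
    ord <- small[order(st$area[match(small, st$id)])]
    for (tsmall in ord) {
      nb <- unique(relabel[as.character(adj$b[adj$a == tsmall])])
      nb <- nb[nb != relabel[[as.character(tsmall)]]]
      if (length(nb) == 0L) {
        relabel[as.character(tsmall)] <- 0L
      } else {
        tgt <- nb[which.max(areaOf[as.character(nb)])]
        me <- relabel[[as.character(tsmall)]]
        areaOf[as.character(tgt)] <- areaOf[[as.character(tgt)]] +
          areaOf[[as.character(me)]]
        relabel[relabel == me] <- tgt
      }
    }
    m <- match(labels, as.integer(names(relabel)))
    upd <- !is.na(m)
    labels[upd] <- as.integer(relabel)[m[upd]]
  }
  compactLabels(labels)
}

compactLabels <- function(labels) {
  ids <- unique(labels[labels > 0L])
  if (length(ids) == 0L) return(labels)
  first <- vapply(ids, function(i) which(labels == i)[1L], 0L)
  ids <- ids[order(first)]
  out <- labels
  out[labels > 0L] <- match(labels[labels > 0L], ids)
  storage.mode(out) <- "integer"
  out
}

#' Sweep FogBank parameters against reference instances
#'
#' Runs [separateObjects()] over a series of binary masks for every
#' combination of erosion size and minimum object size, matches the result to
#' reference instance masks with [matchObjects()] and reports the pooled
#' detection F1 per parameter pair.
#'
#' @param maskSeries list of binary matrices (one per frame).
#' @param referenceInstances list of integer instance masks, same length.
#' @param erodeRange integer vector of erosion sizes (e.g. 1:5).
#' @param minSizeRange integer vector of minimum sizes (e.g. 5:15).
#' @param intensitySeries optional list of intensity images for seed guidance.
#' @param matchCfg a [matchConfig()] used for evaluation.
#' @return data.frame with columns `erodeSize`, `minSize`, `TP`, `FP`, `FN`,
#'   `F1`.
#' @export
sweepFogbankParams <- function(maskSeries, referenceInstances,
                               erodeRange = 1:5, minSizeRange = 5:15,
                               intensitySeries = NULL,
                               matchCfg = matchConfig()) {
  if (length(erodeRange) == 0L || length(minSizeRange) == 0L)
    stop("empty parameter range")
  stopifnot(length(maskSeries) == length(referenceInstances))
  grid <- expand.grid(erodeSize = erodeRange, minSize = minSizeRange)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- fogbankParams(grid$erodeSize[i], grid$minSize[i])
    tp <- fp <- fn <- 0L
    for (f in seq_along(maskSeries)) {
      inten <- if (is.null(intensitySeries)) NULL else intensitySeries[[f]]
      lab <- separateObjects(maskSeries[[f]], inten, p)
      m <- matchObjects(referenceInstances[[f]], lab, matchCfg)
      tp <- tp + m@TP; fp <- fp + m@FP; fn <- fn + m@FN
    }
    f1 <- if (tp + fp + fn == 0L) NA_real_ else 2 * tp / (2 * tp + fn + fp)
    data.frame(erodeSize = grid$erodeSize[i], minSize = grid$minSize[i],
               TP = tp, FP = fp, FN = fn, F1 = f1)
  })
  do.call(rbind, res)
}
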