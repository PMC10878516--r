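# Internal helpers shared across modules: matrix shifting, label statistics,
# overlap tables, reproducible local RNG. Coordinates are (row, col), 1-based
# in R storage; frames are 1-based list positions (0-based times only in
# documentation of elapsed time via Calibration).

# Shift a matrix by (dr, dc), padding with `fill`.
shiftMatrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighborOffsets8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

# 3x3 grayscale maximum filter via shifts (replicate border).
maxFilter3 <- function(m) {
  out <- m
  for (k in seq_len(nrow(neighborOffsets8))) {
    out <- pmax(out, shiftMatrix(m, neighborOffsets8[k, 1L],
                                 neighborOffsets8[k, 2L], fill = -Inf))
  }
  out
}

# Per-object statistics of an instance label matrix.
# Returns data.frame(id, area, row, col, major, minor, theta); `major` is the
# full major-axis length (4 * sqrt(largest eigenvalue of the coordinate
# covariance)), `theta` its orientation in radians measured from the row axis.
objectStats <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(data.frame(id = integer(), area = integer(), row = numeric(),
                      col = numeric(), major = numeric(), minor = numeric(),
                      theta = numeric()))
  lab <- labels[idx]
  nr <- nrow(labels)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  area <- as.integer(table(f))
  mr <- tapply(r, f, mean)
  mc <- tapply(c, f, mean)
  # central second moments
  dr2 <- tapply((r - mr[f])^2, f, mean)
  dc2 <- tapply((c - mc[f])^2, f, mean)
  drc <- tapply((r - mr[f]) * (c - mc[f]), f, mean)
  tr <- dr2 + dc2
  det <- dr2 * dc2 - drc^2
  disc <- sqrt(pmax(0, (tr / 2)^2 - det + 1e-12))
  l1 <- tr / 2 + disc
  l2 <- pmax(0, tr / 2 - disc)
  theta <- 0.5 * atan2(2 * drc, dr2 - dc2)
  data.frame(id = ids, area = area, row = as.numeric(mr), col = as.numeric(mc),
             major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
             theta = as.numeric(theta), row.names = NULL)
}

# Cross-tabulated overlap (pixel counts) between two label matrices.
# Returns data.frame(a, b, n) for label pairs with both labels > 0.
labelOverlap <- function(a, b) {
  sel <- a > 0L & b > 0L
  if (!any(sel))
    return(data.frame(a = integer(), b = integer(), n = integer()))
  key <- paste(a[sel], b[sel])
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  data.frame(a = as.integer(vapply(parts, `[`, "", 1L)),
             b = as.integer(vapply(parts, `[`, "", 2L)),
             n = as.integer(tab), row.names = NULL)
}

# Evaluate expr with a private RNG stream; the caller's RNG state is
# untouched. Seeds are kept below 2^31 by callers.
withSeed <- function(seed, expr) {
  prev <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(prev)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", prev, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# 2-D connected-component labeling, 4-connectivity (EBImage::bwlabel).
labelComponents <- function(binary) {
  m <- EBImage::bwlabel(matrix(as.numeric(binary > 0), nrow(binary)))
  storage.mode(m) <- "integer"
  dim(m) <- dim(binary)
  m
}

# Connected components of a sparse voxel set in (row, col, frame) with
# 26-connectivity. `vox` is a 3-column integer matrix. Returns an integer
# component id per voxel row.
componentLabels3D <- function(vox) {
  n <- nrow(vox)
  if (n == 0L) return(integer())
  nr <- max(vox[, 1L]) + 1L
  nc <- max(vox[, 2L]) + 1L
  enc <- function(r, c, t) (as.numeric(t) * nc + c) * nr + r
  keys <- enc(vox[, 1L], vox[, 2L], vox[, 3L])
  edges <- list(); k <- 1L
  offs <- expand.grid(dr = -1:1, dc = -1:1, dt = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0 & offs$dt == 0), ]
  # half the offsets suffice for undirected edges
  offs <- offs[seq_len(13L), ]
  for (i in seq_len(nrow(offs))) {
    nk <- enc(vox[, 1L] + offs$dr[i], vox[, 2L] + offs$dc[i],
              vox[, 3L] + offs$dt[i])
    j <- match(nk, keys)
    hit <- which(!is.na(j))
    if (length(hit)) {
      edges[[k]] <- cbind(hit, as.integer(j[hit])); k <- k + 1L
    }
  }
  if (length(edges) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  as.integer(comp[seq_len(n)])
}

# Linear index helpers
whichIdx <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}
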