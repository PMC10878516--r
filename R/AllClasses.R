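#' @import methods
#' @importFrom stats rnorm runif rbinom quantile median sd var setNames
#' @importFrom utils head tail
NULL

#' Spatial and temporal calibration of a time-lapse
#'
#' Couples pixel geometry to physical units. `pixelArea` is the area imaged
#' by one pixel in square micrometers, `frameInterval` the time between
#' consecutive frames in minutes. Defaults correspond to a 10X objective on a
#' typical sCMOS camera (0.406 um^2 per pixel) with 2-minute acquisition.
#'
#' @slot pixelArea numeric(1), um^2 per pixel, > 0.
#' @slot frameInterval numeric(1), minutes per frame, > 0.
#' @exportClass Calibration
setClass("Calibration",
  representation(pixelArea = "numeric", frameInterval = "numeric"),
  prototype(pixelArea = 0.406, frameInterval = 2))

setValidity("Calibration", function(object) {
  if (length(object@pixelArea) != 1L || !is.finite(object@pixelArea) ||
      object@pixelArea <= 0)
    return("pixelArea must be a single positive number (um^2)")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number (minutes)")
  TRUE
})

#' Construct a Calibration
#'
#' @param pixelArea area per pixel in um^2 (default 0.406).
#' @param frameInterval minutes per frame (default 2).
#' @return A [Calibration-class] object.
#' @examples
#' calibration()
#' calibration(pixelArea = 0.65, frameInterval = 5)
#' @export
calibration <- function(pixelArea = 0.406, frameInterval = 2) {
  new("Calibration", pixelArea = pixelArea, frameInterval = frameInterval)
}

#' @describeIn calibration area per pixel in um^2
#' @param object a `Calibration`, or an object carrying one.
#' @export
pixelArea <- function(object) {
  if (is(object, "TimeLapse")) object <- object@calibration
  object@pixelArea
}

#' @describeIn calibration minutes per frame
#' @export
frameInterval <- function(object) {
  if (is(object, "TimeLapse")) object <- object@calibration
  object@frameInterval
}

#' An ordered grayscale image stack
#'
#' The universal image container of the pipeline: a list of 2-D numeric
#' matrices of identical shape (row, col indexing, 0-based frame times via
#' positions 1..n), plus a [Calibration-class]. Optionally records how many
#' z-planes were acquired per timepoint before focus selection.
#'
#' @slot frames list of numeric matrices, all the same dimension, finite.
#' @slot calibration a [Calibration-class].
#' @slot zPlanes integer(1), z-planes acquired per timepoint (informational).
#' @exportClass TimeLapse
setClass("TimeLapse",
  representation(frames = "list", calibration = "Calibration",
                 zPlanes = "integer"),
  prototype(zPlanes = 1L))

setValidity("TimeLapse", function(object) {
  fr <- object@frames
  if (length(fr) < 1L) return("a TimeLapse needs at least one frame")
  if (!all(vapply(fr, is.matrix, logical(1))))
    return("all frames must be 2-D matrices")
  d <- dim(fr[[1L]])
  same <- vapply(fr, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) return("all frames must share one height/width")
  fin <- vapply(fr, function(f) all(is.finite(f)), logical(1))
  if (!all(fin)) return("pixel values must be finite")
  TRUE
})

#' Construct a TimeLapse
#'
#' @param frames a list of numeric matrices (identical shape) or a single
#'   matrix, or a 3-D array sliced along its third dimension.
#' @param calibration a [Calibration-class] (default [calibration()]).
#' @param zPlanes number of z-planes acquired per timepoint, informational.
#' @return A [TimeLapse-class].
#' @export
timeLapse <- function(frames, calibration = colonytrack::calibration(),
                      zPlanes = 1L) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]), function(k) frames[, , k])
  new("TimeLapse", frames = frames, calibration = calibration,
      zPlanes = as.integer(zPlanes))
}

#' @describeIn timeLapse list of frame matrices
#' @param x a `TimeLapse`.
#' @export
frames <- function(x) x@frames

#' @describeIn timeLapse number of frames
#' @export
nFrames <- function(x) {
  if (is(x, "ClassMask")) return(dim(x@labels)[3L])
  length(x@frames)
}

#' @describeIn timeLapse height/width of each frame
#' @export
frameDim <- function(x) {
  if (is(x, "ClassMask")) return(dim(x@labels)[1:2])
  dim(x@frames[[1L]])
}

setMethod("show", "TimeLapse", function(object) {
  d <- frameDim(object)
  cat(sprintf("TimeLapse: %d frame(s) of %d x %d px, %.3g um^2/px, %.3g min/frame\n",
              nFrames(object), d[1L], d[2L],
              object@calibration@pixelArea, object@calibration@frameInterval))
})

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.3g um^2/px, %.3g min/frame\n",
              object@pixelArea, object@frameInterval))
})

#' Per-voxel class labels for nuclei and mitosis
#'
#' A dense (rows x cols x frames) integer array with values 0 (background),
#' 1 (nucleus), 2 (mitotic nucleus, condensed DNA before division) and
#' 3 (daughter nucleus immediately after division). Single frames are stored
#' with a third dimension of 1.
#'
#' @slot labels integer array, values in {0, 1, 2, 3}.
#' @exportClass ClassMask
setClass("ClassMask", representation(labels = "array"))

setValidity("ClassMask", function(object) {
  a <- object@labels
  if (length(dim(a)) != 3L) return("labels must be a 3-D (rows, cols, frames) array")
  u <- unique(as.vector(a))
  if (!all(u %in% 0:3)) return("class labels must be within {0,1,2,3}")
  TRUE
})

#' Construct a ClassMask
#'
#' @param labels integer matrix (one frame) or 3-D array (rows, cols, frames)
#'   with values in {0,1,2,3}.
#' @return A [ClassMask-class].
#' @export
classMask <- function(labels) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  storage.mode(labels) <- "integer"
  new("ClassMask", labels = labels)
}

#' @describeIn classMask the underlying integer array
#' @param x a `ClassMask`.
#' @export
classArray <- function(x) x@labels

setMethod("show", "ClassMask", function(object) {
  d <- dim(object@labels)
  tab <- tabulate(as.vector(object@labels) + 1L, nbins = 4L)
  cat(sprintf("ClassMask: %d x %d x %d; voxels by class 0..3: %s\n",
              d[1L], d[2L], d[3L], paste(tab, collapse = " / ")))
})

#' Result of assignment-based object matching
#'
#' Produced by [matchObjects()] and [matchMitoses()]. `pairs` holds one row
#' per matched (reference, test) pair; unmatched test objects are counted as
#' false positives ("additional objects"), unmatched reference objects as
#' false negatives ("missing objects").
#'
#' @slot TP integer(1) matched pairs.
#' @slot FP integer(1) unmatched test objects.
#' @slot FN integer(1) unmatched reference objects.
#' @slot pairs data.frame with columns `ref`, `test`, `distance`, `iou`.
#' @exportClass MatchResult
setClass("MatchResult",
  representation(TP = "integer", FP = "integer", FN = "integer",
                 pairs = "data.frame"))

setValidity("MatchResult", function(object) {
  if (object@TP != nrow(object@pairs)) return("TP must equal nrow(pairs)")
  if (object@FP < 0L || object@FN < 0L) return("FP/FN must be non-negative")
  TRUE
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: TP %d, FP %d (additional), FN %d (missing)\n",
              object@TP, object@FP, object@FN))
})

#' Tracks plus lineage from the cell tracker
#'
#' `tracks` has one row per (track, frame) observation with columns
#' `track_id`, `frame` (1-based), `row`, `col`, `area`, `label` (instance
#' label in that frame), `parent_id` (NA for roots) and `flags`
#' (""/"merged"). `lineage` has one row per division with columns `parent`,
#' `daughter1`, `daughter2`, `frame`.
#'
#' @slot tracks data.frame of per-frame track entries.
#' @slot lineage data.frame of parent -> (daughter, daughter) links.
#' @exportClass TrackSet
setClass("TrackSet",
  representation(tracks = "data.frame", lineage = "data.frame"))

setValidity("TrackSet", function(object) {
  tr <- object@tracks
  need <- c("track_id", "frame", "row", "col", "area", "parent_id")
  if (!all(need %in% names(tr)))
    return(paste("tracks must have columns:", paste(need, collapse = ", ")))
  if (nrow(tr)) {
    dup <- any(duplicated(tr[, c("track_id", "frame")]))
    if (dup) return("a track may not contain two entries in one frame")
  }
  lg <- object@lineage
  if (nrow(lg) && !all(c("parent", "daughter1", "daughter2", "frame") %in% names(lg)))
    return("lineage must have columns parent, daughter1, daughter2, frame")
  TRUE
})

#' @describeIn trackCells per-frame track table of a `TrackSet`
#' @param x a `TrackSet`.
#' @export
tracks <- function(x) x@tracks

#' @describeIn trackCells division edge table of a `TrackSet`
#' @export
lineage <- function(x) x@lineage

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d track(s), %d frame-entries, %d division(s)\n",
              length(unique(object@tracks$track_id)), nrow(object@tracks),
              nrow(object@lineage)))
})

#' A pixel/voxel classifier instance
#'
#' The pluggable predictor contract of the segmentation stage: `predictFun`
#' maps a z-score-normalized frame (plus its frame index, so ground-truth
#' oracles can look up their scene) to a (rows x cols x nClasses) array of
#' per-pixel class probabilities summing to 1. `mode` is `"2D-binary"`
#' (classes background/nucleus) or `"3D-4class"` (classes 0..3).
#'
#' @slot mode character(1), "2D-binary" or "3D-4class".
#' @slot predictFun function(frame, frameIndex, stack) -> probability array.
#' @slot spec list, the [classifierSpec()] used (possibly empty for oracles).
#' @slot tag character(1) identifying the training seed / origin.
#' @exportClass Predictor
setClass("Predictor",
  representation(mode = "character", predictFun = "function",
                 spec = "list", tag = "character"))

setValidity("Predictor", function(object) {
  if (!object@mode %in% c("2D-binary", "3D-4class"))
    return("mode must be '2D-binary' or '3D-4class'")
  TRUE
})

setMethod("show", "Predictor", function(object) {
  cat(sprintf("Predictor <%s> mode %s\n", object@tag, object@mode))
})

#' @describeIn trainClassifier number of classes predicted by a `Predictor`
#' @export
nClasses <- function(x) if (x@mode == "2D-binary") 2L else 4L
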