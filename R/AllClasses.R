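#' @import methods
NULL

#' Approximate-entropy parameters
#'
#' Bundles the embedding dimension \eqn{m} and the tolerance rule for the
#' ApEn estimator.  The tolerance \eqn{r} is never given in signal units:
#' it is a multiplier of a standard deviation, either the SD of each
#' segment the entropy is computed on (\code{"per_segment"}, the default)
#' or one SD supplied for the whole series (\code{"global"}).  Tying
#' \eqn{r} to the SD makes the entropy invariant to the units and offset
#' of the gaze coordinate.
#'
#' @slot m integer embedding dimension, >= 1.
#' @slot rMultiplier positive multiplier of the SD; 0.2 by default.
#' @slot rPolicy \code{"per_segment"} or \code{"global"}.
#' @export
setClass("ApEnParams",
  representation(m = "integer", rMultiplier = "numeric", rPolicy = "character"),
  prototype(m = 2L, rMultiplier = 0.2, rPolicy = "per_segment"))

setValidity("ApEnParams", function(object) {
  msg <- character()
  if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
    msg <- c(msg, "'m' must be a single integer >= 1")
  if (length(object@rMultiplier) != 1L || !is.finite(object@rMultiplier) ||
      object@rMultiplier <= 0)
    msg <- c(msg, "'rMultiplier' must be a single positive number")
  if (length(object@rPolicy) != 1L ||
      !object@rPolicy %in% c("per_segment", "global"))
    msg <- c(msg, "'rPolicy' must be \"per_segment\" or \"global\"")
  if (length(msg)) msg else TRUE
})

#' @param m integer embedding dimension.
#' @param rMultiplier positive multiplier of the SD.
#' @param rPolicy \code{"per_segment"} or \code{"global"}.
#' @rdname ApEnParams-class
#' @return an \code{ApEnParams} object.
#' @examples
#' apEnParams()            # m = 2, r = 0.2 * SD of each segment
#' apEnParams(m = 1L, rMultiplier = 0.15)
#' @export
apEnParams <- function(m = 2L, rMultiplier = 0.2, rPolicy = "per_segment") {
  new("ApEnParams", m = as.integer(m), rMultiplier = as.numeric(rMultiplier),
      rPolicy = match.arg(rPolicy, c("per_segment", "global")))
}

#' Geometry of a Multilevel Entropy Map
#'
#' A map covers a velocity series of \code{nemr} samples with a dyadic
#' grid: level \eqn{l} uses contiguous windows of \code{nss * 2^(l-1)}
#' samples, so level 1 has \code{nemr/nss} cells and the top level a
#' single cell.  Full coverage requires \code{nemr == nss * 2^(levels-1)}.
#' The defaults (2048 samples, 64-sample base segment, 6 levels) give the
#' 32/16/8/4/2/1 cell pyramid used throughout.
#'
#' @slot nemr total samples per velocity series.
#' @slot nss finest segment size (level 1).
#' @slot levels number of dyadic levels.
#' @export
setClass("MemSpec",
  representation(nemr = "integer", nss = "integer", levels = "integer"),
  prototype(nemr = 2048L, nss = 64L, levels = 6L))

setValidity("MemSpec", function(object) {
  msg <- character()
  ok1 <- function(z) length(z) == 1L && !is.na(z) && z >= 1L
  if (!ok1(object@nemr) || !ok1(object@nss) || !ok1(object@levels))
    return("'nemr', 'nss' and 'levels' must each be a single positive integer")
  if (object@nemr != object@nss * 2L^(object@levels - 1L))
    msg <- c(msg, sprintf("full dyadic coverage requires nemr == nss * 2^(levels-1); got %d != %d * 2^%d",
                          object@nemr, object@nss, object@levels - 1L))
  if (length(msg)) msg else TRUE
})

#' @param nemr,nss,levels map geometry, see slots.
#' @rdname MemSpec-class
#' @return a \code{MemSpec} object.
#' @examples
#' memSpec()                    # 2048 = 64 * 2^5, 6 levels
#' memSpec(256, 32, 4)
#' @export
memSpec <- function(nemr = 2048L, nss = 64L, levels = 6L) {
  new("MemSpec", nemr = as.integer(nemr), nss = as.integer(nss),
      levels = as.integer(levels))
}

#' One participant-session gaze recording
#'
#' Raw sampled gaze positions for one participant and session, together
#' with the stimulus schedule of the jumping-point paradigm (onset time
#' of each stimulus position).  Timestamps are in milliseconds and must
#' be strictly increasing with spacing consistent with the declared
#' sampling rate; segmentation into per-stimulus series is sample-index
#' based, timestamps serve only to locate onsets.
#'
#' @slot participant,session identifiers.
#' @slot fs sampling rate in Hz.
#' @slot t timestamps in ms.
#' @slot x horizontal gaze coordinate (screen-normalized or device units).
#' @slot y optional vertical coordinate (length 0 when absent).
#' @slot onsets data.frame with columns \code{stimulus_index}, \code{onset_ms}.
#' @export
setClass("GazeRecording",
  representation(participant = "character", session = "character",
                 fs = "numeric", t = "numeric", x = "numeric", y = "numeric",
                 onsets = "data.frame"))

setValidity("GazeRecording", function(object) {
  msg <- character()
  n <- length(object@t)
  if (length(object@x) != n)
    msg <- c(msg, "'t' and 'x' must have equal length")
  if (length(object@y) && length(object@y) != n)
    msg <- c(msg, "'y', when present, must match the length of 'x'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive sampling rate in Hz")
  if (n >= 2L) {
    dt <- diff(object@t)
    if (any(dt <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
    else {
      nominal <- 1000 / object@fs
      if (abs(stats::median(dt) - nominal) > 0.1 * nominal)
        msg <- c(msg, sprintf(
          "median sample spacing %.4g ms inconsistent with fs = %g Hz",
          stats::median(dt), object@fs))
    }
  }
  on <- object@onsets
  if (!all(c("stimulus_index", "onset_ms") %in% names(on)))
    msg <- c(msg, "'onsets' needs columns stimulus_index, onset_ms")
  else {
    if (is.unsorted(on$onset_ms, strictly = TRUE))
      msg <- c(msg, "stimulus onsets must be strictly increasing in time")
    if (anyDuplicated(on$stimulus_index))
      msg <- c(msg, "stimulus indices must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @param participant,session,fs,t,x,y,onsets see slots.
#' @rdname GazeRecording-class
#' @return a validated \code{GazeRecording}.
#' @export
gazeRecording <- function(t, x, fs, y = numeric(0),
                          participant = "P01", session = "S1",
                          onsets = data.frame(stimulus_index = integer(0),
                                              onset_ms = numeric(0))) {
  new("GazeRecording", participant = as.character(participant),
      session = as.character(session), fs = as.numeric(fs),
      t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
      onsets = onsets)
}

#' One per-stimulus velocity series
#'
#' The eye-movement (EM) series for a single stimulus presentation:
#' horizontal velocity obtained by two-point differentiation of the
#' position samples that follow the stimulus onset, truncated to a fixed
#' power-of-two length so the dyadic entropy grid covers it exactly.
#'
#' @slot participant,session identifiers; \code{stimulus} the stimulus index.
#' @slot v velocity samples (coordinate units per second).
#' @slot fs sampling rate in Hz.
#' @export
setClass("EMSeries",
  representation(participant = "character", session = "character",
                 stimulus = "integer", v = "numeric", fs = "numeric"))

setValidity("EMSeries", function(object) {
  msg <- character()
  if (!length(object@v))
    msg <- c(msg, "'v' must be non-empty")
  if (anyNA(object@v) || any(!is.finite(object@v)))
    msg <- c(msg, "all velocity samples must be finite")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param v,fs,participant,session,stimulus see slots.
#' @rdname EMSeries-class
#' @return a validated \code{EMSeries}.
#' @export
emSeries <- function(v, fs, participant = "P01", session = "S1",
                     stimulus = 1L) {
  new("EMSeries", participant = as.character(participant),
      session = as.character(session), stimulus = as.integer(stimulus),
      v = as.numeric(v), fs = as.numeric(fs))
}

#' Multilevel Entropy Map
#'
#' The triangular grid of per-segment approximate entropies for one EM
#' series (or an average over many): cell \code{MEM(l, s)} holds the ApEn
#' of the \code{s}-th window of \code{nss * 2^(l-1)} velocity samples.
#' Cells whose segment has zero SD are stored as 0 and flagged degenerate
#' (a constant signal is maximally regular).
#'
#' Levels and segments are 1-based, matching the \code{MEM(l, s)}
#' notation used in reports and serialized files.
#'
#' @slot spec the \linkS4class{MemSpec} geometry.
#' @slot cells list of numeric vectors, one per level, finest first.
#' @slot degenerate list of logical vectors parallel to \code{cells}.
#' @slot provenance named list: participant/session/stimulus of the source
#'   series, or \code{source = "averaged"} for averaged maps.
#' @export
setClass("MultilevelEntropyMap",
  representation(spec = "MemSpec", cells = "list", degenerate = "list",
                 provenance = "list"))

setValidity("MultilevelEntropyMap", function(object) {
  msg <- character()
  sp <- object@spec
  want <- sp@nemr %/% (sp@nss * 2L^(seq_len(sp@levels) - 1L))
  if (length(object@cells) != sp@levels ||
      !all(lengths(object@cells) == want))
    msg <- c(msg, "cell layout does not match the spec's dyadic pyramid")
  if (!all(lengths(object@degenerate) == lengths(object@cells)))
    msg <- c(msg, "'degenerate' must parallel 'cells'")
  vals <- unlist(object@cells, use.names = FALSE)
  if (anyNA(vals) || any(!is.finite(vals)))
    msg <- c(msg, "all cells must be finite")
  else if (any(vals < -1e-8))
    msg <- c(msg, "ApEn cells must be non-negative (up to floating error)")
  if (length(msg)) msg else TRUE
})

#' Classification report for one feature set
#'
#' Metrics of the leave-one-participant-session-out knn evaluation of one
#' feature set over a grid of neighbourhood sizes \code{k}: overall
#' accuracy, per-segment (= per-class) accuracy averaged over folds, the
#' pooled confusion matrix, the best-classified segment, and one-vs-rest
#' sensitivity/specificity for a designated class (by default the best
#' segment at each k).
#'
#' @slot featureSet the set name, e.g. \code{"set128_256_512"}.
#' @slot kGrid integer vector of k values.
#' @slot classRanges labels of the classes as sample-time ranges in ms.
#' @slot overall named numeric, overall accuracy per k.
#' @slot perSegment numeric matrix, classes x k, fold-averaged accuracy.
#' @slot confusion list of pooled confusion matrices (truth rows), one per k.
#' @slot bestSegment named integer, argmax per-segment accuracy per k.
#' @slot sensitivity,specificity named numeric per k, for the designated class.
#' @slot designatedClass integer class the sensitivity/specificity refer to
#'   (one per k).
#' @slot nFolds number of cross-validation folds.
#' @export
setClass("EvalReport",
  representation(featureSet = "character", kGrid = "integer",
                 classRanges = "character", overall = "numeric",
                 perSegment = "matrix", confusion = "list",
                 bestSegment = "integer", sensitivity = "numeric",
                 specificity = "numeric", designatedClass = "integer",
                 nFolds = "integer"))

setValidity("EvalReport", function(object) {
  msg <- character()
  nk <- length(object@kGrid)
  if (length(object@overall) != nk || ncol(object@perSegment) != nk ||
      length(object@confusion) != nk)
    msg <- c(msg, "per-k slots must align with 'kGrid'")
  if (any(object@overall < 0 | object@overall > 1) ||
      any(object@perSegment < 0 | object@perSegment > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
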