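#' @rdname levelSizes
#' @export
setGeneric("levelSizes", function(x) standardGeneric("levelSizes"))

#' @rdname memCell
#' @export
setGeneric("memCell", function(x, level, segment) standardGeneric("memCell"))

#' @rdname accessors
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' Segment sizes of the dyadic grid
#'
#' Window length, in samples, of every level of a map or spec, finest
#' level first (e.g. 64, 128, ..., 2048 for the default geometry).
#'
#' @param x a \linkS4class{MemSpec} or \linkS4class{MultilevelEntropyMap}.
#' @return integer vector of length \code{levels}.
#' @name levelSizes
#' @aliases levelSizes,MemSpec-method levelSizes,MultilevelEntropyMap-method
#' @examples
#' levelSizes(memSpec())
#' @export
setMethod("levelSizes", "MemSpec",
          function(x) as.integer(x@nss * 2^(seq_len(x@levels) - 1L)))

#' @export
setMethod("levelSizes", "MultilevelEntropyMap",
          function(x) levelSizes(x@spec))

#' Number of cells per level
#'
#' @param x a \linkS4class{MemSpec} or \linkS4class{MultilevelEntropyMap}.
#' @return integer vector, cells at each level (finest first).
#' @examples
#' levelCellCounts(memSpec())   # 32 16 8 4 2 1
#' @export
levelCellCounts <- function(x) {
  sp <- if (is(x, "MultilevelEntropyMap")) x@spec else x
  stopifnot(is(sp, "MemSpec"))
  sp@nemr %/% levelSizes(sp)
}

#' Read one map cell
#'
#' \code{MEM(l, s)}: the ApEn of segment \code{segment} at level
#' \code{level} (both 1-based).  Vectorized over \code{segment}.
#'
#' @param x a \linkS4class{MultilevelEntropyMap}.
#' @param level level index, 1 = finest.
#' @param segment segment index within the level.
#' @return numeric cell value(s).
#' @name memCell
#' @aliases memCell,MultilevelEntropyMap-method
#' @export
setMethod("memCell", "MultilevelEntropyMap", function(x, level, segment) {
  stopifnot(length(level) == 1L, level >= 1L, level <= x@spec@levels)
  vals <- x@cells[[level]]
  if (any(segment < 1L) || any(segment > length(vals)))
    stop("segment index out of range for level ", level)
  vals[segment]
})

#' Accessors for gazeMEM objects
#'
#' \code{velocity} returns the velocity samples of an
#' \linkS4class{EMSeries}; \code{samplingRate} its (or a recording's)
#' sampling rate in Hz; \code{provenance} the origin identifiers of a
#' \linkS4class{MultilevelEntropyMap}; \code{isDegenerate} the per-cell
#' zero-SD flags as a list parallel to the map levels.
#'
#' @param x the object.
#' @return see description.
#' @name accessors
#' @aliases velocity,EMSeries-method samplingRate,EMSeries-method
#'   samplingRate,GazeRecording-method provenance,MultilevelEntropyMap-method
#'   isDegenerate,MultilevelEntropyMap-method
NULL

#' @export
setMethod("velocity", "EMSeries", function(x) x@v)

#' @export
setMethod("samplingRate", "EMSeries", function(x) x@fs)

#' @export
setMethod("samplingRate", "GazeRecording", function(x) x@fs)

#' @export
setMethod("provenance", "MultilevelEntropyMap", function(x) x@provenance)

#' @export
setMethod("isDegenerate", "MultilevelEntropyMap", function(x) x@degenerate)
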