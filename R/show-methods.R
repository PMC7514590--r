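setMethod("show", "ApEnParams", function(object) {
  cat(sprintf("ApEnParams: m = %d, r = %.3g * SD (%s)\n",
              object@m, object@rMultiplier, object@rPolicy))
})

setMethod("show", "MemSpec", function(object) {
  cat(sprintf("MemSpec: %d samples, %d levels, segment sizes %s\n",
              object@nemr, object@levels,
              paste(levelSizes(object), collapse = "/")))
})

setMethod("show", "GazeRecording", function(object) {
  cat(sprintf("GazeRecording %s/%s: %d samples at %g Hz, %d stimulus onsets\n",
              object@participant, object@session, length(object@x),
              object@fs, nrow(object@onsets)))
})

setMethod("show", "EMSeries", function(object) {
  v <- object@v
  cat(sprintf("EMSeries %s/%s stimulus %d: %d velocity samples at %g Hz (peak |v| = %.3g)\n",
              object@participant, object@session, object@stimulus,
              length(v), object@fs, max(abs(v))))
})

setMethod("show", "MultilevelEntropyMap", function(object) {
  who <- paste(unlist(object@provenance), collapse = "/")
  cat(sprintf("MultilevelEntropyMap [%s]: %d levels over %d samples\n",
              who, object@spec@levels, object@spec@nemr))
  sizes <- levelSizes(object@spec)
  for (l in seq_len(object@spec@levels)) {
    vals <- object@cells[[l]]
    shown <- paste(sprintf("%.2f", utils::head(vals, 8L)), collapse = " ")
    if (length(vals) > 8L) shown <- paste(shown, "...")
    cat(sprintf("  L%d (w=%4d, %2d cells): %s\n", l, sizes[l],
                length(vals), shown))
  }
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0(
    "SynthConfig: %d participant(s) x %d session(s) x %d points, %g Hz, %g ms/trial\n",
    "  latency U[%g, %g] ms, saccade U[%g, %g] ms, amplitude [%g, %g]\n",
    "  noise SD %g, drift SD %g, microsaccades %g/s, seed %d\n"),
    object@nParticipants, object@nSessions, object@nPoints, object@fs,
    object@trialMs, object@latencyRange[1], object@latencyRange[2],
    object@saccadeDurRange[1], object@saccadeDurRange[2],
    object@amplitudeRange[1], object@amplitudeRange[2], object@noiseSd,
    object@driftSd, object@microsaccadeRate, object@seed))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport %s: %d classes, %d folds, k = %s\n",
              object@featureSet, nrow(object@perSegment), object@nFolds,
              paste(object@kGrid, collapse = "/")))
  cat("  overall accuracy: ",
      paste(sprintf("%s=%.3f", names(object@overall), object@overall),
            collapse = " "), "\n", sep = "")
  bs <- object@bestSegment
  cat("  best segment:     ",
      paste(sprintf("%s=%s", names(bs), object@classRanges[bs]),
            collapse = " "), "\n", sep = "")
})
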