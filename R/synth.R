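#' Configuration of the synthetic jumping-point simulator
#'
#' Parameters of the synthetic gaze generator, which emulates the
#' jumping-point paradigm: a fixation target jumps between screen
#' positions at a fixed interval; each trial holds a saccadic-latency
#' period of fixation at the previous target, one saccade with a smooth
#' raised-cosine velocity pulse carrying the eye to the new target, and
#' post-saccadic fixation.  Fixation is white position noise plus a slow
#' random-walk drift, with optional microsaccade pulses.  Defaults
#' mirror the recording conditions the method targets: 1000 Hz, 3 s per
#' stimulus, 29 positions, 24 participants in 2 sessions, latency
#' 100-250 ms, saccade duration 30-80 ms.
#'
#' @slot nParticipants,nSessions,nPoints cohort layout.
#' @slot fs sampling rate in Hz; \code{trialMs} ms per stimulus.
#' @slot latencyRange,saccadeDurRange uniform bounds in ms.
#' @slot amplitudeRange target-step magnitude bounds, screen units.
#' @slot noiseSd fixation white-noise SD of position, screen units.
#' @slot driftSd per-sample SD of the random-walk drift.
#' @slot microsaccadeRate events per second (0 disables);
#'   \code{microsaccadeAmp} their amplitude in screen units.
#' @slot seed RNG seed.
#' @export
setClass("SynthConfig",
  representation(nParticipants = "integer", nSessions = "integer",
                 nPoints = "integer", fs = "numeric", trialMs = "numeric",
                 latencyRange = "numeric", saccadeDurRange = "numeric",
                 amplitudeRange = "numeric", noiseSd = "numeric",
                 driftSd = "numeric", microsaccadeRate = "numeric",
                 microsaccadeAmp = "numeric", seed = "integer"),
  prototype(nParticipants = 24L, nSessions = 2L, nPoints = 29L,
            fs = 1000, trialMs = 3000, latencyRange = c(100, 250),
            saccadeDurRange = c(30, 80), amplitudeRange = c(0.2, 0.8),
            noiseSd = 5e-4, driftSd = 2e-5, microsaccadeRate = 0,
            microsaccadeAmp = 0.01, seed = 1L))

setValidity("SynthConfig", function(object) {
  msg <- character()
  rng2 <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]
  if (object@nParticipants < 1L || object@nSessions < 1L ||
      object@nPoints < 1L)
    msg <- c(msg, "cohort dimensions must be positive")
  if (object@fs <= 0 || object@trialMs <= 0)
    msg <- c(msg, "'fs' and 'trialMs' must be positive")
  if (!rng2(object@latencyRange) || object@latencyRange[1] <= 0)
    msg <- c(msg, "'latencyRange' must be positive bounds [min, max]")
  if (!rng2(object@saccadeDurRange) || object@saccadeDurRange[1] <= 0)
    msg <- c(msg, "'saccadeDurRange' must be positive bounds [min, max]")
  if (!rng2(object@amplitudeRange) || object@amplitudeRange[1] <= 0 ||
      object@amplitudeRange[2] > 1)
    msg <- c(msg, "'amplitudeRange' must lie in (0, 1]")
  if (length(msg) == 0 &&
      object@latencyRange[2] + object@saccadeDurRange[2] >= object@trialMs)
    msg <- c(msg, "infeasible: max latency + max saccade duration must be < trialMs")
  if (object@noiseSd < 0 || object@driftSd < 0 ||
      object@microsaccadeRate < 0 || object@microsaccadeAmp < 0)
    msg <- c(msg, "noise, drift and microsaccade parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param nParticipants,nSessions,nPoints,fs,trialMs,latencyRange,saccadeDurRange,amplitudeRange,noiseSd,driftSd,microsaccadeRate,microsaccadeAmp,seed
#'   see slots.
#' @rdname SynthConfig-class
#' @return a validated \code{SynthConfig}.
#' @examples
#' synthConfig(nParticipants = 2, nSessions = 1, nPoints = 5)
#' @export
synthConfig <- function(nParticipants = 24L, nSessions = 2L, nPoints = 29L,
                        fs = 1000, trialMs = 3000,
                        latencyRange = c(100, 250),
                        saccadeDurRange = c(30, 80),
                        amplitudeRange = c(0.2, 0.8),
                        noiseSd = 5e-4, driftSd = 2e-5,
                        microsaccadeRate = 0, microsaccadeAmp = 0.01,
                        seed = 1L) {
  new("SynthConfig", nParticipants = as.integer(nParticipants),
      nSessions = as.integer(nSessions), nPoints = as.integer(nPoints),
      fs = as.numeric(fs), trialMs = as.numeric(trialMs),
      latencyRange = as.numeric(latencyRange),
      saccadeDurRange = as.numeric(saccadeDurRange),
      amplitudeRange = as.numeric(amplitudeRange),
      noiseSd = as.numeric(noiseSd), driftSd = as.numeric(driftSd),
      microsaccadeRate = as.numeric(microsaccadeRate),
      microsaccadeAmp = as.numeric(microsaccadeAmp),
      seed = as.integer(seed))
}

# integrated raised-cosine displacement profile on [0, 1]:
# its derivative (1 - cos(2*pi*u)) is the velocity pulse shape
.saccadeProfile <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

# one target sequence with step magnitudes in ampRange, kept inside [0, 1]
.targetWalk <- function(n, ampRange) {
  x <- numeric(n + 1L)
  x[1L] <- stats::runif(1, 0.3, 0.7)
  for (j in seq_len(n)) {
    a <- stats::runif(1, ampRange[1], ampRange[2])
    up <- x[j] + a <= 1
    dn <- x[j] - a >= 0
    sgn <- if (up && dn) sample(c(-1, 1), 1L)
           else if (up) 1 else if (dn) -1
           else { a <- max(1 - x[j], x[j]); if (x[j] < 0.5) 1 else -1 }
    x[j + 1L] <- x[j] + sgn * a
  }
  x
}

#' Simulate one jumping-point gaze recording
#'
#' Generates one participant-session: \code{nPoints} trials of
#' \code{trialMs} ms at \code{fs} Hz.  Per trial, the position holds at
#' the previous target during a latency drawn uniformly from
#' \code{latencyRange} (shifted by \code{latencyOffset}, the
#' participant's idiosyncrasy), then moves to the new target along an
#' integrated raised-cosine, so the velocity is a smooth unimodal pulse
#' of uniform random duration whose integral equals the target step;
#' white noise and random-walk drift are superimposed throughout, plus
#' optional microsaccade pulses during fixation.  Fully reproducible
#' from \code{seed}.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param participant,session identifiers stored in the recording.
#' @param latencyOffset additive shift of the latency distribution, ms.
#' @param seed RNG seed (defaults to \code{config@seed}).
#' @return list with \code{recording} (a \linkS4class{GazeRecording})
#'   and \code{truth}, a data.frame with one row per trial: latency,
#'   saccade duration, the saccade window as 1-based velocity-sample
#'   indices relative to trial onset, the absolute trial start sample,
#'   and source/destination targets.
#' @export
simulateRecording <- function(config, participant = "P01", session = "S1",
                              latencyOffset = 0, seed = config@seed) {
  stopifnot(is(config, "SynthConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fs <- config@fs
  nPer <- round(fs * config@trialMs / 1000)
  nTrial <- config@nPoints
  targets <- .targetWalk(nTrial, config@amplitudeRange)
  x <- numeric(nPer * nTrial)
  truth <- vector("list", nTrial)
  maxLat <- config@trialMs - config@saccadeDurRange[2] - 2000 / fs
  for (j in seq_len(nTrial)) {
    lat <- stats::runif(1, config@latencyRange[1], config@latencyRange[2]) +
      latencyOffset
    lat <- min(max(lat, 1000 / fs), maxLat)
    dur <- stats::runif(1, config@saccadeDurRange[1],
                        config@saccadeDurRange[2])
    latSamp <- round(lat * fs / 1000)
    durSamp <- max(2L, round(dur * fs / 1000))
    s <- seq_len(nPer)
    delta <- targets[j + 1L] - targets[j]
    pos <- targets[j] + delta * .saccadeProfile((s - 1L - latSamp) / durSamp)
    if (config@noiseSd > 0)
      pos <- pos + stats::rnorm(nPer, 0, config@noiseSd)
    if (config@driftSd > 0)
      pos <- pos + cumsum(stats::rnorm(nPer, 0, config@driftSd))
    if (config@microsaccadeRate > 0) {
      nms <- stats::rpois(1, config@microsaccadeRate * config@trialMs / 1000)
      if (nms > 0) {
        msDur <- round(0.020 * fs)
        fixIdx <- setdiff(seq_len(nPer - msDur),
                          latSamp:(latSamp + durSamp + msDur))
        ons <- sample(fixIdx, min(nms, length(fixIdx)))
        for (o in ons)
          pos <- pos + sample(c(-1, 1), 1L) * config@microsaccadeAmp *
            .saccadeProfile((s - o) / msDur)
      }
    }
    x[(j - 1L) * nPer + s] <- pos
    truth[[j]] <- data.frame(
      participant = participant, session = session, stimulus_index = j,
      latency_ms = lat, saccade_dur_ms = dur,
      sacc_onset_sample = latSamp + 1L,
      sacc_offset_sample = latSamp + durSamp,
      trial_start_sample = (j - 1L) * nPer + 1L,
      target_from = targets[j], target_to = targets[j + 1L],
      stringsAsFactors = FALSE)
  }
  n <- nPer * nTrial
  rec <- gazeRecording(
    t = (seq_len(n) - 1) * 1000 / fs, x = x, fs = fs,
    participant = participant, session = session,
    onsets = data.frame(stimulus_index = seq_len(nTrial),
                        onset_ms = (seq_len(nTrial) - 1) * config@trialMs))
  list(recording = rec, truth = do.call(rbind, truth))
}

#' Simulate a cohort of recordings
#'
#' One recording per participant x session, with a per-participant
#' latency-mean offset (drawn once per participant, uniform on
#' +/- 20 ms) modelling idiosyncratic saccadic latency.  Per-recording
#' seeds are derived from \code{config@seed}, so the cohort is
#' deterministic and recordings are mutually independent.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list of \code{simulateRecording} results, one per
#'   participant-session, in participant-major order.
#' @seealso \code{\link{writeCohort}}
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  nP <- config@nParticipants
  nS <- config@nSessions
  offs <- stats::runif(nP, -20, 20)
  seeds <- sample.int(2147483646L, nP * nS)
  out <- vector("list", nP * nS)
  i <- 0L
  for (p in seq_len(nP)) for (s in seq_len(nS)) {
    i <- i + 1L
    out[[i]] <- simulateRecording(
      config, participant = sprintf("P%02d", p),
      session = sprintf("S%d", s), latencyOffset = offs[p],
      seed = seeds[i])
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Per recording: \code{<participant>_<session>_gaze.csv} and
#' \code{..._schedule.csv} in the \code{\link{readGaze}} dialect, plus
#' one \code{truth.json} with all ground-truth rows.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the files written.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (r in cohort) {
    rec <- r$recording
    stemName <- sprintf("%s_%s", rec@participant, rec@session)
    g <- file.path(dir, paste0(stemName, "_gaze.csv"))
    s <- file.path(dir, paste0(stemName, "_schedule.csv"))
    writeGaze(rec, g, s)
    files <- c(files, g, s)
  }
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(do.call(rbind, lapply(cohort, `[[`, "truth")), tj,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, tj))
}
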