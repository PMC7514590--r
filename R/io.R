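#' Read a gaze recording from delimited text
#'
#' Reads per-sample gaze data (timestamp in ms plus horizontal and
#' optionally vertical coordinate) and an accompanying stimulus schedule
#' into a validated \linkS4class{GazeRecording}.  The sampling rate is
#' not inferred from the file; it must be declared by the caller and is
#' checked against the timestamp spacing.
#'
#' @param path path to the gaze file.
#' @param fs sampling rate in Hz.
#' @param schedule stimulus schedule: a data.frame with columns
#'   \code{stimulus_index}, \code{onset_ms}, or a path to a delimited
#'   file with those columns.  May be omitted for schedule-free use.
#' @param delim field delimiter for both files (default comma).
#' @param columns named list mapping the roles \code{t}, \code{x} and
#'   optionally \code{y}, \code{participant}, \code{session} to column
#'   names in the gaze file.
#' @param participant,session identifiers used when the file carries no
#'   such columns.
#' @return a \linkS4class{GazeRecording}.
#' @seealso \code{\link{writeGaze}}, \code{\link{extractEMSeries}}
#' @export
readGaze <- function(path, fs, schedule = NULL, delim = ",",
                     columns = list(t = "t", x = "x"),
                     participant = "P01", session = "S1") {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(t = columns$t %||% "t", x = columns$x %||% "x")
  miss <- setdiff(unname(need), names(raw))
  if (length(miss))
    stop("gaze file format error: missing column(s) ",
         paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (anyNA(v)) {
      row <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop("non-numeric value in column '", col, "' at data row ", row)
    }
    v
  }
  t <- num(need[["t"]])
  x <- num(need[["x"]])
  y <- if (!is.null(columns$y) && columns$y %in% names(raw))
    num(columns$y) else numeric(0)
  if (!is.null(columns$participant) && columns$participant %in% names(raw))
    participant <- raw[[columns$participant]][1L]
  if (!is.null(columns$session) && columns$session %in% names(raw))
    session <- raw[[columns$session]][1L]
  onsets <- if (is.null(schedule))
    data.frame(stimulus_index = integer(0), onset_ms = numeric(0))
  else if (is.character(schedule))
    readStimulusSchedule(schedule, delim = delim)
  else schedule
  gazeRecording(t = t, x = x, y = y, fs = fs, participant = participant,
                session = session, onsets = onsets)
}

#' @rdname readGaze
#' @export
readStimulusSchedule <- function(path, delim = ",") {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = delim,
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("stimulus_index", "onset_ms"), names(d))
  if (length(miss))
    stop("schedule format error: missing column(s) ",
         paste(miss, collapse = ", "))
  data.frame(stimulus_index = as.integer(d$stimulus_index),
             onset_ms = as.numeric(d$onset_ms))
}

#' Write a gaze recording and its stimulus schedule
#'
#' Writes the recording as CSV in the dialect \code{\link{readGaze}}
#' reads.  Doubles are written with 17 significant digits so a
#' write-then-read round trip reproduces them exactly.
#'
#' @param rec a \linkS4class{GazeRecording}.
#' @param path output path for the gaze CSV.
#' @param schedulePath optional output path for the schedule CSV.
#' @return invisibly, the paths written.
#' @export
writeGaze <- function(rec, path, schedulePath = NULL) {
  stopifnot(is(rec, "GazeRecording"))
  fmt <- function(v) sprintf("%.17g", v)
  cols <- c("t", "x", if (length(rec@y)) "y", "participant", "session")
  body <- cbind(fmt(rec@t), fmt(rec@x),
                if (length(rec@y)) fmt(rec@y),
                rec@participant, rec@session)
  lines <- c(paste(cols, collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  if (!is.null(schedulePath)) {
    sl <- c("stimulus_index,onset_ms",
            paste(rec@onsets$stimulus_index, fmt(rec@onsets$onset_ms),
                  sep = ","))
    writeLines(sl, schedulePath)
  }
  invisible(c(path, schedulePath))
}

#' Two-point differentiation of position to velocity
#'
#' Forward difference scaled by the sampling rate:
#' \code{v[i] = (x[i+1] - x[i]) * fs}, length \code{length(x) - 1}.
#' Velocity inherits the coordinate's units per second.
#'
#' @param x position samples, length >= 2.
#' @param fs sampling rate in Hz.
#' @return numeric velocity samples.
#' @examples
#' differentiate(c(0, 0.001, 0.003), 1000)  # 1, 2
#' @export
differentiate <- function(x, fs) {
  if (length(x) < 2L) stop("need at least two position samples")
  diff(as.numeric(x)) * fs
}

#' Cut a recording into per-stimulus velocity series
#'
#' For each stimulus onset, takes the \code{nemr + 1} position samples
#' starting at the nearest sample at-or-after the onset time,
#' differentiates them (\code{\link{differentiate}}), and keeps the
#' resulting \code{nemr} velocity samples as one \linkS4class{EMSeries}.
#' Intervals with too few remaining samples are skipped with a warning,
#' so a recording that is defective for some stimuli still yields the
#' remaining series.
#'
#' @param rec a \linkS4class{GazeRecording} with a stimulus schedule.
#' @param nemr series length in velocity samples (default 2048, the
#'   largest power of two inside a 3 s trial at 1000 Hz).
#' @return list of \linkS4class{EMSeries}, at most one per onset.
#' @export
extractEMSeries <- function(rec, nemr = 2048L) {
  stopifnot(is(rec, "GazeRecording"))
  nemr <- as.integer(nemr)
  if (nemr < 2L) stop("'nemr' must be >= 2")
  if (!nrow(rec@onsets)) stop("recording has no stimulus onsets")
  n <- length(rec@x)
  out <- vector("list", nrow(rec@onsets))
  for (j in seq_len(nrow(rec@onsets))) {
    i0 <- which(rec@t >= rec@onsets$onset_ms[j])[1L]
    if (is.na(i0) || i0 + nemr > n) {
      warning(sprintf(
        "stimulus %d: interval too short (%d samples available, %d needed); series skipped",
        rec@onsets$stimulus_index[j], if (is.na(i0)) 0L else n - i0 + 1L,
        nemr + 1L))
      next
    }
    pos <- rec@x[i0:(i0 + nemr)]
    out[[j]] <- emSeries(v = differentiate(pos, rec@fs), fs = rec@fs,
                         participant = rec@participant,
                         session = rec@session,
                         stimulus = rec@onsets$stimulus_index[j])
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Read a run-configuration file
#'
#' Loads a YAML or JSON file of pipeline settings (sampling rate,
#' map geometry, entropy parameters, column mapping, ...) as a named
#' list.  The format is chosen by extension (\code{.yml}/\code{.yaml}
#' vs \code{.json}).  Entries are not interpreted here; callers (and
#' the command-line front end, where a config file overrides flags)
#' merge them over their defaults.
#'
#' @param path path to the configuration file.
#' @return named list of settings.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a mapping of named settings")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
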