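#' Build the Multilevel Entropy Map of one velocity series
#'
#' Computes the approximate entropy of every segment of the dyadic
#' time-scale grid: at level \eqn{l} the series is cut into contiguous
#' non-overlapping windows of \code{nss * 2^(l-1)} samples and
#' \code{\link{apEnAuto}} is applied to each, so cell \code{MEM(l, s)}
#' covers samples \code{(s-1)*w + 1 : s*w} with \code{w} the level's
#' window size.  Windows at level \eqn{l+1} are exact unions of two
#' adjacent level-\eqn{l} windows.  Under the \code{"global"} tolerance
#' policy every cell shares \code{r = rMultiplier * sd(v)} of the full
#' series; under the default \code{"per_segment"} policy each segment
#' uses its own SD.
#'
#' @param series an \linkS4class{EMSeries} whose length equals
#'   \code{spec@nemr}.
#' @param spec a \code{\link{memSpec}}.
#' @param params an \code{\link{apEnParams}}.
#' @return a \linkS4class{MultilevelEntropyMap}.
#' @examples
#' set.seed(1)
#' s <- emSeries(rnorm(256), fs = 1000)
#' buildMEM(s, memSpec(256, 32, 4))
#' @export
buildMEM <- function(series, spec = memSpec(), params = apEnParams()) {
  stopifnot(is(series, "EMSeries"), is(spec, "MemSpec"),
            is(params, "ApEnParams"))
  v <- series@v
  if (length(v) != spec@nemr)
    stop("series length ", length(v), " does not match spec nemr ",
         spec@nemr)
  gsd <- if (params@rPolicy == "global") stats::sd(v) else NULL
  sizes <- levelSizes(spec)
  cells <- degen <- vector("list", spec@levels)
  for (l in seq_len(spec@levels)) {
    w <- sizes[l]
    ns <- spec@nemr %/% w
    vals <- numeric(ns)
    flags <- logical(ns)
    for (s in seq_len(ns)) {
      a <- apEnAuto(v[((s - 1L) * w + 1L):(s * w)], params, globalSd = gsd)
      vals[s] <- as.numeric(a)
      flags[s] <- attr(a, "degenerate")
    }
    cells[[l]] <- vals
    degen[[l]] <- flags
  }
  new("MultilevelEntropyMap", spec = spec, cells = cells, degenerate = degen,
      provenance = list(participant = series@participant,
                        session = series@session,
                        stimulus = series@stimulus))
}

#' Average many entropy maps cell by cell
#'
#' Arithmetic mean and standard deviation of each cell across maps that
#' share one geometry, the standard summary of a cohort of per-trial
#' maps.  Degenerate cells contribute their stored 0 unless
#' \code{excludeDegenerate = TRUE}, in which case a cell's statistics
#' use only the maps where it is non-degenerate (cells degenerate
#' everywhere fall back to 0).
#'
#' @param maps non-empty list of \linkS4class{MultilevelEntropyMap}s with
#'   identical specs.
#' @param sd \code{"sample"} (default, divisor n-1) or
#'   \code{"population"} (divisor n).
#' @param excludeDegenerate drop flagged cells from the statistics.
#' @return list with elements \code{mean} and \code{sd}, both maps; the
#'   mean map's degeneracy flags mark cells degenerate in every input.
#' @export
averageMEMs <- function(maps, sd = c("sample", "population"),
                        excludeDegenerate = FALSE) {
  sd <- match.arg(sd)
  if (!length(maps)) stop("'maps' must be non-empty")
  stopifnot(all(vapply(maps, is, logical(1), "MultilevelEntropyMap")))
  sp <- maps[[1L]]@spec
  same <- vapply(maps, function(m)
    identical(levelSizes(m@spec), levelSizes(sp)) &&
      m@spec@nemr == sp@nemr, logical(1))
  if (!all(same)) stop("all maps must share one MemSpec")
  nmap <- length(maps)
  meanCells <- sdCells <- degen <- vector("list", sp@levels)
  for (l in seq_len(sp@levels)) {
    vals <- do.call(rbind, lapply(maps, function(m) m@cells[[l]]))
    flags <- do.call(rbind, lapply(maps, function(m) m@degenerate[[l]]))
    if (excludeDegenerate) vals[flags] <- NA_real_
    mu <- colMeans(vals, na.rm = TRUE)
    ss <- apply(vals, 2L, stats::sd, na.rm = TRUE)
    if (sd == "population") {
      nn <- colSums(!is.na(vals))
      ss <- ss * sqrt((nn - 1) / nn)
    }
    mu[is.nan(mu)] <- 0
    ss[is.na(ss)] <- 0
    meanCells[[l]] <- mu
    sdCells[[l]] <- ss
    degen[[l]] <- apply(flags, 2L, all)
  }
  prov <- list(source = "averaged", n = nmap)
  list(mean = new("MultilevelEntropyMap", spec = sp, cells = meanCells,
                  degenerate = degen, provenance = prov),
       sd = new("MultilevelEntropyMap", spec = sp, cells = sdCells,
                degenerate = degen, provenance = prov))
}

# fixed entropy bands used for map colouring; left-closed/right-open
.memBands <- data.frame(
  lower = c(-Inf, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
  upper = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, Inf),
  band = c("green", "brown", "blue", "light violet", "light burgundy",
           "light gray", "dark gray", "red"),
  hex = c("#4daf4a", "#a65628", "#377eb8", "#c2a5cf", "#c51b7d",
          "#cccccc", "#777777", "#e41a1c"),
  stringsAsFactors = FALSE)

#' Colour band of an entropy value
#'
#' The fixed 8-band palette used to colour map cells: values below 0.4
#' are green, then brown, blue, light violet, light burgundy, light and
#' dark gray in 0.1-wide bands, and values of 1 or more red.  Intervals
#' are left-closed/right-open, so 0.4 is brown.
#'
#' @param v numeric entropy values.
#' @return character band names, vectorized.
#' @examples
#' memBand(c(0.35, 0.4, 1.2))
#' @export
memBand <- function(v) {
  i <- findInterval(v, c(.memBands$lower[-1L]), left.open = FALSE) + 1L
  .memBands$band[i]
}

#' Long-form table of a map
#'
#' One row per cell: level, segment, covered sample range, ApEn value
#' and degeneracy flag.  This is also the CSV layout written by
#' \code{\link{renderMEM}}.
#'
#' @param map a \linkS4class{MultilevelEntropyMap}.
#' @return data.frame with columns \code{level}, \code{segment},
#'   \code{start_sample}, \code{end_sample}, \code{apen},
#'   \code{degenerate}.
#' @export
memTable <- function(map) {
  stopifnot(is(map, "MultilevelEntropyMap"))
  sizes <- levelSizes(map@spec)
  do.call(rbind, lapply(seq_len(map@spec@levels), function(l) {
    ns <- length(map@cells[[l]])
    s <- seq_len(ns)
    data.frame(level = l, segment = s,
               start_sample = (s - 1L) * sizes[l] + 1L,
               end_sample = s * sizes[l],
               apen = map@cells[[l]],
               degenerate = map@degenerate[[l]])
  }))
}

#' Serialize / restore an entropy map
#'
#' \code{writeMEM} stores a map as a JSON object
#' \code{\{spec, provenance, levels, degenerate\}} with the level arrays
#' finest-first (1-based \code{MEM(l, s)} indexing); \code{readMEM}
#' restores it.
#'
#' @param map a \linkS4class{MultilevelEntropyMap}.
#' @param path file path.
#' @return \code{writeMEM}: the path, invisibly; \code{readMEM}: the map.
#' @export
writeMEM <- function(map, path) {
  stopifnot(is(map, "MultilevelEntropyMap"))
  obj <- list(spec = list(nemr = map@spec@nemr, nss = map@spec@nss,
                          levels = map@spec@levels),
              provenance = map@provenance,
              levels = map@cells,
              degenerate = map@degenerate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMEM
#' @export
readMEM <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- memSpec(obj$spec$nemr, obj$spec$nss, obj$spec$levels)
  cells <- lapply(obj$levels, as.numeric)
  degen <- lapply(obj$degenerate, as.logical)
  new("MultilevelEntropyMap", spec = sp, cells = cells, degenerate = degen,
      provenance = as.list(obj$provenance))
}

#' Render a map as a coloured grid
#'
#' Writes three files sharing a stem: \code{<stem>.html}, an HTML table
#' whose cells are coloured with the 8-band palette of
#' \code{\link{memBand}} (finest level in the top row, each coarser
#' level's cell spanning its two children); \code{<stem>.csv}, the
#' long-form numeric table of \code{\link{memTable}}; and
#' \code{<stem>.json}, the serialized map.
#'
#' @param map a \linkS4class{MultilevelEntropyMap}.
#' @param stem output path without extension.
#' @return invisibly, a named character vector of the files written.
#' @export
renderMEM <- function(map, stem) {
  stopifnot(is(map, "MultilevelEntropyMap"))
  files <- c(html = paste0(stem, ".html"), csv = paste0(stem, ".csv"),
             json = paste0(stem, ".json"))
  utils::write.csv(memTable(map), files[["csv"]], row.names = FALSE)
  writeMEM(map, files[["json"]])
  ncol1 <- length(map@cells[[1L]])
  rows <- vapply(seq_len(map@spec@levels), function(l) {
    vals <- map@cells[[l]]
    span <- ncol1 %/% length(vals)
    hex <- .memBands$hex[match(memBand(vals), .memBands$band)]
    cells <- sprintf(
      '<td colspan="%d" style="background:%s;border:1px solid #333;text-align:center">%.3f</td>',
      span, hex, vals)
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, character(1))
  who <- paste(unlist(map@provenance), collapse = " / ")
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>Multilevel Entropy Map</title></head><body>",
            sprintf("<p>Multilevel Entropy Map — %s</p>", who),
            "<table style='border-collapse:collapse;font-family:monospace'>",
            rows, "</table></body></html>")
  ok <- tryCatch({ writeLines(html, files[["html"]]); TRUE },
                 error = function(e) stop("cannot write ", files[["html"]],
                                          ": ", conditionMessage(e)))
  invisible(files)
}
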