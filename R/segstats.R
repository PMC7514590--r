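#' Compare segment positions at one map level
#'
#' Tests whether mean entropy differs between segment positions at a
#' given level, across a collection of per-trial maps: a one-way ANOVA
#' with segment position as the factor (observations = the cell values
#' of each map), followed by all-pairs Tukey HSD at a 95% family-wise
#' confidence level.  This is the routine check that early segments —
#' the ones carrying the saccade — really differ from late, purely
#' fixational ones.
#'
#' @param maps list of at least two \linkS4class{MultilevelEntropyMap}s
#'   sharing a spec.
#' @param level map level to compare (must hold >= 2 segments).
#' @param conf.level family-wise confidence level for Tukey HSD.
#' @return list with \code{anova} (the \code{\link[stats]{aov}} fit),
#'   \code{p.value} (ANOVA F-test p), \code{tukey} (data.frame of
#'   pairwise differences with adjusted p-values) and \code{data} (the
#'   long-form values used).
#' @export
compareSegments <- function(maps, level = 1L, conf.level = 0.95) {
  if (is(maps, "MultilevelEntropyMap")) maps <- list(maps)
  if (length(maps) < 2L)
    stop("need at least two maps to compare segment distributions")
  stopifnot(all(vapply(maps, is, logical(1), "MultilevelEntropyMap")))
  level <- as.integer(level)
  ns <- length(maps[[1L]]@cells[[level]])
  if (ns < 2L) stop("level ", level, " has fewer than two segments")
  d <- do.call(rbind, lapply(seq_along(maps), function(i)
    data.frame(map = i, segment = factor(seq_len(ns)),
               apen = maps[[i]]@cells[[level]])))
  fit <- stats::aov(apen ~ segment, data = d)
  pv <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = conf.level)$segment
  tukey <- data.frame(pair = rownames(tk), tk, row.names = NULL)
  list(anova = fit, p.value = pv, tukey = tukey, data = d)
}
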