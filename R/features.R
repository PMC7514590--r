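#' Feature-set specification
#'
#' A feature set combines one or more map levels, named by their segment
#' sizes: \code{"set64"}, \code{"set64_128"}, \code{"set128_256_512"},
#' and so on.  The finest listed size \eqn{X} fixes the element grid:
#' each map yields \code{nemr / X} elements, element \eqn{i} carrying
#' class label \eqn{i} (its position within the series) and, for every
#' listed size \eqn{S}, the ApEn of the level-\eqn{S} ancestor segment
#' whose time window contains element \eqn{i}.
#'
#' @param sizes either a set name like \code{"set128_256_512"} or an
#'   increasing integer vector of segment sizes.
#' @param spec the \code{\link{memSpec}} the sizes must belong to.
#' @return object of class \code{FeatureSetSpec} with fields
#'   \code{name}, \code{sizes}, \code{levels} (map level of each size),
#'   \code{nElements} (elements per map = number of classes) and
#'   \code{finest}.
#' @examples
#' featureSetSpec("set64_128")
#' featureSetSpec(c(128, 256, 512))$nElements  # 16
#' @export
featureSetSpec <- function(sizes, spec = memSpec()) {
  stopifnot(is(spec, "MemSpec"))
  if (is.character(sizes)) {
    stopifnot(length(sizes) == 1L)
    if (!grepl("^set[0-9]+(_[0-9]+)*$", sizes))
      stop("malformed feature-set name: ", sizes)
    sizes <- as.integer(strsplit(sub("^set", "", sizes), "_")[[1L]])
  }
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || is.unsorted(sizes, strictly = TRUE))
    stop("'sizes' must be strictly increasing")
  lv <- match(sizes, levelSizes(spec))
  if (anyNA(lv))
    stop("segment size(s) ", paste(sizes[is.na(lv)], collapse = ", "),
         " are not levels of the map (valid: ",
         paste(levelSizes(spec), collapse = ", "), ")")
  structure(list(name = paste0("set", paste(sizes, collapse = "_")),
                 sizes = sizes, levels = lv,
                 finest = sizes[1L],
                 nElements = spec@nemr %/% sizes[1L]),
            class = "FeatureSetSpec")
}

#' @export
print.FeatureSetSpec <- function(x, ...) {
  cat(sprintf("FeatureSetSpec %s: %d feature(s), %d elements/classes per map\n",
              x$name, length(x$sizes), x$nElements))
  invisible(x)
}

#' Assemble a classification dataset from entropy maps
#'
#' For every map, emits one row per element of the finest listed level:
#' element \eqn{i} (1-based) gets class label \eqn{i} and the feature
#' vector \code{(MEM(level(S), ceiling(i * X / S)))} over the listed
#' sizes \eqn{S}, with \eqn{X} the finest size — i.e. each coarser
#' feature is the ancestor segment containing the element's time
#' window.  For \code{"set64_128"}, element 3 is
#' \code{[MEM(1,3), MEM(2,2)]} and element 4 \code{[MEM(1,4), MEM(2,2)]}.
#' Labels therefore span \code{1 .. nemr/X} and are balanced within any
#' complete collection of maps.
#'
#' @param maps list of \linkS4class{MultilevelEntropyMap}s sharing a spec.
#' @param fsSpec a \code{\link{featureSetSpec}} (or set name / size
#'   vector, coerced against the maps' spec).
#' @return a \code{FeatureDataset}: a data.frame with identifier columns
#'   \code{participant}, \code{session}, \code{stimulus}, the class
#'   label \code{element}, its time window \code{range_ms}, and one
#'   \code{apen<S>} column per size, plus attribute \code{fsSpec}.
#' @export
buildFeatures <- function(maps, fsSpec) {
  if (is(maps, "MultilevelEntropyMap")) maps <- list(maps)
  stopifnot(length(maps) > 0L,
            all(vapply(maps, is, logical(1), "MultilevelEntropyMap")))
  sp <- maps[[1L]]@spec
  if (!inherits(fsSpec, "FeatureSetSpec")) fsSpec <- featureSetSpec(fsSpec, sp)
  if (!all(fsSpec$sizes %in% levelSizes(sp)))
    stop("segment size(s) ",
         paste(setdiff(fsSpec$sizes, levelSizes(sp)), collapse = ", "),
         " are not levels of the supplied maps")
  X <- fsSpec$finest
  i <- seq_len(fsSpec$nElements)
  anc <- lapply(seq_along(fsSpec$sizes), function(j)
    as.integer(ceiling(i * X / fsSpec$sizes[j])))
  rows <- lapply(maps, function(m) {
    if (m@spec@nemr != sp@nemr || m@spec@nss != sp@nss)
      stop("all maps must share one MemSpec")
    feats <- lapply(seq_along(fsSpec$sizes), function(j)
      m@cells[[fsSpec$levels[j]]][anc[[j]]])
    names(feats) <- paste0("apen", fsSpec$sizes)
    pr <- m@provenance
    data.frame(participant = as.character(pr$participant %||% "averaged"),
               session = as.character(pr$session %||% ""),
               stimulus = as.integer(pr$stimulus %||% NA_integer_),
               element = i,
               range_ms = sprintf("%d-%d", (i - 1L) * X, i * X),
               feats, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fsSpec") <- fsSpec
  class(out) <- c("FeatureDataset", class(out))
  out
}

featureColumns <- function(dataset) grep("^apen[0-9]+$", names(dataset),
                                         value = TRUE)
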