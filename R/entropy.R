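#' Approximate entropy of a time series
#'
#' Classical approximate entropy \eqn{ApEn(m, r, N)} of Pincus: with
#' template vectors \eqn{x(i) = [u(i), ..., u(i+m-1)]} and Chebyshev
#' distance, \eqn{C_i^m(r)} is the fraction of the \eqn{N-m+1} templates
#' within tolerance \eqn{r} of \eqn{x(i)} (the self-match included, so
#' \eqn{C_i^m \ge 1/(N-m+1)} and the logarithm is always defined),
#' \eqn{\Phi_m(r)} the mean natural log of the \eqn{C_i^m}, and
#' \deqn{ApEn(m, r, N) = \Phi_m(r) - \Phi_{m+1}(r).}
#' At dimension \eqn{m+1} both the count and the normalizer run over the
#' \eqn{N-m} templates that exist there.  Lower values mean a more
#' regular (more self-similar) signal; with self-matches included the
#' estimator is non-negative up to floating error.
#'
#' Distances are compared with a plain \code{<= r}; only the natural
#' logarithm is supported.
#'
#' @param u numeric series of length \code{N >= m + 2}.
#' @param m embedding dimension (default 2, the usual choice for
#'   biomedical signals).
#' @param r positive tolerance, in the units of \code{u}.  See
#'   \code{\link{apEnAuto}} for the SD-relative form.
#' @return a single non-negative number.
#' @seealso \code{\link{apEnAuto}}, \code{\link{buildMEM}}
#' @examples
#' set.seed(1)
#' u <- rnorm(128)
#' approxEntropy(u, m = 2, r = 0.2 * sd(u))
#' approxEntropy(rep(1, 64), m = 2, r = 0.05)  # constant series -> 0
#' @export
approxEntropy <- function(u, m = 2L, r) {
  u <- as.numeric(u)
  m <- as.integer(m)
  N <- length(u)
  if (anyNA(u) || any(!is.finite(u))) stop("'u' must be finite")
  if (m < 1L) stop("'m' must be >= 1")
  if (N < m + 2L)
    stop("series too short: need N >= m + 2 (got N = ", N, ", m = ", m, ")")
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single positive tolerance")
  # pairwise |u_i - u_j| once; the Chebyshev distance matrix at each
  # embedding dimension is a running maximum over shifted diagonals, so
  # dimensions m and m+1 share one incremental chain
  D <- abs(outer(u, u, "-"))
  M <- D
  phiM <- 0
  for (mm in seq_len(m + 1L)[-1L]) {
    if (mm == m + 1L) {
      n <- N - m + 1L
      phiM <- mean(log(.rowMeans(M <= r, n, n)))
    }
    n <- N - mm + 1L
    idx <- mm:(mm + n - 1L)
    M <- pmax(M[seq_len(n), seq_len(n), drop = FALSE],
              D[idx, idx, drop = FALSE])
  }
  if (m == 1L) phiM <- mean(log(.rowMeans(D <= r, N, N)))
  n <- N - m
  phiM - mean(log(.rowMeans(M <= r, n, n)))
}

#' Approximate entropy with SD-relative tolerance
#'
#' Computes \code{\link{approxEntropy}} with \eqn{r} derived from a
#' standard deviation: \code{r = rMultiplier * SD}, where SD is the
#' series' own sample SD under the \code{"per_segment"} policy or a
#' caller-supplied \code{globalSd} under \code{"global"} (used when many
#' segments of one longer series should share a tolerance).  Because
#' \eqn{r} scales with the signal, the result is invariant to translation
#' and positive rescaling of \code{u}.
#'
#' A zero-SD (constant) segment admits no tolerance; it is defined as
#' maximally regular and returns 0, marked with attribute
#' \code{degenerate = TRUE}.
#'
#' @param u numeric series.
#' @param params an \code{\link{apEnParams}} object.
#' @param globalSd SD of the parent series, required when
#'   \code{params@rPolicy == "global"}.
#' @return ApEn value with logical attribute \code{degenerate}.
#' @examples
#' set.seed(1)
#' u <- rnorm(128)
#' apEnAuto(u, apEnParams())  # == approxEntropy(u, 2, 0.2 * sd(u))
#' @export
apEnAuto <- function(u, params = apEnParams(), globalSd = NULL) {
  stopifnot(is(params, "ApEnParams"))
  s <- switch(params@rPolicy,
    per_segment = stats::sd(u),
    global = {
      if (is.null(globalSd))
        stop("'globalSd' is required under the global r policy")
      as.numeric(globalSd)
    })
  if (!is.finite(s)) stop("standard deviation is not finite")
  if (s == 0)
    return(structure(0, degenerate = TRUE))
  structure(approxEntropy(u, params@m, params@rMultiplier * s),
            degenerate = FALSE)
}
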