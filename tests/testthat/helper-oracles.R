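# Independent oracles, written as literal translations of the defining
# formulas so they stay independent of the package's optimized paths.

# Approximate entropy by exhaustive double loop over template vectors:
# C_i^m(r) = #{j : max_k |u(i+k-1) - u(j+k-1)| <= r} / (N-m+1),
# Phi_m = mean log C_i^m, ApEn = Phi_m - Phi_{m+1}.
apenBruteForce <- function(u, m, r) {
  N <- length(u)
  phi <- function(mm) {
    n <- N - mm + 1L
    C <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        dmax <- 0
        for (k in 0:(mm - 1L)) {
          d <- abs(u[i + k] - u[j + k])
          if (d > dmax) dmax <- d
        }
        if (dmax <= r) cnt <- cnt + 1L
      }
      C[i] <- cnt / n
    }
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

# A map whose cell values encode their own coordinates (level * 1000 +
# segment), for index-identity checks.
symbolicMap <- function(spec = memSpec()) {
  counts <- levelCellCounts(spec)
  new("MultilevelEntropyMap", spec = spec,
      cells = lapply(seq_along(counts), function(l)
        l * 1000 + seq_len(counts[l])),
      degenerate = lapply(counts, function(n) rep(FALSE, n)),
      provenance = list(participant = "SYM", session = "S1", stimulus = 1L))
}

# A small random map (cheap stand-in where only structure matters).
randomMap <- function(spec = memSpec(256L, 32L, 4L), participant = "P01",
                      session = "S1", stimulus = 1L) {
  counts <- levelCellCounts(spec)
  new("MultilevelEntropyMap", spec = spec,
      cells = lapply(counts, function(n) stats::runif(n, 0.1, 1.4)),
      degenerate = lapply(counts, function(n) rep(FALSE, n)),
      provenance = list(participant = participant, session = session,
                        stimulus = stimulus))
}
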