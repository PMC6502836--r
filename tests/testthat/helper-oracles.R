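# Independent oracles used by the unit and acceptance tests.

# Exhaustive zero-variance segmentation of a noiseless piecewise-constant
# series: dynamic programme minimizing the number of segments subject to
# zero within-segment variance.  Returns 0-based change points.
brute_force_changepoints <- function(x) {
  n <- length(x)
  # best[i]: minimal segments covering x[1..i]; prev[i]: split before
  best <- rep(Inf, n)
  prev <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      seg <- x[j:i]
      if (all(seg == seg[1])) {
        cand <- if (j == 1) 1 else best[j - 1] + 1
        if (cand < best[i]) {
          best[i] <- cand
          prev[i] <- j - 1L
        }
      }
    }
  }
  cps <- integer(0)
  i <- n
  while (i > 0) {
    if (prev[i] > 0) cps <- c(prev[i], cps)
    i <- prev[i]
  }
  cps
}

# All set partitions of seq_len(n) (Bell number growth: keep n small).
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    p[[length(p) + 1]] <- n
    out[[length(out) + 1]] <- p
  }
  out
}

# Minimum-description-length cost of grouping whole-trace segments
# (one segment per trace, so no transition cost) into clusters.
# Mirrors the published two-part code: residual bits + half a log2(N) per
# state mean.
partition_mdl <- function(partition, traces, sigma) {
  N <- sum(lengths(traces))
  ss <- 0
  for (cl in partition) {
    vals <- unlist(traces[cl])
    ss <- ss + sum((vals - mean(vals))^2)
  }
  ss / (2 * sigma^2 * log(2)) + 0.5 * length(partition) * log2(N)
}

# Mean dwell times per state from a continuous Gillespie path
# (excluding the final, censored dwell).
path_dwells <- function(path, duration) {
  d <- diff(c(path$start, duration))
  if (length(d) > 1) {
    data.frame(state = path$state[-length(d)], dwell = d[-length(d)])
  } else data.frame(state = integer(0), dwell = numeric(0))
}
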