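#' Nearest-neighbour transition-rate matrix
#'
#' Builds the rate matrix of a linear kinetic chain in which each state
#' exchanges only with its neighbours in efficiency order.  Every state has
#' the same total exit rate `1 / mean_dwell`; interior states split it
#' equally between their two neighbours.
#'
#' @param n_states number of conformational states.
#' @param mean_dwell mean dwell time per state, ms.
#' @return `n_states x n_states` rate matrix (ms^-1) with rows summing to 0.
#' @export
nearest_neighbour_rates <- function(n_states, mean_dwell = 150) {
  stopifnot(n_states >= 1, is.finite(mean_dwell), mean_dwell > 0)
  Q <- matrix(0, n_states, n_states)
  if (n_states > 1) {
    k <- 1 / mean_dwell
    for (i in seq_len(n_states)) {
      nb <- c(i - 1, i + 1)
      nb <- nb[nb >= 1 & nb <= n_states]
      Q[i, nb] <- k / length(nb)
    }
    diag(Q) <- -rowSums(Q)
  }
  Q
}

#' Configuration for the synthetic smFRET photon-trace simulator
#'
#' Defines the generative model: a continuous-time Markov chain over discrete
#' FRET states, Poisson photon emission partitioned between donor and
#' acceptor channels by the state efficiency, exponential single-fluorophore
#' photobleaching, and a labelling-stoichiometry mixture matching the
#' photobleach-step distribution seen for stochastically labelled homomeric
#' receptors (10% four steps / 50% three / 35% two / 5% one).
#'
#' Defaults give, after 5 ms analysis binning, shot-noise widths comparable
#' to experimental efficiency histograms, and FRETing regions (time to the
#' first bleach of a donor-acceptor pair) averaging roughly 1.7 s.
#'
#' @param state_efficiencies true FRET efficiency of each state, each
#'   strictly in (0, 1).
#' @param rate_matrix transition-rate matrix in ms^-1 (off-diagonals >= 0,
#'   diagonal = minus the row sum).  Default: nearest-neighbour chain with
#'   `mean_dwell` ms dwells.
#' @param mean_dwell mean state dwell time (ms) used when `rate_matrix` is
#'   not supplied.
#' @param total_intensity mean summed donor+acceptor photons per 1 ms bin per
#'   FRETing donor (counts).
#' @param background mean background counts per channel per bin.
#' @param bleach_rate_donor,bleach_rate_acceptor exponential photobleach
#'   hazard per fluorophore, ms^-1.
#' @param direct_intensity mean counts per bin per live acceptor in the
#'   direct-excitation channel.
#' @param stoichiometry_weights probability that a molecule carries 1, 2, 3
#'   or 4 fluorophores (i.e. shows that many bleach steps); must sum to 1.
#' @param duration trace length, ms; the default (20 s) is long enough for
#'   essentially complete photobleaching at the default hazards, as in
#'   acquisitions recorded to the end of the bleach cascade.
#' @param bin_width native bin width, ms (1 ms as acquired).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(state_efficiencies,
                       rate_matrix = NULL,
                       mean_dwell = 150,
                       total_intensity = 50,
                       background = 2,
                       bleach_rate_donor = 3e-4,
                       bleach_rate_acceptor = 3e-4,
                       direct_intensity = 25,
                       stoichiometry_weights = c(0.05, 0.35, 0.50, 0.10),
                       duration = 20000,
                       bin_width = 1) {
  E <- as.numeric(state_efficiencies)
  if (length(E) < 1 || any(!is.finite(E)) || any(E <= 0 | E >= 1))
    stop("state_efficiencies must be finite and strictly inside (0, 1)")
  n <- length(E)
  if (is.null(rate_matrix)) rate_matrix <- nearest_neighbour_rates(n, mean_dwell)
  Q <- as.matrix(rate_matrix)
  if (!is.numeric(Q) || nrow(Q) != n || ncol(Q) != n)
    stop("rate_matrix must be a numeric ", n, "x", n, " matrix")
  if (any(!is.finite(Q))) stop("rate_matrix entries must be finite")
  off <- Q[row(Q) != col(Q)]
  if (any(!is.finite(off)) || any(off < 0))
    stop("rate_matrix off-diagonal rates must be finite and >= 0")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  w <- as.numeric(stoichiometry_weights)
  if (length(w) != 4 || any(!is.finite(w)) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-8)
    stop("stoichiometry_weights must be 4 non-negative values summing to 1")
  w <- w / sum(w)
  for (nm in c("total_intensity", "background", "bleach_rate_donor",
               "bleach_rate_acceptor", "direct_intensity", "duration",
               "bin_width")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop(nm, " must be a single finite non-negative number")
  }
  if (duration <= 0 || bin_width <= 0)
    stop("duration and bin_width must be positive")
  structure(list(
    state_efficiencies = E, rate_matrix = Q,
    total_intensity = total_intensity, background = background,
    bleach_rate_donor = bleach_rate_donor,
    bleach_rate_acceptor = bleach_rate_acceptor,
    direct_intensity = direct_intensity,
    stoichiometry_weights = w,
    duration = duration, bin_width = bin_width
  ), class = "sim_config")
}

#' Read a simulator configuration from a key = value text file
#'
#' Lines of the form `key = value`; vectors comma-separated
#' (e.g. `state_efficiencies = 0.93, 0.82, 0.70`); `#` starts a comment.
#' Keys are the arguments of [sim_config()] except `rate_matrix`, which is
#' given implicitly through `mean_dwell`.
#'
#' @param path file path.
#' @return `sim_config` object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("unparseable config line: ", lines[which(bad)[1]])
  args <- lapply(kv, function(m)
    suppressWarnings(as.numeric(strsplit(m[3], ",")[[1]])))
  names(args) <- vapply(kv, `[`, "", 2)
  if (any(vapply(args, function(v) any(is.na(v)), TRUE)))
    stop("non-numeric value in config file ", path)
  do.call(sim_config, args)
}

# stationary distribution of a rate matrix (rows sum to zero)
.stationary <- function(Q) {
  n <- nrow(Q)
  if (n == 1) return(1)
  p <- qr.solve(rbind(t(Q), rep(1, n)), c(rep(0, n), 1))
  p <- pmax(p, 0)
  p / sum(p)
}

# Gillespie sample of the conformational path on [0, duration)
# returns data.frame(start, state); last segment runs to duration
.gillespie_path <- function(Q, duration) {
  n <- nrow(Q)
  p0 <- .stationary(Q)
  s <- sample.int(n, 1, prob = p0)
  starts <- numeric(64); states <- integer(64); m <- 0L
  t <- 0
  while (t < duration) {
    m <- m + 1L
    if (m > length(starts)) {
      starts <- c(starts, numeric(length(starts)))
      states <- c(states, integer(length(states)))
    }
    starts[m] <- t; states[m] <- s
    rate <- -Q[s, s]
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t >= duration) break
    pr <- Q[s, ]; pr[s] <- 0
    s <- sample.int(n, 1, prob = pr)
  }
  data.frame(start = starts[seq_len(m)], state = states[seq_len(m)])
}

# time-weighted mean state efficiency per bin
.bin_average_efficiency <- function(path, E, n_bins, bw) {
  e <- numeric(n_bins)
  ends <- c(path$start[-1], n_bins * bw)
  for (k in seq_len(nrow(path))) {
    a <- path$start[k]; b <- min(ends[k], n_bins * bw)
    if (b <= a) next
    i0 <- floor(a / bw) + 1
    i1 <- min(n_bins, ceiling(b / bw))
    idx <- i0:i1
    lo <- (idx - 1) * bw
    frac <- (pmin(b, lo + bw) - pmax(a, lo)) / bw
    e[idx] <- e[idx] + frac * E[path$state[k]]
  }
  e
}

# fraction of each bin covered by [t0, t1), only over touched bins
.add_interval <- function(acc, t0, t1, bw, n_bins, value) {
  if (t1 <= t0) return(acc)
  i0 <- floor(t0 / bw) + 1
  i1 <- min(n_bins, ceiling(t1 / bw))
  if (i0 > n_bins || i1 < i0) return(acc)
  idx <- i0:i1
  lo <- (idx - 1) * bw
  frac <- (pmin(t1, lo + bw) - pmax(t0, lo)) / bw
  acc[idx] <- acc[idx] + frac * value
  acc
}

# donor/acceptor counts for the fluorophore set: nd donors FRETing to na
# live acceptors with per-pair rate ratio E/(1-E)
.multi_acceptor_E <- function(e_bin, na) {
  if (na == 0) return(rep(0, length(e_bin)))
  phi <- e_bin / (1 - e_bin)
  na * phi / (1 + na * phi)
}

.fluor_composition <- function(n_fluor) {
  switch(n_fluor,
    if (runif(1) < 0.5) c(1L, 0L) else c(0L, 1L),  # 1 step
    c(1L, 1L),                                     # 2 steps: one D, one A
    if (runif(1) < 0.5) c(2L, 1L) else c(1L, 2L),  # 3 steps
    c(2L, 2L))                                     # 4 steps
}

#' Simulate one synthetic smFRET photon trace
#'
#' Samples a molecule's labelling stoichiometry, per-fluorophore bleach
#' times, and a continuous-time Markov conformational path (Gillespie), then
#' draws per-bin Poisson photon counts.  While a donor and at least one
#' acceptor are alive, the donor's `total_intensity` photons are partitioned
#' `(1 - E)` into the donor channel and `E` into the acceptor channel (with
#' multiple live acceptors competing for the transfer); after all acceptors
#' bleach, every donor-excitation photon routes to the donor channel; after a
#' donor bleaches its stream stops.  The direct-excitation acceptor channel
#' is a constant-mean Poisson stream per live acceptor.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical traces.
#' @param molecule_id identifier stored in the trace.
#' @return list with elements `trace` (a [photon_trace()]) and `truth`
#'   (ground truth: per-bin `state_path`, `bin_efficiency`, `bleach_times`,
#'   `stoichiometry`, and the continuous `path`).
#' @export
simulate_trace <- function(config, seed = NULL, molecule_id = "mol_001") {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object")
  if (!is.null(seed)) set.seed(as.integer(seed))
  bw <- config$bin_width
  n_bins <- floor(config$duration / bw)
  dur <- n_bins * bw
  E <- config$state_efficiencies

  n_fluor <- sample.int(4L, 1L, prob = config$stoichiometry_weights)
  comp <- .fluor_composition(n_fluor)
  nd <- comp[1]; na <- comp[2]
  bleach_d <- if (nd > 0 && config$bleach_rate_donor > 0)
    rexp(nd, config$bleach_rate_donor) else rep(Inf, nd)
  bleach_a <- if (na > 0 && config$bleach_rate_acceptor > 0)
    rexp(na, config$bleach_rate_acceptor) else rep(Inf, na)

  path <- .gillespie_path(config$rate_matrix, dur)
  e_bin <- .bin_average_efficiency(path, E, n_bins, bw)
  mid <- (seq_len(n_bins) - 0.5) * bw
  state_path <- path$state[findInterval(mid, path$start)]

  donor_mean <- rep(config$background, n_bins)
  acc_mean <- rep(config$background, n_bins)
  dir_mean <- rep(config$background, n_bins)

  events <- sort(unique(c(0, pmin(c(bleach_d, bleach_a), dur), dur)))
  for (k in seq_len(length(events) - 1)) {
    t0 <- events[k]; t1 <- events[k + 1]
    if (t1 <= t0) next
    ndl <- sum(bleach_d > t0)
    nal <- sum(bleach_a > t0)
    if (ndl > 0) {
      em <- .multi_acceptor_E(e_bin, nal)
      frac <- .add_interval(numeric(n_bins), t0, t1, bw, n_bins, 1)
      donor_mean <- donor_mean + frac * ndl * config$total_intensity * (1 - em)
      acc_mean <- acc_mean + frac * ndl * config$total_intensity * em
    }
    if (nal > 0)
      dir_mean <- .add_interval(dir_mean, t0, t1, bw, n_bins,
                                nal * config$direct_intensity)
  }

  trace <- photon_trace(
    molecule_id = molecule_id, bin_width = bw,
    donor = rpois(n_bins, donor_mean),
    acceptor = rpois(n_bins, acc_mean),
    acceptor_direct = rpois(n_bins, dir_mean),
    provenance = sprintf("fretscape simulate_trace n_states=%d", length(E)))
  truth <- structure(list(
    state_path = state_path,
    bin_efficiency = e_bin,
    bleach_times = list(donor = bleach_d, acceptor = bleach_a),
    stoichiometry = c(donor = nd, acceptor = na),
    path = path), class = "sim_truth")
  list(trace = trace, truth = truth)
}

#' Simulate a dataset of synthetic smFRET molecules
#'
#' Per-molecule seeds are drawn deterministically from the master seed, so a
#' dataset is reproducible as a whole while molecules remain independent.
#'
#' @param config a [sim_config()].
#' @param n_molecules number of molecules (>= 1).
#' @param seed master integer seed.
#' @param dir optional directory: traces and a manifest are written there in
#'   the package trace format (see [write_traces()]).
#' @param condition condition label recorded in the manifest.
#' @return invisible list of `list(trace, truth)` pairs.
#' @export
simulate_dataset <- function(config, n_molecules, seed = NULL, dir = NULL,
                             condition = NA_character_) {
  if (!is.numeric(n_molecules) || length(n_molecules) != 1 ||
      !is.finite(n_molecules) || n_molecules < 1)
    stop("n_molecules must be >= 1")
  n_molecules <- as.integer(n_molecules)
  if (!is.null(seed)) set.seed(as.integer(seed))
  seeds <- sample.int(2147483646L, n_molecules)
  mols <- lapply(seq_len(n_molecules), function(i)
    simulate_trace(config, seed = seeds[i],
                   molecule_id = sprintf("mol_%04d", i)))
  if (!is.null(dir))
    write_traces(lapply(mols, `[[`, "trace"), dir, condition = condition)
  invisible(mols)
}
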