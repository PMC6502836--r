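#' Convert FRET efficiency to inter-fluorophore distance
#'
#' Inverts the Forster relation `E = 1 / (1 + (R/R0)^6)`:
#' `R = R0 * (1/E - 1)^(1/6)`.  At `E = 0.5` the distance equals the
#' Forster radius.  Reported distances are conventionally rounded to the
#' nearest angstrom.
#'
#' @param E efficiencies, each strictly in (0, 1).
#' @param R0 Forster radius, angstrom (default 51, appropriate for the
#'   Alexa 555 / Alexa 647 pair; configurable).
#' @param round round to the nearest angstrom (default `TRUE`, the
#'   reporting convention).
#' @return distances in angstrom.
#' @export
efficiency_to_distance <- function(E, R0 = 51, round = TRUE) {
  if (any(!is.finite(E)) || any(E <= 0 | E >= 1))
    stop("E must lie strictly inside (0, 1)")
  if (!is.numeric(R0) || R0 <= 0) stop("R0 must be positive")
  r <- R0 * (1 / E - 1)^(1 / 6)
  if (round) round(r) else r
}

#' Convert distance to FRET efficiency
#'
#' Forster relation `E = 1 / (1 + (R/R0)^6)`; exact inverse of
#' [efficiency_to_distance()] (before rounding).
#'
#' @param R distances, angstrom (> 0).
#' @param R0 Forster radius, angstrom.
#' @return efficiencies in (0, 1).
#' @export
distance_to_efficiency <- function(R, R0 = 51) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("R must be positive")
  if (!is.numeric(R0) || R0 <= 0) stop("R0 must be positive")
  1 / (1 + (R / R0)^6)
}

#' Per-state distance table
#'
#' @param state_model a [state_model()] (or numeric efficiencies).
#' @param R0 Forster radius, angstrom.
#' @return data frame with `state`, `efficiency`, `R0`, `distance_A`
#'   (rounded) and `distance_exact`.
#' @export
distance_table <- function(state_model, R0 = 51) {
  E <- if (inherits(state_model, "state_model"))
    state_model$state_efficiencies else as.numeric(state_model)
  data.frame(state = seq_along(E), efficiency = E, R0 = R0,
             distance_A = efficiency_to_distance(E, R0, round = TRUE),
             distance_exact = efficiency_to_distance(E, R0, round = FALSE))
}

#' Count state-to-state transitions
#'
#' Bin-to-bin assignment changes are counted within molecules only — a
#' molecule boundary never contributes a transition.  The per-bin transition
#' probability divides each count by the total number of bins spent in the
#' starting state, honouring the convention that the starting-state
#' concentration is its fractional occupancy.
#'
#' @param assignments list of per-molecule integer state vectors (or one
#'   vector), or a [state_model()].
#' @param n_states number of states (inferred if a model is given).
#' @return list with `transition_counts` (integer matrix, zero diagonal)
#'   and `transition_probs`.
#' @export
count_transitions <- function(assignments, n_states = NULL) {
  if (inherits(assignments, "state_model")) {
    n_states <- assignments$n_states
    assignments <- assignments$assignments
  }
  if (is.numeric(assignments)) assignments <- list(as.integer(assignments))
  if (is.null(n_states))
    n_states <- max(unlist(assignments, use.names = FALSE))
  counts <- matrix(0L, n_states, n_states)
  time_in <- numeric(n_states)
  for (a in assignments) {
    a <- as.integer(a)
    if (any(a < 1 | a > n_states)) stop("assignment outside 1..n_states")
    time_in <- time_in + tabulate(a, nbins = n_states)
    if (length(a) < 2) next
    from <- a[-length(a)]; to <- a[-1]
    ch <- from != to
    if (any(ch)) {
      tab <- table(factor(from[ch], levels = seq_len(n_states)),
                   factor(to[ch], levels = seq_len(n_states)))
      counts <- counts + matrix(as.integer(tab), n_states, n_states)
    }
  }
  probs <- counts / ifelse(time_in > 0, time_in, NA_real_)
  probs[is.na(probs)] <- 0
  list(transition_counts = counts, transition_probs = probs)
}

#' Standard free energy of each state from occupancies
#'
#' `deltaG_i = -ln(p_i / p_max)` in units of kBT, so the most populated
#' state sits at exactly 0 and every other state is >= 0.  This is
#' `-kBT ln Keq` with `Keq` the occupancy ratio against the reference
#' state.  Unvisited states (zero occupancy) get `Inf` and are flagged.
#'
#' @param occupancies state occupancies summing to 1.
#' @return numeric vector of free energies (kBT); attribute `"unvisited"`
#'   marks zero-occupancy states.
#' @export
state_free_energies <- function(occupancies) {
  p <- as.numeric(occupancies)
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("occupancies must be non-negative and sum to 1")
  dG <- -log(p / max(p))
  attr(dG, "unvisited") <- which(p == 0)
  dG
}

#' Activation energy barriers from transition probabilities
#'
#' First-order rates `k_ij = p_ij / bin_width` (small-p limit; the exact
#' form `-ln(1 - p)/bin_width` is available via `method = "log"`), then the
#' Arrhenius relation `Ea_ij = -ln(k_ij / A)` in kBT units with
#' pre-exponential `A`.  Forward and reverse barriers are averaged in the
#' symmetrized output; pairs with an unobserved direction are `NA` there and
#' flagged.
#'
#' @param transition_probs per-bin transition probability matrix.
#' @param bin_width analysis bin width, ms (default 5).
#' @param A Arrhenius pre-exponential, ms^-1 (default 10).
#' @param method `"linear"` (`k = p/dt`, default) or `"log"`
#'   (`k = -ln(1-p)/dt`).
#' @return list with `rates` (ms^-1), `Ea` (kBT; `Inf` where `p = 0`) and
#'   `Ea_symmetrized` (`NA` on pairs missing a direction, listed in
#'   attribute `"omitted_pairs"`).
#' @export
activation_energies <- function(transition_probs, bin_width = 5, A = 10,
                                method = c("linear", "log")) {
  method <- match.arg(method)
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (!is.numeric(A) || A <= 0) stop("A must be > 0")
  p <- as.matrix(transition_probs)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("transition probabilities must lie in [0, 1]")
  k <- switch(method, linear = p / bin_width,
              log = -log(1 - pmin(p, 1 - 1e-12)) / bin_width)
  Ea <- ifelse(k > 0, -log(k / A), Inf)
  diag(Ea) <- NA_real_
  Ea_sym <- (Ea + t(Ea)) / 2
  omitted <- which(is.infinite(Ea_sym), arr.ind = TRUE)
  Ea_sym[is.infinite(Ea_sym)] <- NA_real_
  attr(Ea_sym, "omitted_pairs") <- omitted
  list(rates = k, Ea = Ea, Ea_symmetrized = Ea_sym)
}

#' Convert energies from kBT to kcal/mol
#'
#' @param x energies in kBT units.
#' @param temperature kelvin (default 298).
#' @return energies in kcal/mol (R = 1.98720425e-3 kcal/(mol K)).
#' @export
kbt_to_kcal <- function(x, temperature = 298) {
  x * 1.98720425e-3 * temperature
}

#' Assemble the full energy landscape of a state model
#'
#' Combines occupancy-based standard free energies, the transition map, the
#' per-pair rates and Arrhenius activation barriers, and the Forster
#' distance table into one object.
#'
#' @param state_model a [state_model()].
#' @param bin_width analysis bin width, ms.
#' @param A Arrhenius pre-exponential, ms^-1 (default 10).
#' @param R0 Forster radius, angstrom (default 51).
#' @param rate_method passed to [activation_energies()].
#' @return object of class `energy_landscape`.
#' @export
energy_landscape <- function(state_model, bin_width = 5, A = 10, R0 = 51,
                             rate_method = "linear") {
  stopifnot(inherits(state_model, "state_model"))
  tr <- count_transitions(state_model)
  dG <- state_free_energies(state_model$occupancies)
  K_eq <- outer(state_model$occupancies, state_model$occupancies, `/`)
  ae <- activation_energies(tr$transition_probs, bin_width, A,
                            method = rate_method)
  structure(list(
    occupancies = state_model$occupancies,
    delta_G = dG,
    K_eq = K_eq,
    transition_counts = tr$transition_counts,
    transition_probs = tr$transition_probs,
    rates = ae$rates,
    Ea = ae$Ea,
    Ea_symmetrized = ae$Ea_symmetrized,
    pre_exponential_A = A,
    bin_width = bin_width,
    distances = distance_table(state_model, R0)), class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  n <- length(x$delta_G)
  cat(sprintf("<energy_landscape> %d state(s); reference state dG = 0 kBT\n", n))
  print(data.frame(state = seq_len(n),
                   efficiency = round(x$distances$efficiency, 3),
                   distance_A = x$distances$distance_A,
                   occupancy = round(x$occupancies, 3),
                   delta_G_kBT = round(x$delta_G, 3)), row.names = FALSE)
  if (n > 1) {
    cat("transition counts:\n")
    print(x$transition_counts)
  }
  invisible(x)
}
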