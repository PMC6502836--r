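test_that("Forster inversion reproduces the reference efficiency-distance pairs", {
  pairs <- rbind(
    c(0.89, 36), c(0.95, 31), c(0.93, 33),
    c(0.69, 45), c(0.83, 39), c(0.92, 34),
    c(0.79, 41), c(0.70, 44))
  expect_equal(efficiency_to_distance(pairs[, 1], R0 = 51), pairs[, 2])
  expect_equal(efficiency_to_distance(0.5, R0 = 51), 51)
  expect_error(efficiency_to_distance(1.2), "inside")
  expect_error(efficiency_to_distance(0.5, R0 = -2), "positive")
})

test_that("distance conversion inverts exactly before rounding", {
  E <- seq(0.05, 0.95, by = 0.05)
  R <- efficiency_to_distance(E, R0 = 51, round = FALSE)
  expect_equal(distance_to_efficiency(R, R0 = 51), E, tolerance = 1e-12)
  # strictly decreasing in E; E = 0.5 at R0 for any R0
  expect_true(all(diff(R) < 0))
  expect_equal(efficiency_to_distance(0.5, R0 = 62.7, round = FALSE), 62.7)
})

test_that("distance table rounds for reporting and keeps exact values", {
  dt <- distance_table(c(0.93, 0.82, 0.70, 0.58, 0.39), R0 = 51)
  expect_identical(dt$distance_A, c(33, 40, 44, 48, 55))
  expect_equal(round(dt$distance_exact), dt$distance_A)
})

test_that("transition counting is within-molecule, additive, zero-diagonal", {
  tr <- count_transitions(list(c(1L, 1L, 2L, 2L, 1L)), 2)
  expect_identical(tr$transition_counts,
                   matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE))
  expect_equal(tr$transition_probs[1, 2], 1 / 3)
  expect_equal(tr$transition_probs[2, 1], 1 / 2)
  # two molecules never create a boundary transition
  a <- list(c(1L, 1L, 2L), c(2L, 1L, 1L))
  both <- count_transitions(a, 2)$transition_counts
  single <- count_transitions(list(c(1L, 1L, 2L, 2L, 1L, 1L)), 2)$transition_counts
  expect_identical(both, count_transitions(a[1], 2)$transition_counts +
                     count_transitions(a[2], 2)$transition_counts)
  expect_true(all(diag(both) == 0))
  # single-state model: empty map is valid
  empty <- count_transitions(list(rep(1L, 10)), 1)
  expect_identical(sum(empty$transition_counts), 0L)
})

test_that("state free energies follow -ln(p/pmax) with exact reference zero", {
  expect_equal(state_free_energies(c(0.5, 0.5)), c(0, 0),
               ignore_attr = TRUE)
  dG <- state_free_energies(c(0.6, 0.3, 0.1))
  expect_equal(as.numeric(dG), c(0, log(2), log(6)), tolerance = 1e-12)
  expect_identical(as.numeric(state_free_energies(1)), 0)
  dG0 <- state_free_energies(c(0.7, 0.3, 0))
  expect_true(is.infinite(dG0[3]))
  expect_identical(attr(dG0, "unvisited"), 3L)
  # dG ordering is the reverse of occupancy ordering
  p <- c(0.15, 0.4, 0.05, 0.4)
  expect_identical(order(as.numeric(state_free_energies(p))), order(-p))
})

test_that("Arrhenius barriers match hand-evaluated rates", {
  p <- matrix(c(0, 0.05, 0.05, 0), 2, byrow = TRUE)
  ae <- activation_energies(p, bin_width = 5, A = 10)
  expect_equal(ae$rates[1, 2], 0.01)
  expect_equal(ae$Ea[1, 2], log(1000), tolerance = 1e-12)
  # k = A gives a vanishing barrier
  ae0 <- activation_energies(matrix(c(0, 0.5, 0.5, 0), 2), bin_width = 5, A = 0.1)
  expect_equal(ae0$Ea[1, 2], 0)
  # halving p raises Ea by exactly ln 2
  ae2 <- activation_energies(p / 2, bin_width = 5, A = 10)
  expect_equal(ae2$Ea[1, 2] - ae$Ea[1, 2], log(2), tolerance = 1e-12)
  # unobserved direction: infinite barrier, symmetrized entry omitted
  p3 <- matrix(c(0, 0.02, 0, 0), 2, byrow = TRUE)
  ae3 <- activation_energies(p3, 5, 10)
  expect_true(is.infinite(ae3$Ea[2, 1]))
  expect_true(is.na(ae3$Ea_symmetrized[1, 2]))
  expect_equal(kbt_to_kcal(1), 0.5922, tolerance = 1e-3)
})

test_that("the assembled landscape honours detailed balance on long traces", {
  Q <- matrix(c(-0.008, 0.008, 0.004, -0.004), 2, byrow = TRUE)
  cfg <- sim_config(c(0.8, 0.4), rate_matrix = Q, bleach_rate_donor = 0,
                    bleach_rate_acceptor = 0, total_intensity = 30,
                    stoichiometry_weights = c(0, 1, 0, 0), duration = 3e5)
  m <- simulate_trace(cfg, seed = 23)
  et <- efficiency_trace(m$trace, bin_ms = 5, background_d = 2, background_a = 2)
  sm <- stasi_fit(list(et), max_states = 4)
  expect_identical(sm$n_states, 2L)
  land <- energy_landscape(sm, bin_width = 5, A = 10)
  # stationary occupancy pi = (1/3, 2/3); dG2 - dG1 = ln(pi1/pi2) = -ln 2
  expect_equal(land$delta_G[[1]] - land$delta_G[[2]], log(2), tolerance = 0.15)
  # recovered rate ordering matches the generator (k12 > k21)
  expect_gt(land$rates[1, 2], land$rates[2, 1])
  expect_gt(land$Ea[2, 1], land$Ea[1, 2])
  expect_equal(land$Ea_symmetrized[1, 2],
               (land$Ea[1, 2] + land$Ea[2, 1]) / 2)
})
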