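test_that("noiseless two-step staircase yields exact change points", {
  x <- rep(c(100, 50, 0), each = 50)
  st <- detect_bleach_steps(x, bin_width = 1)
  expect_identical(st$step_count, 2L)
  expect_equal(sort(st$step_times), c(50, 100))
  expect_identical(detect_bleach_steps(rep(40, 60), 1)$step_count, 0L)
  expect_error(detect_bleach_steps(rep(5, 10), 1), "at least 20")
})

test_that("step detection matches the exhaustive oracle on noiseless input", {
  set.seed(14)
  for (rep in 1:10) {
    levels <- sample(c(120, 80, 40, 0), sample(2:4, 1))
    lens <- sample(15:60, length(levels), replace = TRUE)
    x <- rep(levels, lens)
    if (length(x) > 200) x <- x[1:200]
    got <- fretscape:::.segment_series(x, t_threshold = 5, min_segment = 3)
    want <- brute_force_changepoints(x)
    want <- want[want >= 3 & want <= length(x) - 3]
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("two-fluorophore bleach cascades are counted and timed correctly", {
  set.seed(4)
  n_ok_count <- 0; n_ok_time <- 0; n_trials <- 200
  for (i in seq_len(n_trials)) {
    b1 <- runif(1, 300, 900)
    b2 <- b1 + runif(1, 100, 800)
    mu <- 50 * ((seq_len(2000) <= b1) + (seq_len(2000) <= b2)) + 2
    x <- rpois(2000, mu)
    st <- detect_bleach_steps(x, bin_width = 1)
    if (st$step_count == 2) {
      n_ok_count <- n_ok_count + 1
      if (all(abs(sort(st$step_times) - c(b1, b2)) <= 10))
        n_ok_time <- n_ok_time + 1
    }
  }
  expect_gte(n_ok_count / n_trials, 0.95)
  expect_gte(n_ok_time / n_trials, 0.95)
})

test_that("anticorrelation statistic behaves at its three reference points", {
  # perfectly anticorrelated two-level pair
  d <- rep(c(10L, 40L), 50)
  tr <- photon_trace("perfect", 1, donor = d, acceptor = 50L - d)
  expect_equal(check_anticorrelation(tr), -1.0)
  # independent Poisson channels
  set.seed(2)
  tr2 <- photon_trace("indep", 1, rpois(1e4, 25), rpois(1e4, 25))
  expect_lt(abs(check_anticorrelation(tr2)), 0.2)
  # genuine 2-state FRET dynamics
  cfg <- sim_config(c(0.9, 0.5), bleach_rate_donor = 0,
                    bleach_rate_acceptor = 0,
                    stoichiometry_weights = c(0, 1, 0, 0), duration = 3000)
  m <- simulate_trace(cfg, seed = 6)
  expect_lt(check_anticorrelation(m$trace, bin_ms = 5), -0.5)
  # zero-variance channel flagged
  tr3 <- photon_trace("flat", 1, rep(5L, 100), rpois(100, 20))
  expect_true(is.na(check_anticorrelation(tr3)))
})

test_that("molecule selection accepts single pairs and names rejection causes", {
  cfg11 <- sim_config(c(0.9, 0.5), stoichiometry_weights = c(0, 1, 0, 0),
                      duration = 8000)
  m <- simulate_trace(cfg11, seed = 5)
  r <- select_molecule(m$trace)
  expect_true(r$accepted)
  expect_equal(r$fret_region[["end_ms"]],
               min(unlist(m$truth$bleach_times)), tolerance = 10)
  # two acceptors: rejected on the acceptor step count
  cfg12 <- sim_config(c(0.9, 0.5), stoichiometry_weights = c(0, 0, 1, 0))
  set.seed(31)
  found <- FALSE
  for (i in 1:20) {
    m2 <- simulate_trace(cfg12, seed = 100 + i)
    if (m2$truth$stoichiometry[["acceptor"]] == 2 &&
        all(unlist(m2$truth$bleach_times) < 15000)) { found <- TRUE; break }
  }
  expect_true(found)
  r2 <- select_molecule(m2$trace)
  expect_false(r2$accepted)
  expect_identical(r2$reject_reason, "multiple_acceptor_steps")
})

test_that("acceptance is invariant to uniform intensity scaling", {
  cfg <- sim_config(c(0.9, 0.5), stoichiometry_weights = c(0, 1, 0, 0),
                    duration = 8000)
  m <- simulate_trace(cfg, seed = 9)
  tr <- m$trace
  tr3 <- photon_trace(tr$molecule_id, tr$bin_width, tr$donor * 3L,
                      tr$acceptor * 3L, tr$acceptor_direct * 3L)
  r <- select_molecule(tr); r3 <- select_molecule(tr3)
  expect_identical(r$accepted, r3$accepted)
  expect_identical(r$donor_steps, r3$donor_steps)
  expect_identical(r$acceptor_steps, r3$acceptor_steps)
})

test_that("qc_table summarizes an ensemble one row per molecule", {
  cfg <- sim_config(c(0.85, 0.55), duration = 6000)
  mols <- simulate_dataset(cfg, 12, seed = 13)
  qt <- qc_table(lapply(mols, `[[`, "trace"))
  expect_identical(nrow(qt), 12L)
  expect_true(all(qt$reject_reason[qt$accepted] == "accepted"))
  expect_true(all(qt$fret_end_ms <= 20000))
})
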