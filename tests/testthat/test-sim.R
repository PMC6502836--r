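test_that("config validation rejects malformed generative parameters", {
  expect_error(sim_config(c(0.5, 1.2)), "inside")
  expect_error(sim_config(0.5, rate_matrix = matrix(-1, 1, 1) * NA), "finite")
  expect_error(sim_config(c(0.7, 0.3),
                          rate_matrix = matrix(c(-1, 1, -2, 2), 2, byrow = TRUE)),
               "off-diagonal")
  expect_error(sim_config(0.5, stoichiometry_weights = c(1, 1, 1, 1) / 3),
               "summing to 1")
  cfg <- sim_config(c(0.9, 0.5))
  expect_s3_class(cfg, "sim_config")
  expect_equal(rowSums(cfg$rate_matrix), c(0, 0))
})

test_that("a single state at E = 0.5 splits photons evenly between channels", {
  cfg <- sim_config(0.5, background = 0, bleach_rate_donor = 0,
                    bleach_rate_acceptor = 0,
                    stoichiometry_weights = c(0, 1, 0, 0), duration = 1e4)
  m <- simulate_trace(cfg, seed = 1)
  n <- length(m$trace$donor)
  se <- sqrt(2 * cfg$total_intensity / 2 / n)   # se of the mean difference
  expect_lt(abs(mean(m$trace$donor) - mean(m$trace$acceptor)), 3 * se)
  # energy-transfer partition: total conserved
  expect_lt(abs(mean(m$trace$donor + m$trace$acceptor) - cfg$total_intensity),
            3 * sqrt(cfg$total_intensity / n))
})

test_that("dwell times follow the exponential 1/k law", {
  Q <- matrix(c(-0.02, 0.02, 0.02, -0.02), 2, byrow = TRUE)
  cfg <- sim_config(c(0.9, 0.5), rate_matrix = Q, bleach_rate_donor = 0,
                    bleach_rate_acceptor = 0,
                    stoichiometry_weights = c(0, 1, 0, 0), duration = 5000)
  dwells <- do.call(rbind, lapply(1:100, function(i) {
    m <- simulate_trace(cfg, seed = i)
    path_dwells(m$truth$path, cfg$duration)
  }))
  for (s in 1:2)
    expect_lt(abs(mean(dwells$dwell[dwells$state == s]) - 50), 5)  # 10% of 1/k
})

test_that("empirical occupancy converges to the stationary distribution", {
  Q <- matrix(c(-0.01, 0.01, 0.004, -0.004), 2, byrow = TRUE)
  cfg <- sim_config(c(0.8, 0.4), rate_matrix = Q, bleach_rate_donor = 0,
                    bleach_rate_acceptor = 0,
                    stoichiometry_weights = c(0, 1, 0, 0), duration = 1e6)
  set.seed(3)
  p <- fretscape:::.gillespie_path(Q, cfg$duration)
  d <- diff(c(p$start, cfg$duration))
  occ <- tapply(d, factor(p$state, levels = 1:2), sum) / cfg$duration
  stat <- c(0.004, 0.01) / 0.014
  expect_lt(max(abs(occ - stat)), 0.02)
})

test_that("labelling stoichiometry reproduces the bleach-step mixture", {
  cfg <- sim_config(c(0.9, 0.5), duration = 500)
  set.seed(21)
  mols <- simulate_dataset(cfg, 500, seed = 21)
  st <- t(vapply(mols, function(m) m$truth$stoichiometry, c(donor = 0L, acceptor = 0L)))
  frac_11 <- mean(st[, 1] == 1 & st[, 2] == 1)
  expect_lt(abs(frac_11 - 0.35), 3 * sqrt(0.35 * 0.65 / 500))
  n_fluor <- rowSums(st)
  expect_lt(abs(mean(n_fluor == 3) - 0.50), 3 * sqrt(0.5 * 0.5 / 500))
})

test_that("per-bin proximity ratio is an unbiased efficiency estimator", {
  for (E in c(0.5, 0.7)) {
    cfg <- sim_config(E, background = 0, bleach_rate_donor = 0,
                      bleach_rate_acceptor = 0,
                      stoichiometry_weights = c(0, 1, 0, 0), duration = 2e4)
    m <- simulate_trace(cfg, seed = 7)
    e <- compute_efficiency(m$trace$donor, m$trace$acceptor)
    expect_lt(abs(mean(e, na.rm = TRUE) - E), 0.005)
  }
})

test_that("photon counts are non-negative integers and seeds reproduce", {
  cfg <- sim_config(c(0.8, 0.4), duration = 2000)
  a <- simulate_trace(cfg, seed = 5)
  b <- simulate_trace(cfg, seed = 5)
  expect_identical(a$trace$donor, b$trace$donor)
  expect_identical(a$truth$state_path, b$truth$state_path)
  expect_true(all(a$trace$donor >= 0))
  expect_type(a$trace$donor, "integer")
  expect_equal(length(a$truth$state_path), 2000)
})

test_that("dataset simulation is deterministic and rejects empty requests", {
  cfg <- sim_config(0.7, duration = 600)
  d1 <- file.path(tempdir(), "sim_d1"); d2 <- file.path(tempdir(), "sim_d2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_dataset(cfg, 10, seed = 2, dir = d1)
  simulate_dataset(cfg, 10, seed = 2, dir = d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(simulate_dataset(cfg, 0, seed = 1), ">= 1")
})
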