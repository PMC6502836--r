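test_that("noiseless two-level traces are recovered exactly", {
  x <- rep(c(0.9, 0.6, 0.9), c(40, 40, 40))
  sm <- stasi_fit(list(x))
  expect_identical(sm$n_states, 2L)
  expect_equal(sm$state_efficiencies, c(0.9, 0.6))
  expect_identical(sm$assignments[[1]], rep(c(1L, 2L, 1L), c(40, 40, 40)))
  # constant trace: one state
  sm1 <- stasi_fit(list(rep(0.42, 50)))
  expect_identical(sm1$n_states, 1L)
  expect_equal(sm1$state_efficiencies, 0.42)
})

test_that("MDL-selected state count equals the exhaustive partition optimum", {
  # one constant trace per segment, bounded noise so no bin is masked:
  # the candidate clusterings then live on whole traces and the cost has
  # no transition term, making full enumeration feasible
  set.seed(17)
  levels <- c(0.92, 0.92, 0.63, 0.63, 0.30, 0.30)
  traces <- lapply(levels, function(mu) mu + runif(80, -0.05, 0.05))
  sm <- stasi_fit(traces, use_denoised = FALSE)
  sigma <- estimate_noise_sd(traces)
  parts <- set_partitions(length(traces))
  costs <- vapply(parts, partition_mdl, 0, traces = traces, sigma = sigma)
  best <- parts[[which.min(costs)]]
  expect_identical(sm$n_states, length(best))
  oracle_means <- sort(vapply(best, function(cl) mean(unlist(traces[cl])), 0),
                       decreasing = TRUE)
  expect_equal(sm$state_efficiencies, oracle_means, tolerance = 1e-6)
})

test_that("MDL cost is convex around the selected state count", {
  set.seed(30)
  truth <- c(0.9, 0.6, 0.3)
  traces <- lapply(1:8, function(i) {
    s <- sample(1:3, 20, replace = TRUE)
    rep(truth[s], each = 10) + rnorm(200, 0, 0.04)
  })
  sm <- stasi_fit(traces, max_states = 6)
  mdl <- attr(sm, "mdl")[1:6]
  k <- which.min(mdl)
  expect_identical(sm$n_states, 3L)
  expect_identical(k, 3L)
  expect_true(all(diff(mdl[1:k]) < 0))       # merging too far is penalized
  expect_true(all(mdl[(k + 1):6] > mdl[k]))  # splitting further never wins
})

test_that("stasi_fit is invariant under trace reordering", {
  set.seed(12)
  traces <- lapply(1:6, function(i)
    rep(sample(c(0.85, 0.45), 8, replace = TRUE), each = 15) + rnorm(120, 0, 0.05))
  a <- stasi_fit(traces)
  b <- stasi_fit(rev(traces))
  expect_identical(a$n_states, b$n_states)
  expect_equal(a$state_efficiencies, b$state_efficiencies, tolerance = 1e-9)
  expect_equal(a$occupancies, b$occupancies, tolerance = 1e-9)
})

test_that("occupancies are exact time fractions of the assignments", {
  sm <- state_model(c(0.8, 0.5, 0.2), rep(0.1, 3),
                    list(rep(1:3, c(10, 30, 60))))
  expect_identical(sum(sm$occupancies), 1)
  expect_equal(sm$occupancies, c(0.1, 0.3, 0.6))
  expect_identical(sm$n_bins, c(10L, 30L, 60L))
})

test_that("the Gaussian HMM matches the noiseless and single-state references", {
  x <- rep(c(0.9, 0.6), each = 60) + rep(c(0.001, -0.001), 60)
  hm <- hmm_fit(list(x), n_states_max = 3, n_restarts = 3)
  expect_identical(hm$n_states, 2L)
  expect_equal(hm$state_efficiencies, c(0.9, 0.6), tolerance = 0.01)
  set.seed(3)
  y <- rnorm(600, 0.7, 0.05)
  hm1 <- hmm_fit(list(y), n_states_max = 3, n_restarts = 3)
  expect_identical(hm1$n_states, 1L)
})

test_that("segmentation and HMM agree on a simulated multi-state dataset", {
  truth <- c(0.88, 0.62, 0.35)
  cfg <- sim_config(truth, mean_dwell = 150, total_intensity = 20,
                    stoichiometry_weights = c(0, 1, 0, 0), duration = 6000)
  mols <- simulate_dataset(cfg, 25, seed = 19)
  traces <- lapply(mols, `[[`, "trace")
  qt <- qc_table(traces)
  eff <- lapply(which(qt$accepted), function(i) {
    r <- attr(qt, "reports")[[i]]
    efficiency_trace(traces[[i]], region = r$fret_region, bin_ms = 5,
                     background_d = 2, background_a = 2)
  })
  sm <- stasi_fit(eff, max_states = 5)
  hm <- hmm_fit(eff, n_states_max = 5, n_restarts = 5)
  expect_identical(sm$n_states, 3L)
  expect_identical(hm$n_states, 3L)
  expect_lt(max(abs(sm$state_efficiencies - truth)), 0.02)
  expect_lt(max(abs(sm$state_efficiencies - hm$state_efficiencies)), 0.03)
})

test_that("Gaussian mixture fitting recovers known peaks and is monotone in width", {
  x <- seq(0.005, 1.045, by = 0.01)
  mix <- function(mu, s, w) rowSums(vapply(seq_along(mu), function(k)
    w[k] * dnorm(x, mu[k], s[k]), numeric(length(x))))
  h <- data.frame(mid = x, density = mix(c(0.89, 0.70), c(0.04, 0.04), c(0.5, 0.5)))
  fit <- fit_gaussians(h, c(0.85, 0.72), sd_init = 0.05)
  expect_lt(max(abs(fit$peak_E - c(0.89, 0.70))), 0.005)
  expect_equal(sum(fit$area), 1, tolerance = 0.01)
  # single component: area 1
  h1 <- data.frame(mid = x, density = mix(0.6, 0.05, 1))
  f1 <- fit_gaussians(h1, 0.55, sd_init = 0.04)
  expect_equal(f1$area, 1, tolerance = 0.01)
  # narrower input -> smaller fitted FWHM
  h2 <- data.frame(mid = x, density = mix(0.6, 0.02, 1))
  f2 <- fit_gaussians(h2, 0.55, sd_init = 0.04)
  expect_lt(f2$fwhm, f1$fwhm)
})
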