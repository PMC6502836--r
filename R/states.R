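#' Conformational state model
#'
#' Constructor used by [stasi_fit()] and [hmm_fit()].  States are sorted by
#' decreasing efficiency; assignments are per-molecule integer vectors
#' referencing that ordering; occupancies are the fraction of analysis bins
#' per state and sum to 1.
#'
#' @param state_efficiencies per-state mean efficiency, any order.
#' @param state_halfwidths per-state Gaussian FWHM of the raw efficiencies.
#' @param assignments list (one element per molecule) of per-bin state
#'   indices, referring to the order of `state_efficiencies`.
#' @param method `"stasi"` or `"hmm"`.
#' @param converged logical flag (HMM EM convergence; `TRUE` for STaSI).
#' @return object of class `state_model`.
#' @export
state_model <- function(state_efficiencies, state_halfwidths, assignments,
                        method = c("stasi", "hmm"), converged = TRUE) {
  method <- match.arg(method)
  K <- length(state_efficiencies)
  ord <- order(state_efficiencies, decreasing = TRUE)
  relabel <- match(seq_len(K), ord)
  assignments <- lapply(assignments, function(a) relabel[a])
  counts <- tabulate(unlist(assignments, use.names = FALSE), nbins = K)
  structure(list(
    n_states = K,
    state_efficiencies = state_efficiencies[ord],
    state_halfwidths = state_halfwidths[ord],
    assignments = assignments,
    n_bins = counts,
    occupancies = counts / sum(counts),
    method = method,
    converged = converged), class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model:%s> %d state(s) over %d molecules, %d bins\n",
              x$method, x$n_states, length(x$assignments), sum(x$n_bins)))
  print(data.frame(state = seq_len(x$n_states),
                   efficiency = round(x$state_efficiencies, 4),
                   fwhm = round(x$state_halfwidths, 4),
                   occupancy = round(x$occupancies, 4)), row.names = FALSE)
  invisible(x)
}

.as_eff_list <- function(traces, use_denoised) {
  if (is.numeric(traces)) traces <- list(traces)
  lapply(traces, function(tr) {
    if (is.numeric(tr)) as.numeric(tr)
    else if (use_denoised) as.numeric(tr$denoised) else as.numeric(tr$raw)
  })
}

# agglomerative merging of segment means; returns, for each candidate state
# count K <= keep_max, the segment -> cluster map and cluster means
.merge_levels <- function(means, weights, keep_max) {
  m <- length(means)
  cl <- seq_len(m)            # segment -> cluster id (a segment index)
  cmean <- means; cw <- weights
  alive <- rep(TRUE, m)
  out <- vector("list", m)
  snapshot <- function(k) {
    ids <- which(alive)
    list(map = match(cl, ids), means = cmean[ids], k = k)
  }
  if (m <= keep_max) out[[m]] <- snapshot(m)
  for (k in rev(seq_len(m - 1))) {
    ids <- which(alive)
    o <- order(cmean[ids])
    gaps <- diff(cmean[ids][o])
    j <- which.min(gaps)
    i1 <- ids[o][j]; i2 <- ids[o][j + 1]
    w <- cw[i1] + cw[i2]
    cmean[i1] <- (cmean[i1] * cw[i1] + cmean[i2] * cw[i2]) / w
    cw[i1] <- w
    alive[i2] <- FALSE
    cl[cl == i2] <- i1
    if (k <= keep_max) out[[k]] <- snapshot(k)
  }
  out
}

# MDL cost: residual code length + model cost.  Each state costs half a
# log2(N) (its mean, to the precision the data support); each surviving
# transition costs its position (log2 N) plus the identity of the state it
# enters (log2 K).
.mdl_cost <- function(ss_total, K, n_transitions, N, sigma) {
  fit <- if (sigma > 0) ss_total / (2 * sigma^2 * log(2))
         else if (ss_total > N * 1e-18) Inf else 0
  fit + 0.5 * K * log2(N) + n_transitions * (log2(N) + log2(K))
}

#' STaSI-style state identification
#'
#' Step Transition and State Identification: (1) each trace is segmented
#' into constant levels by recursive t-test change-point splitting; (2)
#' candidate state sets are formed by hierarchically merging the nearest
#' segment means; (3) the state count minimizing a minimum-description-
#' length cost — a goodness-of-fit term scaled by the shot-noise level
#' (estimated from the finest wavelet details of the raw series) plus a
#' model-complexity term — is selected.  Segments map to their surviving
#' state; states closer than `min_separation` are merged and refit.
#'
#' States are fit globally across all molecules, as pooled efficiency
#' histograms are.
#'
#' @param traces list of `efficiency_trace` objects (or numeric vectors,
#'   taken as both raw and denoised).
#' @param use_denoised segment the denoised series (default) or the raw one.
#' @param t_threshold t-statistic threshold for a split (default 5).
#' @param min_segment minimum segment length, bins (default 3).
#' @param min_separation minimum efficiency separation between distinct
#'   states (default 0.03).
#' @param max_states largest candidate state count (default 10).
#' @return a [state_model()] with attribute `"mdl"` (the cost per candidate
#'   K) and `"sigma"` (the noise estimate).
#' @export
stasi_fit <- function(traces, use_denoised = TRUE, t_threshold = 5,
                      min_segment = 3, min_separation = 0.03,
                      max_states = 10) {
  ys <- .as_eff_list(traces, use_denoised)
  raws <- .as_eff_list(traces, FALSE)
  N <- sum(lengths(ys))
  if (length(ys) < 1 || N < 20)
    stop("stasi_fit needs at least one trace and 20 bins in total")

  # Per-trace change-point segmentation.  Bins flanking an interior change
  # point are time-averaged mixtures of two states (motion blur at the
  # analysis bin width); they keep their segment assignment but are
  # excluded ("core" mask) from all level statistics, where they would
  # otherwise seed spurious mid-gap states.
  seg_trace <- integer(0); seg_mean <- numeric(0); seg_len <- integer(0)
  seg_raw_mean <- numeric(0)
  seg_of_bin <- vector("list", length(ys))
  core_of_bin <- vector("list", length(ys))
  sigma <- estimate_noise_sd(raws)
  for (i in seq_along(ys)) {
    y <- ys[[i]]
    raw <- raws[[i]]
    cps <- .segment_series(y, t_threshold, min_segment)
    bounds <- c(0L, cps, length(y))
    nseg <- length(bounds) - 1
    ids <- integer(length(y))
    core <- rep(TRUE, length(y))
    core[cps] <- FALSE
    core[pmin(cps + 1L, length(y))] <- FALSE
    for (s in seq_len(nseg)) {
      idx <- (bounds[s] + 1):bounds[s + 1]
      take <- idx[core[idx]]
      if (length(take) >= 3 && sigma > 0) {
        # excursions too short for the change-point search (below the
        # minimum segment length) leave outlier bins inside a segment;
        # they are dwell data of another state, not level data of this one
        out <- abs(raw[take] - mean(raw[take])) > 3 * sigma
        if (any(out) && !all(out)) {
          core[take[out]] <- FALSE
          take <- take[!out]
        }
      }
      if (!length(take)) take <- idx[ceiling(length(idx) / 2)]
      seg_trace <- c(seg_trace, i)
      seg_mean <- c(seg_mean, mean(y[take]))
      seg_len <- c(seg_len, length(take))
      seg_raw_mean <- c(seg_raw_mean, mean(raw[take]))
      ids[idx] <- length(seg_mean)
    }
    seg_of_bin[[i]] <- ids
    core_of_bin[[i]] <- core
  }
  m <- length(seg_mean)

  # candidate sets come from merging the (denoised) segment means; the MDL
  # fit term is scored against the observed data, whose noise level sigma
  # refers to
  keep_max <- min(max_states, m)
  cands <- .merge_levels(seg_mean, seg_len, keep_max)
  Ks <- which(!vapply(cands, is.null, TRUE))
  mdl <- rep(NA_real_, length(cands))
  seg_ss <- numeric(m)
  for (s in seq_len(m)) {
    i <- seg_trace[s]
    idx <- which(seg_of_bin[[i]] == s & core_of_bin[[i]])
    if (!length(idx)) next
    seg_ss[s] <- sum((ys[[i]][idx] - seg_mean[s])^2)
  }
  for (K in Ks) {
    cand <- cands[[K]]
    ss <- sum(seg_ss) +
      sum(seg_len * (seg_mean - cand$means[cand$map])^2)
    trans <- sum(vapply(seq_along(ys), function(i) {
      a <- cand$map[which(seg_trace == i)]
      sum(diff(a) != 0)
    }, 0))
    mdl[K] <- .mdl_cost(ss, K, trans, N, sigma)
  }
  K_best <- Ks[which.min(mdl[Ks])]
  cand <- cands[[K_best]]
  map <- cand$map

  # refine the state positions on the observed (raw) segment means:
  # wavelet shrinkage pulls denoised levels toward the centre, which would
  # misplace the decision boundaries between states
  for (it in seq_len(50)) {
    st_mean <- vapply(sort(unique(map)), function(s) {
      w <- seg_len[map == s]
      sum(seg_raw_mean[map == s] * w) / sum(w)
    }, 0)
    new_map <- apply(abs(outer(seg_raw_mean, st_mean, `-`)), 1, which.min)
    new_map <- sort(unique(map))[new_map]
    if (identical(new_map, map)) break
    map <- new_map
  }

  # enforce minimum state separation: states closer than the per-bin noise
  # are not resolvable as distinct levels, so the effective floor is
  # max(min_separation, sigma)
  sep_thr <- max(min_separation, sigma)
  repeat {
    st <- sort(unique(map))
    means <- vapply(st, function(s)
      sum(seg_raw_mean[map == s] * seg_len[map == s]) / sum(seg_len[map == s]), 0)
    o <- order(means)
    if (length(means) <= 1 || all(diff(means[o]) >= sep_thr)) break
    j <- which.min(diff(means[o]))
    map[map == st[o][j + 1]] <- st[o][j]
  }
  st <- sort(unique(map))
  map <- match(map, st)
  K <- length(st)

  # state efficiencies and widths are reported from the raw (observed)
  # bins of each state: wavelet soft-thresholding shrinks step amplitudes,
  # which would bias the extreme states toward the centre
  assignments <- lapply(seq_along(ys), function(i) map[seg_of_bin[[i]]])
  raw_by_state <- lapply(seq_len(K), function(s)
    unlist(lapply(seq_along(raws), function(i)
      raws[[i]][assignments[[i]] == s & core_of_bin[[i]]]), use.names = FALSE))
  st_mean <- vapply(raw_by_state, mean, 0)
  halfw <- vapply(raw_by_state, function(v)
    if (length(v) > 1) 2 * sqrt(2 * log(2)) * sd(v) else 0, 0)

  sm <- state_model(st_mean, halfw, assignments, method = "stasi")
  attr(sm, "mdl") <- mdl
  attr(sm, "sigma") <- sigma
  sm
}

#' Gaussian hidden Markov model fit with state-count selection
#'
#' Fits Gaussian-emission HMMs with `K = 1 .. n_states_max` states to the
#' raw (not denoised) efficiency series of all molecules jointly, by
#' expectation-maximization with multiple deterministic restarts, and picks
#' K by the Bayesian information criterion.  Assignments are the Viterbi
#' most-probable path per molecule.  Works on observed data so it serves as
#' an independent cross-check of the segmentation-based fit.
#'
#' @param traces list of `efficiency_trace` objects or numeric vectors.
#' @param n_states_max largest K tried (default 6).
#' @param n_restarts EM restarts per K (default 10).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed seed for the deterministic restarts (default 1).
#' @return a [state_model()] with attribute `"bic"` (per candidate K) and
#'   `"loglik"`; `converged` is `FALSE` when no restart converged for the
#'   selected K (the best model is still returned, with a warning).
#' @export
hmm_fit <- function(traces, n_states_max = 6, n_restarts = 10,
                    max_iter = 200, tol = 1e-6, seed = 1) {
  seqs <- .as_eff_list(traces, FALSE)
  N <- sum(lengths(seqs))
  if (length(seqs) < 1 || N < 20)
    stop("hmm_fit needs at least one trace and 20 bins in total")
  all_v <- unlist(seqs, use.names = FALSE)
  sd_all <- max(sd(all_v), 1e-4)

  runif(1)  # ensure RNG state exists
  old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old_seed, envir = globalenv()))

  bic <- rep(NA_real_, n_states_max)
  fits <- vector("list", n_states_max)
  for (K in seq_len(n_states_max)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(as.integer(seed) + 1000L * K + r)
      mu0 <- as.numeric(quantile(all_v, probs = (seq_len(K) - 0.5) / K))
      if (r > 1) mu0 <- mu0 + rnorm(K, 0, 0.25 * sd_all)
      sd0 <- rep(sd_all / sqrt(K), K)
      A0 <- matrix(if (K > 1) 0.1 / (K - 1) else 0, K, K)
      diag(A0) <- if (K > 1) 0.9 else 1
      pi0 <- rep(1 / K, K)
      fit <- hmm_em(seqs, mu0, sd0, A0, pi0,
                    as.integer(max_iter), tol)
      if (is.null(best) || fit$loglik > best$loglik ||
          (fit$converged && !best$converged &&
           fit$loglik > best$loglik - 1e-6)) best <- fit
    }
    p <- (K - 1) + K * (K - 1) + 2 * K
    bic[K] <- -2 * best$loglik + p * log(N)
    fits[[K]] <- best
  }
  K_best <- which.min(bic)
  fit <- fits[[K_best]]
  if (!fit$converged)
    warning("EM did not converge for K = ", K_best,
            " within ", max_iter, " iterations; best model returned")

  assignments <- lapply(seqs, function(x)
    hmm_viterbi(x, fit$mu, fit$sd, fit$A, fit$pi) + 1L)
  halfw <- 2 * sqrt(2 * log(2)) * fit$sd
  sm <- state_model(fit$mu, halfw, assignments, method = "hmm",
                    converged = fit$converged)
  attr(sm, "bic") <- bic
  attr(sm, "loglik") <- fit$loglik
  sm
}

#' Fit a fixed-count Gaussian mixture to an efficiency histogram
#'
#' Least-squares fit of `sum_k w_k Normal(mu_k, sd_k)` to the histogram
#' density, initialized at the state-model efficiencies, as used to report
#' per-state peak position, full width at half maximum, and area.
#'
#' @param histogram data frame from [efficiency_histogram()] (columns `mid`
#'   and `density`).
#' @param state_model a [state_model()], or a numeric vector of initial
#'   means.
#' @param sd_init initial component standard deviation (default from the
#'   model half-widths, else 0.04).
#' @return data frame with `peak_E`, `fwhm`, `area` (one row per
#'   component), areas summing to ~1 for a normalized histogram; residual
#'   sum of squares as attribute `"rss"`.
#' @export
fit_gaussians <- function(histogram, state_model, sd_init = NULL) {
  mu0 <- if (inherits(state_model, "state_model"))
    state_model$state_efficiencies else as.numeric(state_model)
  K <- length(mu0)
  if (is.null(sd_init)) {
    sd_init <- if (inherits(state_model, "state_model"))
      pmax(state_model$state_halfwidths / (2 * sqrt(2 * log(2))), 0.01)
    else rep(0.04, K)
  }
  sd_init <- rep_len(sd_init, K)
  w0 <- if (inherits(state_model, "state_model"))
    pmax(state_model$occupancies, 1e-3) else rep(1 / K, K)
  x <- histogram$mid; y <- histogram$density
  obj <- function(par) {
    mu <- par[seq_len(K)]
    s <- exp(par[K + seq_len(K)])
    w <- exp(par[2 * K + seq_len(K)])
    yhat <- rowSums(vapply(seq_len(K),
                           function(k) w[k] * dnorm(x, mu[k], s[k]),
                           numeric(length(x))))
    sum((y - yhat)^2)
  }
  par0 <- c(mu0, log(sd_init), log(w0))
  fit <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("Gaussian mixture fit did not converge (code ", fit$convergence,
         "); residual sum of squares = ", signif(fit$value, 4))
  mu <- fit$par[seq_len(K)]
  s <- exp(fit$par[K + seq_len(K)])
  w <- exp(fit$par[2 * K + seq_len(K)])
  o <- order(mu, decreasing = TRUE)
  out <- data.frame(peak_E = mu[o], fwhm = 2 * sqrt(2 * log(2)) * s[o],
                    area = w[o])
  attr(out, "rss") <- fit$value
  out
}
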