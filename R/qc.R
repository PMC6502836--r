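# Change-point segmentation by recursive binary splitting with a Welch
# t-statistic.  Shared by bleach-step detection (QC) and state segmentation.
# Returns 0-based change-point indices: a change point at c means the new
# level starts at bin c+1.

.best_split <- function(x, min_segment) {
  n <- length(x)
  if (n < 2 * min_segment) return(NULL)
  idx <- min_segment:(n - min_segment)
  cs <- cumsum(x); cs2 <- cumsum(x * x)
  n1 <- idx; n2 <- n - idx
  m1 <- cs[idx] / n1
  m2 <- (cs[n] - cs[idx]) / n2
  ss1 <- pmax(cs2[idx] - n1 * m1^2, 0)
  ss2 <- pmax(cs2[n] - cs2[idx] - n2 * m2^2, 0)
  v1 <- ss1 / pmax(n1 - 1, 1)
  v2 <- ss2 / pmax(n2 - 1, 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  tt <- abs(m1 - m2) / se
  tt[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 0, Inf)
  k <- which.max(tt)
  list(at = idx[k], t = tt[k], drop = m1[k] - m2[k])
}

.segment_series <- function(x, t_threshold, min_segment) {
  cps <- integer(0)
  recurse <- function(lo, hi) {
    sp <- .best_split(x[lo:hi], min_segment)
    if (is.null(sp) || is.na(sp$t)) return(invisible())
    if (sp$t >= t_threshold) {
      cp <- lo - 1L + sp$at
      cps <<- c(cps, cp)
      recurse(lo, cp)
      recurse(cp + 1L, hi)
    }
    invisible()
  }
  recurse(1L, length(x))
  .prune_changepoints(x, sort(cps), t_threshold)
}

# backward elimination: greedy binary splitting can leave boundaries that
# are no longer significant once their final neighbours are known; drop
# the weakest until every remaining boundary separates genuinely
# different levels
.prune_changepoints <- function(x, cps, t_threshold) {
  adjacent_t <- function(lo, cp, hi) {
    a <- x[(lo + 1):cp]; b <- x[(cp + 1):hi]
    m1 <- mean(a); m2 <- mean(b)
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (!is.finite(se) || se == 0) {
      if (m1 == m2) 0 else Inf
    } else abs(m1 - m2) / se
  }
  while (length(cps)) {
    bounds <- c(0L, cps, length(x))
    tt <- vapply(seq_along(cps), function(i)
      adjacent_t(bounds[i], bounds[i + 1], bounds[i + 2]), 0)
    if (min(tt) >= t_threshold) break
    cps <- cps[-which.min(tt)]
  }
  cps
}

#' Detect photobleaching steps in a single-channel intensity series
#'
#' Locates downward change points by recursive binary segmentation with a
#' Welch t-statistic and reports those whose level drop is significant.
#' Single-fluorophore photobleaching appears as one such step; molecules
#' carrying several copies of a fluorophore show several.
#'
#' @param channel counts per bin.
#' @param bin_width bin width, ms.
#' @param t_threshold minimum |t| for a change point (default 5).
#' @param min_segment minimum segment length, bins (default 10).
#' @return list with `step_count`, `step_times` (ms, bin-start time of the
#'   first bin after each drop) and `change_points` (all change points, any
#'   direction, 0-based bin index).
#' @export
detect_bleach_steps <- function(channel, bin_width = 1, t_threshold = 5,
                                min_segment = 10) {
  if (length(channel) < 20)
    stop("channel must have at least 20 bins")
  cps <- .segment_series(channel, t_threshold, min_segment)
  bounds <- c(0L, cps, length(channel))
  means <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(channel[(bounds[i] + 1):bounds[i + 1]]), 0)
  drops <- which(diff(means) < 0)
  step_times <- cps[drops] * bin_width
  list(step_count = length(drops), step_times = step_times,
       change_points = cps)
}

#' Donor-acceptor anticorrelation over a trace region
#'
#' Pearson correlation of donor versus acceptor counts within the FRETing
#' region.  Genuine FRET dynamics move the two channels in opposite
#' directions, so accepted molecules show strongly negative values; a
#' zero-variance channel yields `NA` with a flag.
#'
#' @param trace a [photon_trace()].
#' @param region integer bin range `c(first, last)` (1-based, inclusive);
#'   default the whole trace.
#' @param bin_ms optionally sum counts into bins of this width (ms) before
#'   correlating, which suppresses shot noise relative to the
#'   conformational signal; `NULL` (default) correlates at native
#'   resolution.
#' @return Pearson coefficient (`NA` if undefined, with attribute
#'   `"zero_variance" = TRUE`).
#' @export
check_anticorrelation <- function(trace, region = NULL, bin_ms = NULL) {
  if (is.null(region)) region <- c(1L, length(trace$donor))
  if (region[2] - region[1] + 1 < 50)
    stop("anticorrelation region must span at least 50 bins")
  d <- trace$donor[region[1]:region[2]]
  a <- trace$acceptor[region[1]:region[2]]
  if (!is.null(bin_ms) && bin_ms > trace$bin_width) {
    m <- as.integer(round(bin_ms / trace$bin_width))
    n_out <- length(d) %/% m
    if (n_out >= 2) {
      d <- colSums(matrix(d[seq_len(n_out * m)], nrow = m))
      a <- colSums(matrix(a[seq_len(n_out * m)], nrow = m))
    }
  }
  if (sd(d) == 0 || sd(a) == 0) {
    r <- NA_real_
    attr(r, "zero_variance") <- TRUE
    return(r)
  }
  cor(d, a)
}

#' Select analyzable smFRET molecules
#'
#' A molecule is accepted when both channels show exactly one photobleaching
#' step (one donor, one acceptor — so the trace reports a single
#' donor-acceptor distance) and the channels are anticorrelated over the
#' FRETing region.  The FRETing region runs from the trace start to the
#' earliest bleach event in either channel; the donor-only tail is used only
#' for step counting.
#'
#' @param trace a [photon_trace()].
#' @param t_threshold,min_segment step-detection settings, see
#'   [detect_bleach_steps()].
#' @param anticorrelation_max acceptance threshold on the Pearson
#'   coefficient (accept when r <= this value; default -0.3).
#' @param anticorr_bin_ms bin width (ms) at which the channels are
#'   correlated (default 5, the analysis bin width).
#' @param min_region_bins minimum FRETing-region length in bins (default 50).
#' @return object of class `qc_report`: step counts and times per channel,
#'   anticorrelation, `fret_region` as half-open `[start_ms, end_ms)`,
#'   `accepted`, and `reject_reason` (`"accepted"` when accepted).
#' @export
select_molecule <- function(trace, t_threshold = 5, min_segment = 10,
                            anticorrelation_max = -0.3,
                            anticorr_bin_ms = 5,
                            min_region_bins = 50) {
  stopifnot(inherits(trace, "photon_trace"))
  bw <- trace$bin_width
  # Conformational transitions shuttle intensity between the two
  # donor-excitation channels but conserve their sum, so donor bleaches are
  # the only downward steps of the summed signal.  Acceptor bleaches are
  # counted on the direct-excitation channel (free of FRET dynamics) when
  # it was recorded, else on the acceptor channel itself.
  ds <- detect_bleach_steps(trace$donor + trace$acceptor, bw,
                            t_threshold, min_segment)
  as <- detect_bleach_steps(if (is.null(trace$acceptor_direct))
    trace$acceptor else trace$acceptor_direct, bw, t_threshold, min_segment)
  all_steps <- c(ds$step_times, as$step_times)
  end_ms <- if (length(all_steps)) min(all_steps) else length(trace$donor) * bw
  region_bins <- c(1L, max(1L, floor(end_ms / bw)))
  anticorr <- NA_real_
  reason <- "accepted"
  if (ds$step_count == 0) reason <- "no_donor_step"
  else if (ds$step_count > 1) reason <- "multiple_donor_steps"
  else if (as$step_count == 0) reason <- "no_acceptor_step"
  else if (as$step_count > 1) reason <- "multiple_acceptor_steps"
  else if (region_bins[2] - region_bins[1] + 1 < min_region_bins)
    reason <- "short_fret_region"
  else {
    # correlate up to the donor bleach: an acceptor bleach inside that
    # window (acceptor falls, donor rises) is itself the strongest
    # anticorrelation evidence of a genuine FRET pair
    ac_end <- max(1L, floor(ds$step_times[1] / bw))
    anticorr <- check_anticorrelation(trace, c(1L, ac_end),
                                      bin_ms = anticorr_bin_ms)
    if (is.na(anticorr)) reason <- "zero_variance_channel"
    else if (anticorr > anticorrelation_max) reason <- "weak_anticorrelation"
  }
  structure(list(
    molecule_id = trace$molecule_id,
    donor_steps = ds$step_count, acceptor_steps = as$step_count,
    donor_step_times = ds$step_times, acceptor_step_times = as$step_times,
    anticorrelation = as.numeric(anticorr),
    fret_region = c(start_ms = 0, end_ms = end_ms),
    accepted = identical(reason, "accepted"),
    reject_reason = reason), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: D steps %d, A steps %d, r = %s, region [0, %g) ms -> %s\n",
              x$molecule_id, x$donor_steps, x$acceptor_steps,
              ifelse(is.na(x$anticorrelation), "NA",
                     sprintf("%.2f", x$anticorrelation)),
              x$fret_region[["end_ms"]],
              if (x$accepted) "accepted" else x$reject_reason))
  invisible(x)
}

#' QC a list of traces into a report table
#'
#' @param traces list of [photon_trace()] objects.
#' @param ... passed to [select_molecule()].
#' @return data frame with one row per molecule (all `qc_report` scalar
#'   fields); the full reports as attribute `"reports"`.
#' @export
qc_table <- function(traces, ...) {
  reports <- lapply(traces, select_molecule, ...)
  df <- data.frame(
    molecule_id = vapply(reports, `[[`, "", "molecule_id"),
    donor_steps = vapply(reports, `[[`, 0L, "donor_steps"),
    acceptor_steps = vapply(reports, `[[`, 0L, "acceptor_steps"),
    anticorrelation = vapply(reports, `[[`, 0, "anticorrelation"),
    fret_start_ms = vapply(reports, function(r) r$fret_region[["start_ms"]], 0),
    fret_end_ms = vapply(reports, function(r) r$fret_region[["end_ms"]], 0),
    accepted = vapply(reports, `[[`, TRUE, "accepted"),
    reject_reason = vapply(reports, `[[`, "", "reject_reason"))
  attr(df, "reports") <- reports
  df
}
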