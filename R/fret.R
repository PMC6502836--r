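#' Re-bin a photon trace to a coarser bin width
#'
#' Counts are summed over non-overlapping windows; a trailing partial window
#' is dropped.  Acquisition is at 1 ms; analysis uses 5 ms bins.
#'
#' @param trace a [photon_trace()].
#' @param target_bin new bin width, ms; must be an integer multiple of the
#'   trace bin width.
#' @return a [photon_trace()] at the new bin width.
#' @export
bin_trace <- function(trace, target_bin = 5) {
  stopifnot(inherits(trace, "photon_trace"))
  ratio <- target_bin / trace$bin_width
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("target_bin must be an integer multiple of the trace bin width")
  m <- as.integer(round(ratio))
  n_out <- length(trace$donor) %/% m
  if (n_out < 1) stop("trace shorter than one target bin")
  rebin <- function(x) {
    if (is.null(x)) return(NULL)
    as.integer(colSums(matrix(x[seq_len(n_out * m)], nrow = m)))
  }
  photon_trace(molecule_id = trace$molecule_id,
               bin_width = target_bin,
               donor = rebin(trace$donor),
               acceptor = rebin(trace$acceptor),
               acceptor_direct = rebin(trace$acceptor_direct),
               provenance = paste0(trace$provenance, "; binned to ",
                                   target_bin, " ms"))
}

#' Per-bin FRET efficiency (proximity ratio)
#'
#' `E = (IA - bgA) / ((ID - bgD) + (IA - bgA))` from background-subtracted
#' intensities.  Bins whose total corrected intensity is not positive are
#' invalid (`NA`); values are returned unclamped (use [clamp_efficiency()]
#' for plotting ranges).
#'
#' @param donor,acceptor counts per bin.
#' @param background_d,background_a mean background per bin and channel.
#' @return numeric vector of efficiencies, invalid bins `NA`, with attribute
#'   `"n_invalid"`.
#' @export
compute_efficiency <- function(donor, acceptor, background_d = 0,
                               background_a = 0) {
  stopifnot(length(donor) == length(acceptor))
  id <- donor - background_d
  ia <- acceptor - background_a
  denom <- id + ia
  e <- ifelse(denom > 0, ia / denom, NA_real_)
  if (all(is.na(e))) stop("all bins invalid: corrected total intensity <= 0")
  attr(e, "n_invalid") <- sum(is.na(e))
  e
}

#' Clamp efficiencies to a display range
#'
#' @param e efficiencies.
#' @param lo,hi clamp bounds (default -0.1 and 1.1).
#' @return clamped vector.
#' @export
clamp_efficiency <- function(e, lo = -0.1, hi = 1.1) pmin(pmax(e, lo), hi)

# one level of the Haar analysis / synthesis pair
.haar_down <- function(x) {
  odd <- x[c(TRUE, FALSE)]; even <- x[c(FALSE, TRUE)]
  list(a = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2))
}
.haar_up <- function(a, d) {
  n <- length(a)
  out <- numeric(2 * n)
  out[c(TRUE, FALSE)] <- (a + d) / sqrt(2)
  out[c(FALSE, TRUE)] <- (a - d) / sqrt(2)
  out
}

# single-shift Haar wavelet shrinkage
.denoise_once <- function(x, pad, depth, mode) {
  n <- length(x)
  block <- 2^depth
  N <- block * ceiling(n / block)
  if (N > n) {
    p <- N - n
    tail_pad <- switch(pad,
      symmetric = x[n - seq_len(p) + 1],
      periodic = x[seq_len(p)])
    xx <- c(x, tail_pad)
  } else xx <- x
  a <- xx
  details <- vector("list", depth)
  for (j in seq_len(depth)) {
    h <- .haar_down(a)
    a <- h$a
    details[[j]] <- h$d
  }
  thr <- mad(details[[1]]) * sqrt(2 * log(N))
  details <- lapply(details, function(d)
    if (mode == "soft") sign(d) * pmax(abs(d) - thr, 0) else d * (abs(d) > thr))
  for (j in rev(seq_len(depth))) a <- .haar_up(a, details[[j]])
  a[seq_len(n)]
}

#' Wavelet denoising of an efficiency series
#'
#' Translation-invariant Haar wavelet shrinkage: the series is decomposed
#' to depth `min(4, floor(log2 n) - 1)`, detail coefficients are
#' thresholded at the universal level `sigma * sqrt(2 log N)` (`sigma` from
#' the median absolute deviation of the finest details), the transform is
#' inverted, and the result is averaged over circularly shifted copies
#' (cycle spinning) to suppress the block-boundary artifacts of the
#' decimated transform.  The Haar family preserves the step-like
#' transitions between conformational states; hard thresholding (default)
#' keeps step amplitudes unbiased, soft thresholding is available for a
#' smoother output.
#'
#' @param x numeric series (>= 8 bins, no `NA`).
#' @param pad `"symmetric"` (default) or `"periodic"` extension to a
#'   multiple of the block size.
#' @param depth decomposition depth; default `min(4, floor(log2 n) - 1)`.
#' @param mode `"hard"` (default) or `"soft"` thresholding.
#' @param shifts number of circular shifts averaged (default 16; 1 disables
#'   cycle spinning).
#' @return denoised series, same length as the input.
#' @export
denoise <- function(x, pad = c("symmetric", "periodic"), depth = NULL,
                    mode = c("hard", "soft"), shifts = 16) {
  pad <- match.arg(pad)
  mode <- match.arg(mode)
  n <- length(x)
  if (n < 8) stop("denoise requires at least 8 bins")
  if (any(!is.finite(x))) stop("denoise input must be finite (no NA bins)")
  if (is.null(depth)) depth <- min(4, floor(log2(n)) - 1)
  depth <- max(1L, as.integer(depth))
  shifts <- max(1L, min(as.integer(shifts), n))
  if (shifts == 1) return(.denoise_once(x, pad, depth, mode))
  acc <- numeric(n)
  for (s in seq_len(shifts) - 1L) {
    xs <- if (s == 0) x else c(x[(s + 1):n], x[seq_len(s)])
    ds <- .denoise_once(xs, pad, depth, mode)
    acc <- acc + if (s == 0) ds else c(ds[(n - s + 1):n], ds[seq_len(n - s)])
  }
  acc / shifts
}

#' Build a binned, denoised efficiency trace from an accepted photon trace
#'
#' Restricts to the FRETing region, re-bins to the analysis bin width,
#' computes the per-bin proximity ratio and its wavelet-denoised version.
#' Invalid bins (non-positive corrected intensity) are bridged by linear
#' interpolation before denoising and stay flagged.
#'
#' @param trace a [photon_trace()] at native resolution.
#' @param region FRETing region `c(start_ms, end_ms)` (half-open, ms);
#'   default the whole trace.
#' @param bin_ms analysis bin width, ms (default 5).
#' @param background_d,background_a mean background per native bin.
#' @param pad padding mode for [denoise()].
#' @return object of class `efficiency_trace` with fields `molecule_id`,
#'   `bin_width`, `raw`, `denoised`, `valid`, `region`.
#' @export
efficiency_trace <- function(trace, region = NULL, bin_ms = 5,
                             background_d = 0, background_a = 0,
                             pad = "symmetric") {
  stopifnot(inherits(trace, "photon_trace"))
  bw <- trace$bin_width
  if (is.null(region)) region <- c(0, length(trace$donor) * bw)
  i0 <- floor(region[1] / bw) + 1L
  i1 <- min(length(trace$donor), ceiling(region[2] / bw))
  sub <- photon_trace(trace$molecule_id, bw,
                      trace$donor[i0:i1], trace$acceptor[i0:i1],
                      provenance = trace$provenance)
  binned <- bin_trace(sub, bin_ms)
  m <- bin_ms / bw
  raw <- compute_efficiency(binned$donor, binned$acceptor,
                            background_d * m, background_a * m)
  valid <- !is.na(raw)
  filled <- as.numeric(raw)
  if (any(!valid)) {
    ok <- which(valid)
    filled[!valid] <- stats::approx(ok, filled[ok], xout = which(!valid),
                                    rule = 2)$y
  }
  den <- if (length(filled) >= 8) denoise(filled, pad = pad) else filled
  structure(list(molecule_id = trace$molecule_id, bin_width = bin_ms,
                 raw = filled, denoised = den, valid = valid,
                 region = region), class = "efficiency_trace")
}

#' @export
print.efficiency_trace <- function(x, ...) {
  cat(sprintf("<efficiency_trace> %s: %d x %g ms bins, mean E = %.3f\n",
              x$molecule_id, length(x$raw), x$bin_width, mean(x$raw)))
  invisible(x)
}

#' Pooled FRET-efficiency histogram
#'
#' Each count is one analysis bin; counts from all molecules are pooled and
#' normalized to fractional occurrence, matching how experimental efficiency
#' histograms are assembled.
#'
#' @param traces list of `efficiency_trace` objects (or numeric vectors).
#' @param breaks histogram break points (default 0.01-wide bins on
#'   `[0, 1.05]`).
#' @param use_denoised histogram the denoised (default) or raw series.
#' @return data frame with `mid`, `count`, `fraction`, `density`.
#' @export
efficiency_histogram <- function(traces, breaks = seq(0, 1.05, by = 0.01),
                                 use_denoised = TRUE) {
  vals <- unlist(lapply(traces, function(tr) {
    if (is.numeric(tr)) tr
    else if (use_denoised) tr$denoised else tr$raw
  }), use.names = FALSE)
  vals <- clamp_efficiency(vals, min(breaks), max(breaks) - 1e-9)
  h <- hist(vals, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts,
             fraction = h$counts / sum(h$counts),
             density = h$density)
}

# noise sd of raw efficiency series from the MAD of finest Haar details
#' Estimate per-bin noise from finest-scale wavelet details
#'
#' @param traces list of numeric series or `efficiency_trace` objects (raw
#'   series are used).
#' @return noise standard deviation estimate.
#' @export
estimate_noise_sd <- function(traces) {
  if (!is.list(traces)) traces <- list(traces)
  d <- unlist(lapply(traces, function(tr) {
    x <- if (is.numeric(tr)) tr else tr$raw
    n <- 2 * (length(x) %/% 2)
    if (n < 2) return(numeric(0))
    .haar_down(x[seq_len(n)])$d
  }), use.names = FALSE)
  if (!length(d)) return(0)
  mad(d)
}
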