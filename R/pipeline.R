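#' Pipeline run configuration
#'
#' Collects every tunable of the simulate -> QC -> efficiency -> states ->
#' landscape workflow with the package defaults: 5 ms analysis bins, |t| >=
#' 5 change-point thresholds, r <= -0.3 anticorrelation acceptance, R0 = 51
#' angstrom, Arrhenius pre-exponential 10 ms^-1.
#'
#' @param input trace source: a directory/file for [read_traces()] or an
#'   in-memory list of [photon_trace()] objects.
#' @param output_dir optional directory for result tables and provenance.
#' @param condition condition label (e.g. `"glutamate_Na"`).
#' @param bin_ms analysis bin width, ms.
#' @param background_d,background_a mean background per native bin.
#' @param histogram_breaks efficiency histogram breaks.
#' @param t_threshold_qc,min_segment_qc,anticorrelation_max,min_region_bins
#'   QC settings, see [select_molecule()].
#' @param t_threshold_states,min_segment_states,min_separation,max_states
#'   state-identification settings, see [stasi_fit()].
#' @param hmm fit the HMM cross-check as well (default `TRUE`).
#' @param hmm_restarts EM restarts per candidate K.
#' @param R0 Forster radius, angstrom.
#' @param A Arrhenius pre-exponential, ms^-1.
#' @param rate_method rate convention, see [activation_energies()].
#' @param seed integer seed recorded in provenance and used for the HMM
#'   restarts.
#' @return object of class `run_config`.
#' @export
run_config <- function(input, output_dir = NULL, condition = NA_character_,
                       bin_ms = 5, background_d = 2, background_a = 2,
                       histogram_breaks = seq(0, 1.05, by = 0.01),
                       t_threshold_qc = 5, min_segment_qc = 10,
                       anticorrelation_max = -0.3, min_region_bins = 50,
                       t_threshold_states = 5, min_segment_states = 3,
                       min_separation = 0.03, max_states = 6,
                       hmm = TRUE, hmm_restarts = 10,
                       R0 = 51, A = 10, rate_method = "linear", seed = 1) {
  stopifnot(bin_ms > 0, R0 > 0, A > 0, max_states >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full smFRET landscape pipeline
#'
#' Reads (or takes) photon traces, applies photobleach-step and
#' anticorrelation QC, restricts accepted molecules to their FRETing
#' regions, bins to the analysis resolution, computes raw and denoised
#' efficiencies, identifies states by the segmentation/MDL fit (with an HMM
#' cross-check), and derives the distance table, transition map and energy
#' landscape.  With `output_dir` set, all tables plus a machine-readable
#' provenance record are written; identical inputs and config give
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return object of class `fret_bundle`: QC table, efficiency traces,
#'   histogram, `stasi` and (optionally) `hmm` state models, Gaussian
#'   histogram fit, `landscape`, `distances`, molecule counts and the
#'   config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  traces <- if (is.list(config$input) &&
                all(vapply(config$input, inherits, TRUE, "photon_trace")))
    config$input else read_traces(config$input)

  qc <- qc_table(traces,
                 t_threshold = config$t_threshold_qc,
                 min_segment = config$min_segment_qc,
                 anticorrelation_max = config$anticorrelation_max,
                 min_region_bins = config$min_region_bins)
  keep <- which(qc$accepted)
  if (length(keep) == 0)
    stop("no molecules passed QC (", nrow(qc), " input traces)")

  eff <- lapply(keep, function(i) {
    r <- attr(qc, "reports")[[i]]
    tryCatch(
      efficiency_trace(traces[[i]], region = r$fret_region,
                       bin_ms = config$bin_ms,
                       background_d = config$background_d,
                       background_a = config$background_a),
      error = function(e) stop("efficiency stage failed for molecule ",
                               traces[[i]]$molecule_id, ": ",
                               conditionMessage(e)))
  })
  eff <- eff[lengths(lapply(eff, `[[`, "raw")) >= 8]
  if (length(eff) == 0) stop("no molecules passed QC with usable regions")

  stasi <- stasi_fit(eff, use_denoised = TRUE,
                     t_threshold = config$t_threshold_states,
                     min_segment = config$min_segment_states,
                     min_separation = config$min_separation,
                     max_states = config$max_states)
  hmm <- if (isTRUE(config$hmm))
    hmm_fit(eff, n_states_max = config$max_states,
            n_restarts = config$hmm_restarts, seed = config$seed)
  else NULL

  histo <- efficiency_histogram(eff, breaks = config$histogram_breaks)
  gauss <- tryCatch(fit_gaussians(histo, stasi),
                    error = function(e) { warning(conditionMessage(e)); NULL })
  land <- energy_landscape(stasi, bin_width = config$bin_ms,
                           A = config$A, R0 = config$R0,
                           rate_method = config$rate_method)

  bundle <- structure(list(
    condition = config$condition,
    n_input = length(traces), n_accepted = length(eff),
    qc = qc, efficiency_traces = eff, histogram = histo,
    stasi = stasi, hmm = hmm, gaussians = gauss,
    landscape = land, distances = land$distances,
    config = config), class = "fret_bundle")

  if (!is.null(config$output_dir)) .write_bundle(bundle, config$output_dir)
  bundle
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results(bundle$stasi, bundle$landscape, dir,
                histogram = bundle$histogram)
  .write_tsv(bundle$qc, file.path(dir, "qc_table.tsv"))
  for (tr in bundle$efficiency_traces) {
    df <- data.frame(time_ms = (seq_along(tr$raw) - 1) * tr$bin_width,
                     E_raw = tr$raw, E_denoised = tr$denoised)
    .write_tsv(df, file.path(dir, paste0("efficiency_", tr$molecule_id,
                                         ".tsv")))
  }
  cfg <- bundle$config
  cfg$input <- if (is.character(cfg$input)) cfg$input else "<in-memory traces>"
  cfg <- cfg[order(names(cfg))]
  prov <- list(package = "fretscape",
               version = as.character(packageVersion("fretscape")),
               condition = bundle$condition,
               n_input = bundle$n_input,
               n_accepted = bundle$n_accepted,
               n_states_stasi = bundle$stasi$n_states,
               n_states_hmm = if (is.null(bundle$hmm)) NA_integer_
                              else bundle$hmm$n_states,
               config = cfg)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.fret_bundle <- function(x, ...) {
  cat(sprintf("<fret_bundle> condition %s: %d/%d molecules accepted\n",
              x$condition, x$n_accepted, x$n_input))
  print(x$stasi)
  if (!is.null(x$hmm))
    cat(sprintf("HMM cross-check: %d state(s) at %s\n", x$hmm$n_states,
                paste(round(x$hmm$state_efficiencies, 3), collapse = ", ")))
  invisible(x)
}

#' Compare two analyzed conditions
#'
#' Matches states between two result bundles by nearest efficiency and
#' reports per-state efficiency and occupancy differences — descriptive
#' only, no hypothesis testing.  Unmatched states (when the counts differ)
#' are listed separately.
#'
#' @param bundle_a,bundle_b `fret_bundle` objects (or [state_model()]s).
#' @return list with `matched` (data frame: efficiencies, occupancies,
#'   `delta_E = E_b - E_a`, `delta_occupancy`) and `unmatched` (data frame
#'   naming the bundle and state).
#' @export
compare_conditions <- function(bundle_a, bundle_b) {
  ma <- if (inherits(bundle_a, "fret_bundle")) bundle_a$stasi else bundle_a
  mb <- if (inherits(bundle_b, "fret_bundle")) bundle_b$stasi else bundle_b
  stopifnot(inherits(ma, "state_model"), inherits(mb, "state_model"))
  Ea <- ma$state_efficiencies; Eb <- mb$state_efficiencies
  # greedy nearest-efficiency matching
  pairs <- expand.grid(a = seq_along(Ea), b = seq_along(Eb))
  pairs$d <- abs(Ea[pairs$a] - Eb[pairs$b])
  pairs <- pairs[order(pairs$d), ]
  used_a <- logical(length(Ea)); used_b <- logical(length(Eb))
  sel <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    if (!used_a[p$a] && !used_b[p$b]) {
      sel <- c(sel, i)
      used_a[p$a] <- TRUE; used_b[p$b] <- TRUE
    }
  }
  mt <- pairs[sel, ]
  mt <- mt[order(mt$a), ]
  matched <- data.frame(
    state_a = mt$a, state_b = mt$b,
    E_a = Ea[mt$a], E_b = Eb[mt$b],
    occupancy_a = ma$occupancies[mt$a], occupancy_b = mb$occupancies[mt$b])
  matched$delta_E <- matched$E_b - matched$E_a
  matched$delta_occupancy <- matched$occupancy_b - matched$occupancy_a
  unmatched <- rbind(
    if (any(!used_a)) data.frame(bundle = "a", state = which(!used_a),
                                 efficiency = Ea[!used_a]),
    if (any(!used_b)) data.frame(bundle = "b", state = which(!used_b),
                                 efficiency = Eb[!used_b]))
  list(matched = matched,
       unmatched = if (is.null(unmatched))
         data.frame(bundle = character(0), state = integer(0),
                    efficiency = numeric(0)) else unmatched)
}
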