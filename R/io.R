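#' Two-channel photon trace for one molecule
#'
#' Container for binned photon counts of a single immobilized molecule:
#' donor and acceptor emission under donor excitation and, optionally, the
#' acceptor emission under direct acceptor excitation (used for label
#' verification only).  Time is bin-start, 0-based, in milliseconds.
#'
#' @param molecule_id unique identifier.
#' @param bin_width bin width, ms (> 0).
#' @param donor,acceptor non-negative integer counts per bin, equal length.
#' @param acceptor_direct optional counts per bin under direct acceptor
#'   excitation; `NULL` if not recorded.
#' @param provenance free-text metadata.
#' @return object of class `photon_trace`.
#' @export
photon_trace <- function(molecule_id, bin_width, donor, acceptor,
                         acceptor_direct = NULL, provenance = "") {
  if (!is.character(molecule_id) || length(molecule_id) != 1 ||
      !nzchar(molecule_id))
    stop("molecule_id must be a non-empty string")
  if (!is.numeric(bin_width) || length(bin_width) != 1 || !(bin_width > 0))
    stop("bin_width must be a single positive number")
  .check_counts <- function(x, name) {
    if (!is.numeric(x) || any(!is.finite(x)))
      stop(name, " counts must be finite numbers (molecule ", molecule_id, ")")
    if (any(x < 0))
      stop("negative ", name, " count in molecule ", molecule_id,
           " at row ", which(x < 0)[1])
    as.integer(round(x))
  }
  donor <- .check_counts(donor, "donor")
  acceptor <- .check_counts(acceptor, "acceptor")
  if (length(donor) != length(acceptor))
    stop("channel lengths differ for molecule ", molecule_id)
  if (!is.null(acceptor_direct)) {
    acceptor_direct <- .check_counts(acceptor_direct, "acceptor_direct")
    if (length(acceptor_direct) != length(donor))
      stop("channel lengths differ for molecule ", molecule_id)
  }
  structure(list(molecule_id = molecule_id, bin_width = bin_width,
                 donor = donor, acceptor = acceptor,
                 acceptor_direct = acceptor_direct,
                 provenance = provenance),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("<photon_trace> %s: %d bins x %g ms%s\n", x$molecule_id,
              length(x$donor), x$bin_width,
              if (is.null(x$acceptor_direct)) "" else " (+direct excitation)"))
  invisible(x)
}

#' @export
length.photon_trace <- function(x) length(x$donor)

.trace_filename <- function(molecule_id) paste0(molecule_id, ".tsv")

#' Write photon traces as per-molecule TSV files with a manifest
#'
#' One tab-separated file per molecule with columns `time_ms`, `donor`,
#' `acceptor` and, when present, `acceptor_direct`, plus a `manifest.tsv`
#' listing file, molecule id and condition label.
#'
#' @param traces list of [photon_trace()] objects.
#' @param dir output directory (created if needed).
#' @param condition condition label (recycled) stored in the manifest,
#'   e.g. `"apo_Na"` or `"glutamate_Cs"`.
#' @return invisible character vector of written trace files.
#' @export
write_traces <- function(traces, dir, condition = NA_character_) {
  if (inherits(traces, "photon_trace")) traces <- list(traces)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  condition <- rep_len(as.character(condition), length(traces))
  files <- character(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "photon_trace"))
    df <- data.frame(time_ms = (seq_along(tr$donor) - 1) * tr$bin_width,
                     donor = tr$donor, acceptor = tr$acceptor)
    if (!is.null(tr$acceptor_direct)) df$acceptor_direct <- tr$acceptor_direct
    files[i] <- .trace_filename(tr$molecule_id)
    .write_tsv(df, file.path(dir, files[i]))
  }
  manifest <- data.frame(file = files,
                         molecule_id = vapply(traces, `[[`, "", "molecule_id"),
                         condition = condition)
  .write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(files)
}

#' Read photon traces from TSV files
#'
#' `path` may be a directory (read via its `manifest.tsv`, or all `*.tsv`
#' files except the manifest if absent), a single trace file, or a vector of
#' trace files.  Files must have columns `time_ms`, `donor`, `acceptor` and
#' optionally `acceptor_direct`; the bin width is inferred from the time
#' column.  All invariants (equal channel lengths, non-negative counts,
#' unique molecule ids) are enforced.
#'
#' @param path directory, file, or files.
#' @return list of [photon_trace()] objects; conditions (from the manifest,
#'   if any) attached as attribute `"condition"`.
#' @export
read_traces <- function(path) {
  condition <- NULL
  if (length(path) == 1 && dir.exists(path)) {
    man_file <- file.path(path, "manifest.tsv")
    if (file.exists(man_file)) {
      man <- read.delim(man_file, stringsAsFactors = FALSE)
      files <- file.path(path, man$file)
      condition <- man$condition
    } else {
      files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
      files <- files[basename(files) != "manifest.tsv"]
    }
  } else {
    if (!all(file.exists(path))) stop("no such file: ", path[!file.exists(path)][1])
    files <- path
  }
  if (length(files) == 0) stop("no trace files found under ", path[1])
  traces <- lapply(files, .read_one_trace)
  ids <- vapply(traces, `[[`, "", "molecule_id")
  if (anyDuplicated(ids))
    stop("duplicate molecule_id: ", ids[duplicated(ids)][1])
  if (!is.null(condition)) attr(traces, "condition") <- condition
  traces
}

.read_one_trace <- function(file) {
  df <- tryCatch(read.delim(file, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse trace file ", file,
                                          ": ", conditionMessage(e)))
  id <- sub("\\.tsv$", "", basename(file))
  need <- c("time_ms", "donor", "acceptor")
  if (!all(need %in% names(df)))
    stop("trace file ", file, " lacks columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in intersect(c("time_ms", "donor", "acceptor", "acceptor_direct"),
                        names(df))) {
    if (!is.numeric(df[[col]]) || any(is.na(df[[col]])))
      stop("malformed ", col, " in molecule ", id, " at row ",
           which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))[1])
  }
  if (nrow(df) < 2) stop("trace ", id, " has fewer than 2 bins")
  bw <- diff(df$time_ms[1:2])
  if (bw <= 0 || any(abs(diff(df$time_ms) - bw) > 1e-9))
    stop("non-uniform time axis in molecule ", id)
  photon_trace(molecule_id = id, bin_width = bw,
               donor = df$donor, acceptor = df$acceptor,
               acceptor_direct = df[["acceptor_direct"]],
               provenance = paste0("read from ", basename(file)))
}

# fixed-format TSV writer: %.15g keeps doubles to full working precision and
# makes reruns byte-identical
.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis result tables
#'
#' Writes the state table (efficiency, FWHM, occupancy, bin count,
#' distance), transition count and probability matrices, and the
#' free-energy/activation-barrier tables as deterministic TSV files.
#'
#' @param state_model a [state_model()] (or `NULL` for header-only tables).
#' @param landscape an [energy_landscape()] (or `NULL`).
#' @param dir output directory.
#' @param histogram optional efficiency histogram data frame.
#' @return invisible character vector of files written.
#' @export
write_results <- function(state_model, landscape, dir, histogram = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  st <- if (is.null(state_model) || state_model$n_states == 0) {
    data.frame(state = integer(0), efficiency = numeric(0),
               fwhm = numeric(0), occupancy = numeric(0),
               n_bins = integer(0))
  } else {
    data.frame(state = seq_len(state_model$n_states),
               efficiency = state_model$state_efficiencies,
               fwhm = state_model$state_halfwidths,
               occupancy = state_model$occupancies,
               n_bins = state_model$n_bins)
  }
  if (!is.null(landscape)) {
    st$distance_A <- if (nrow(st)) landscape$distances$distance_A else numeric(0)
    st$delta_G_kBT <- if (nrow(st)) landscape$delta_G else numeric(0)
  }
  f <- file.path(dir, "state_table.tsv"); .write_tsv(st, f); files <- c(files, f)
  if (!is.null(landscape)) {
    .write_matrix <- function(m, name) {
      df <- as.data.frame(m)
      names(df) <- paste0("to_", seq_len(ncol(m)))
      df <- cbind(from = seq_len(nrow(m)), df)
      fp <- file.path(dir, name)
      .write_tsv(df, fp)
      fp
    }
    files <- c(files,
               .write_matrix(landscape$transition_counts, "transition_counts.tsv"),
               .write_matrix(landscape$transition_probs, "transition_probs.tsv"),
               .write_matrix(landscape$Ea, "activation_energy.tsv"),
               .write_matrix(landscape$Ea_symmetrized,
                             "activation_energy_symmetrized.tsv"))
    fe <- data.frame(state = seq_along(landscape$delta_G),
                     occupancy = landscape$occupancies,
                     delta_G_kBT = landscape$delta_G)
    f <- file.path(dir, "free_energy.tsv"); .write_tsv(fe, f)
    files <- c(files, f)
  }
  if (!is.null(histogram)) {
    f <- file.path(dir, "histogram.tsv"); .write_tsv(histogram, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read result tables written by [write_results()]
#'
#' @param dir directory containing the TSV tables.
#' @return named list of data frames (only the files present).
#' @export
read_results <- function(dir) {
  out <- list()
  for (nm in c("state_table", "transition_counts", "transition_probs",
               "activation_energy", "activation_energy_symmetrized",
               "free_energy", "histogram")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(f)) out[[nm]] <- read.delim(f, stringsAsFactors = FALSE)
  }
  out
}
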