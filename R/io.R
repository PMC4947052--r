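# Readers and writers for the pipeline's artifacts.
#
# Times are serialized in seconds; electrode ids are 1..64 row-major
# over the 8x8 grid. Spike trains: two-column CSV (electrode_id,
# spike_time_s) or HDF5; stimulation log: CSV (stim_time_s, site_label);
# response patterns: HDF5 (stimulus x electrode x bin integer array) or
# a long-format CSV; signatures: CSV matrices with NA for
# not-applicable cells; reports, ground truth and configs: JSON (YAML
# also accepted for configs).

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop_param("HDF5 support requires the 'rhdf5' package")
}

#' Write / read a spike-train set
#'
#' @param spikes a [spike_train_set()].
#' @param path output file; `.h5` selects HDF5, anything else CSV.
#' @return `write_spike_trains`: the path, invisibly.
#' @export
write_spike_trains <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (grepl("\\.h5$", path)) {
    need_rhdf5()
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(spikes$spikes$electrode, path, "electrode_id")
    rhdf5::h5write(spikes$spikes$time_s, path, "spike_time_s")
    rhdf5::h5write(spikes$duration_s, path, "duration_s")
    rhdf5::h5write(c(spikes$geometry$n_rows, spikes$geometry$n_cols),
                   path, "grid_dims")
    rhdf5::h5closeAll()
  } else {
    write.csv(data.frame(electrode_id = spikes$spikes$electrode,
                         spike_time_s = spikes$spikes$time_s),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_spike_trains
#' @param geometry geometry for the returned set (CSV carries none;
#'   HDF5 stores the grid dimensions).
#' @param duration_s optional duration override.
#' @return `read_spike_trains`: a [spike_train_set()]. Out-of-order rows
#'   are sorted with a warning.
#' @export
read_spike_trains <- function(path, geometry = array_geometry(),
                              duration_s = NULL) {
  if (grepl("\\.h5$", path)) {
    need_rhdf5()
    el <- as.integer(rhdf5::h5read(path, "electrode_id"))
    tt <- as.numeric(rhdf5::h5read(path, "spike_time_s"))
    duration_s <- duration_s %||% as.numeric(rhdf5::h5read(path, "duration_s"))
    dims <- as.integer(rhdf5::h5read(path, "grid_dims"))
    rhdf5::h5closeAll()
    if (all(dims == c(geometry$n_rows, geometry$n_cols)) ||
        missing(geometry))
      geometry <- array_geometry(dims[1], dims[2])
  } else {
    df <- read.csv(path)
    req <- c("electrode_id", "spike_time_s")
    if (!all(req %in% names(df)))
      stop_param("spike-train file must have columns ",
                 paste(req, collapse = ", "))
    el <- as.integer(df$electrode_id); tt <- as.numeric(df$spike_time_s)
  }
  if (is.unsorted(tt))
    warning("spike times out of order in ", path, "; sorting")
  spike_train_set(el, tt, geometry, duration_s = duration_s)
}

#' Write / read a stimulation log
#'
#' @param stims a [stimulation_log()].
#' @param path CSV path.
#' @export
write_stimulation_log <- function(stims, path) {
  write.csv(data.frame(stim_time_s = stims$time_s, site_label = stims$site,
                       block = stims$block),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulation_log
#' @return `read_stimulation_log`: a [stimulation_log()]. Unknown site
#'   labels raise an error naming the offending row.
#' @export
read_stimulation_log <- function(path) {
  df <- read.csv(path)
  req <- c("stim_time_s", "site_label")
  if (!all(req %in% names(df)))
    stop_param("stimulation log must have columns ",
               paste(req, collapse = ", "))
  stimulation_log(df$stim_time_s, df$site_label,
                  block = if ("block" %in% names(df)) df$block else NULL)
}

#' Write / read response patterns
#'
#' HDF5 (`.h5`) stores the stimulus x electrode x bin integer array with
#' site labels and the window as attributes-like datasets; any other
#' extension writes long-format CSV (stimulus, electrode, bin, count,
#' site, block) plus activation times.
#'
#' @param patterns a [extract_patterns()] result.
#' @param path output path.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "response_patterns"))
  if (grepl("\\.h5$", path)) {
    need_rhdf5()
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(patterns$counts, path, "counts")
    rhdf5::h5write(patterns$site, path, "site")
    rhdf5::h5write(patterns$block, path, "block")
    act <- patterns$activation_ms
    act[is.na(act)] <- -1
    rhdf5::h5write(act, path, "activation_ms")
    rhdf5::h5write(unlist(patterns$window[c("response_window_ms",
                                            "synaptic_onset_ms",
                                            "bin_width_ms")]),
                   path, "window")
    rhdf5::h5write(c(patterns$geometry$n_rows, patterns$geometry$n_cols),
                   path, "grid_dims")
    rhdf5::h5closeAll()
  } else {
    d <- dim(patterns$counts)
    idx <- which(patterns$counts > 0L, arr.ind = TRUE)
    long <- data.frame(stimulus = idx[, 1L], electrode = idx[, 2L],
                       bin = idx[, 3L],
                       count = patterns$counts[idx],
                       site = patterns$site[idx[, 1L]],
                       block = patterns$block[idx[, 1L]])
    meta <- list(n_stimuli = d[1L], n_electrodes = d[2L], n_bins = d[3L],
                 site = patterns$site, block = patterns$block,
                 window = patterns$window[c("response_window_ms",
                                            "synaptic_onset_ms",
                                            "bin_width_ms")],
                 grid_dims = c(patterns$geometry$n_rows,
                               patterns$geometry$n_cols),
                 activation_ms = as.vector(patterns$activation_ms))
    write.csv(long, path, row.names = FALSE)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' @rdname write_patterns
#' @return `read_patterns`: a `response_patterns` object.
#' @export
read_patterns <- function(path) {
  if (grepl("\\.h5$", path)) {
    need_rhdf5()
    counts <- rhdf5::h5read(path, "counts")
    site <- as.character(rhdf5::h5read(path, "site"))
    block <- as.integer(rhdf5::h5read(path, "block"))
    act <- rhdf5::h5read(path, "activation_ms")
    act[act < 0] <- NA_real_
    w <- as.numeric(rhdf5::h5read(path, "window"))
    dims <- as.integer(rhdf5::h5read(path, "grid_dims"))
    rhdf5::h5closeAll()
    window <- window_spec(w[1], w[2], w[3])
    geometry <- array_geometry(dims[1], dims[2])
  } else {
    long <- read.csv(path)
    meta <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
    counts <- array(0L, c(meta$n_stimuli, meta$n_electrodes, meta$n_bins))
    if (nrow(long))
      counts[cbind(long$stimulus, long$electrode, long$bin)] <-
        as.integer(long$count)
    site <- as.character(meta$site)
    block <- as.integer(meta$block)
    act <- matrix(as.numeric(meta$activation_ms),
                  meta$n_stimuli, meta$n_electrodes)
    window <- window_spec(meta$window$response_window_ms,
                          meta$window$synaptic_onset_ms,
                          meta$window$bin_width_ms)
    geometry <- array_geometry(meta$grid_dims[1], meta$grid_dims[2])
  }
  counts <- array(as.integer(counts), dim(counts))
  structure(list(counts = counts,
                 activation_ms = matrix(as.numeric(act), dim(counts)[1L],
                                        dim(counts)[2L]),
                 total = matrix(as.integer(apply(counts, c(1L, 2L), sum)),
                                dim(counts)[1L], dim(counts)[2L]),
                 site = site, block = block, window = window,
                 geometry = geometry),
            class = "response_patterns")
}

#' Write a signature pair as CSV + JSON summary
#'
#' Writes `<stem>_overlap.csv` and `<stem>_flags.csv` (electrodes x
#' bins, NA for not-applicable) plus `<stem>_summary.json`.
#'
#' @param signature a [build_signatures()] result.
#' @param stem output path stem.
#' @export
write_signatures <- function(signature, stem) {
  write.csv(signature$overlaps, paste0(stem, "_overlap.csv"),
            row.names = FALSE)
  write.csv(signature$flags * 1, paste0(stem, "_flags.csv"),
            row.names = FALSE)
  s <- list(feature = signature$feature, alpha = signature$alpha,
            test = signature$test, n_cells = signature$n_cells,
            electrodes = signature$electrodes,
            n_selective = sum(signature$flags, na.rm = TRUE),
            median_overlap = if (signature$n_cells > 0)
              stats::median(signature$overlaps, na.rm = TRUE) else NA)
  jsonlite::write_json(s, paste0(stem, "_summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(stem)
}

#' Write ground truth to a JSON sidecar
#' @param truth the `truth` component of [generate_recording()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(selective_electrodes = truth$selective_electrodes,
              selective_rate_electrodes = truth$selective_rate_electrodes,
              selective_latency_electrodes = truth$selective_latency_electrodes,
              selective_rate_cells = which(truth$selective_rate_cells,
                                           arr.ind = TRUE),
              spont_burst_times_s = truth$spont_burst_times_s,
              isi_s = truth$isi_s, seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read raw traces (HDF5)
#'
#' Channels x samples matrix in microvolts with the sampling rate
#' stored alongside.
#'
#' @param raw a `raw_recording`.
#' @param path `.h5` path.
#' @export
write_raw_recording <- function(raw, path) {
  need_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(raw$data, path, "traces_uv")
  rhdf5::h5write(raw$sampling_rate_hz, path, "sampling_rate_hz")
  rhdf5::h5write(raw$channel_ids, path, "channel_ids")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_raw_recording
#' @export
read_raw_recording <- function(path) {
  need_rhdf5()
  dat <- rhdf5::h5read(path, "traces_uv")
  fs <- as.numeric(rhdf5::h5read(path, "sampling_rate_hz"))
  ch <- as.integer(rhdf5::h5read(path, "channel_ids"))
  rhdf5::h5closeAll()
  structure(list(data = dat, sampling_rate_hz = fs, channel_ids = ch,
                 duration_s = ncol(dat) / fs),
            class = "raw_recording")
}

#' Read a pipeline configuration (JSON or YAML)
#'
#' @param path `.json`, `.yaml` or `.yml` file with any of the blocks
#'   `geometry`, `protocol`, `window`, `detection`, `model`,
#'   `selectivity`, `classification`, `seed`.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_param("YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a classification report (or list of reports) as JSON
#' @param report a `classification_report` or a named list of them.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  strip <- function(r) r[setdiff(names(r), c("confusion", "cluster"))]
  out <- if (inherits(report, "classification_report")) strip(report)
         else lapply(report, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
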