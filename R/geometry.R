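#' Microelectrode array geometry
#'
#' Describes the planar electrode grid. The default is the 8 x 8 layout of
#' 64 electrodes of 50 um size spaced 150 um apart that is standard for
#' commercial planar MEAs used with dissociated cultures. Electrode ids
#' run 1..n_rows*n_cols in row-major order over the grid.
#'
#' @param n_rows,n_cols grid dimensions (default 8 x 8).
#' @param electrode_pitch_um centre-to-centre spacing in micrometres
#'   (default 150); must exceed `electrode_size_um`.
#' @param electrode_size_um electrode side length in micrometres (default 50).
#' @return an object of class `mea_geometry`.
#' @examples
#' geom <- array_geometry()
#' n_electrodes(geom)  # 64
#' @export
array_geometry <- function(n_rows = 8L, n_cols = 8L,
                           electrode_pitch_um = 150,
                           electrode_size_um = 50) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L)
    stop_param("grid dimensions must be positive")
  if (!(electrode_pitch_um > electrode_size_um && electrode_size_um > 0))
    stop_param("electrode pitch must exceed electrode size, both positive")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         electrode_pitch_um = electrode_pitch_um,
         electrode_size_um = electrode_size_um),
    class = "mea_geometry")
}

#' Number of electrodes on an array
#' @param geometry an [array_geometry()] object.
#' @return integer electrode count.
#' @export
n_electrodes <- function(geometry) geometry$n_rows * geometry$n_cols

#' Grid position of electrodes
#'
#' @param geometry an [array_geometry()] object.
#' @return data.frame with columns `electrode`, `row`, `col` (row-major ids)
#'   and physical coordinates `x_um`, `y_um`.
#' @export
electrode_positions <- function(geometry) {
  ne <- n_electrodes(geometry)
  e <- seq_len(ne)
  row <- (e - 1L) %/% geometry$n_cols + 1L
  col <- (e - 1L) %% geometry$n_cols + 1L
  data.frame(electrode = e, row = row, col = col,
             x_um = (col - 1L) * geometry$electrode_pitch_um,
             y_um = (row - 1L) * geometry$electrode_pitch_um)
}

#' @export
print.mea_geometry <- function(x, ...) {
  cat(sprintf("MEA geometry: %d x %d electrodes (%d total), %g um size, %g um pitch\n",
              x$n_rows, x$n_cols, n_electrodes(x),
              x$electrode_size_um, x$electrode_pitch_um))
  invisible(x)
}

#' Stimulation protocol specification
#'
#' The trial protocol stimulates each of two sites in alternating blocks:
#' S1 x 15 stimuli, S2 x 15, S1 x 15, S2 x 15, for 30 stimuli per site in
#' total. The inter-stimulus interval is matched to the culture's
#' spontaneous inter-burst interval (10--20 s); if `inter_stimulus_interval_s`
#' is NULL one value is drawn uniformly from `interval_range_s` per
#' generated recording, mirroring the per-culture choice.
#'
#' @param n_sites number of stimulation sites (default 2).
#' @param stimuli_per_block stimuli per block (default 15).
#' @param blocks_per_site blocks per site (default 2).
#' @param inter_stimulus_interval_s fixed inter-stimulus interval in
#'   seconds, or NULL to draw per recording.
#' @param interval_range_s admissible interval range in seconds
#'   (default c(10, 20)), matching spontaneous inter-burst intervals.
#' @param site_order order of blocks as site indices; default alternates
#'   `1,2,1,2,...` over `n_sites * blocks_per_site` blocks.
#' @return an object of class `mea_protocol`.
#' @export
protocol_spec <- function(n_sites = 2L, stimuli_per_block = 15L,
                          blocks_per_site = 2L,
                          inter_stimulus_interval_s = NULL,
                          interval_range_s = c(10, 20),
                          site_order = NULL) {
  n_sites <- as.integer(n_sites)
  stimuli_per_block <- as.integer(stimuli_per_block)
  blocks_per_site <- as.integer(blocks_per_site)
  if (n_sites < 1L || stimuli_per_block < 1L || blocks_per_site < 1L)
    stop_param("protocol counts must be positive")
  if (length(interval_range_s) != 2L || diff(interval_range_s) < 0 ||
      interval_range_s[1] <= 0)
    stop_param("interval_range_s must be an increasing positive pair")
  if (!is.null(inter_stimulus_interval_s) &&
      (inter_stimulus_interval_s < interval_range_s[1] ||
       inter_stimulus_interval_s > interval_range_s[2]))
    stop_param("inter_stimulus_interval_s outside interval_range_s")
  if (is.null(site_order))
    site_order <- rep(seq_len(n_sites), blocks_per_site)
  site_order <- as.integer(site_order)
  if (length(site_order) != n_sites * blocks_per_site ||
      any(tabulate(site_order, n_sites) != blocks_per_site))
    stop_param("site_order must contain each site blocks_per_site times")
  structure(
    list(n_sites = n_sites, stimuli_per_block = stimuli_per_block,
         blocks_per_site = blocks_per_site,
         inter_stimulus_interval_s = inter_stimulus_interval_s,
         interval_range_s = interval_range_s,
         site_order = site_order),
    class = "mea_protocol")
}

#' @export
print.mea_protocol <- function(x, ...) {
  cat(sprintf(
    "Stimulation protocol: %d site(s), %d block(s) x %d stimuli per site (%d per site in total)\n",
    x$n_sites, x$blocks_per_site, x$stimuli_per_block,
    x$blocks_per_site * x$stimuli_per_block))
  cat(sprintf("  block order: %s\n",
              paste0("S", x$site_order, collapse = " ")))
  isi <- if (is.null(x$inter_stimulus_interval_s)) {
    sprintf("drawn per recording from [%g, %g] s", x$interval_range_s[1],
            x$interval_range_s[2])
  } else sprintf("%g s", x$inter_stimulus_interval_s)
  cat("  inter-stimulus interval:", isi, "\n")
  invisible(x)
}

site_labels <- function(protocol) paste0("S", seq_len(protocol$n_sites))

#' Construct a spike-train set
#'
#' The native container of the pipeline: one row per spike with its
#' electrode id and absolute time in seconds from recording start.
#'
#' @param electrode integer electrode ids (1-based, row-major grid order).
#' @param time_s spike times in seconds.
#' @param geometry an [array_geometry()]; electrode ids must not exceed
#'   its electrode count.
#' @param duration_s recording duration in seconds (defaults to the last
#'   spike time).
#' @return an object of class `spike_train_set`: a list with a `spikes`
#'   data.frame (sorted by time), the geometry and the duration.
#' @export
spike_train_set <- function(electrode, time_s, geometry = array_geometry(),
                            duration_s = NULL) {
  electrode <- as.integer(electrode)
  time_s <- as.numeric(time_s)
  if (length(electrode) != length(time_s))
    stop_param("electrode and time_s lengths differ")
  if (length(time_s) && (any(!is.finite(time_s)) || any(time_s < 0)))
    stop_param("spike times must be finite and non-negative")
  ne <- n_electrodes(geometry)
  if (length(electrode) && (any(electrode < 1L) || any(electrode > ne)))
    stop_param("electrode ids must be in 1..", ne)
  o <- order(time_s, electrode)
  spikes <- data.frame(electrode = electrode[o], time_s = time_s[o])
  duration_s <- duration_s %||% if (nrow(spikes)) max(spikes$time_s) else 0
  structure(list(spikes = spikes, geometry = geometry,
                 duration_s = duration_s),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("Spike-train set: %d spikes on %d electrodes, %.1f s\n",
              nrow(x$spikes), n_electrodes(x$geometry), x$duration_s))
  invisible(x)
}

#' Construct a stimulation log
#'
#' @param time_s stimulus onset times (seconds), strictly increasing.
#' @param site site labels (`"S1"`, `"S2"`, ...) or site indices.
#' @param block optional block index per stimulus (1-based); inferred as a
#'   new block whenever the site changes if omitted.
#' @return an object of class `stimulation_log`: data.frame with columns
#'   `stim_index`, `time_s`, `site`, `block`.
#' @export
stimulation_log <- function(time_s, site, block = NULL) {
  time_s <- as.numeric(time_s)
  if (any(!is.finite(time_s)) || is.unsorted(time_s, strictly = TRUE))
    stop_param("stimulus times must be finite and strictly increasing")
  if (is.numeric(site)) site <- paste0("S", as.integer(site))
  site <- as.character(site)
  bad <- !grepl("^S[0-9]+$", site)
  if (any(bad))
    stop_param("unknown site label '", site[which(bad)[1]], "' at row ",
               which(bad)[1])
  if (length(site) != length(time_s)) stop_param("site/time length mismatch")
  if (is.null(block)) {
    block <- integer(length(site))
    seen <- integer(0); names(seen) <- character(0)
    run <- cumsum(c(TRUE, site[-1] != site[-length(site)]))
    for (s in unique(site)) block[site == s] <-
        as.integer(factor(run[site == s]))
  }
  df <- data.frame(stim_index = seq_along(time_s), time_s = time_s,
                   site = site, block = as.integer(block))
  structure(df, class = c("stimulation_log", "data.frame"))
}

#' @export
print.stimulation_log <- function(x, ...) {
  cat(sprintf("Stimulation log: %d stimuli, sites %s\n", nrow(x),
              paste(sort(unique(x$site)), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
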