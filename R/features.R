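# Per-stimulus response features and inclusion filters.
#
# Each stimulus opens a 300 ms post-stimulus window. Spikes in the first
# 15 ms are of non-synaptic origin and are discarded; the remaining
# spikes are binned into 20 ms bins aligned to the stimulus ([0,20),
# [20,40), ... [280,300) ms, the first bin therefore effectively
# covering [15,20) ms). Per electrode the features are the binned
# spike-rate pattern, the activation time (latency of the first retained
# spike) and the total spike count.

#' Post-stimulus window specification
#'
#' @param response_window_ms length of the response window (default 300).
#' @param synaptic_onset_ms spikes earlier than this are discarded as
#'   non-synaptic (default 15).
#' @param bin_width_ms bin width (default 20); must divide the window.
#' @return an object of class `window_spec` with derived `n_bins`.
#' @export
window_spec <- function(response_window_ms = 300, synaptic_onset_ms = 15,
                        bin_width_ms = 20) {
  if (response_window_ms %% bin_width_ms != 0)
    stop_param("bin width must divide the response window")
  if (!(synaptic_onset_ms >= 0 && synaptic_onset_ms < response_window_ms))
    stop_param("synaptic onset must lie inside the response window")
  structure(list(response_window_ms = response_window_ms,
                 synaptic_onset_ms = synaptic_onset_ms,
                 bin_width_ms = bin_width_ms,
                 n_bins = as.integer(response_window_ms / bin_width_ms)),
            class = "window_spec")
}

#' Extract one stimulus response
#'
#' @param spikes a [spike_train_set()].
#' @param stim_time_s stimulus onset (seconds).
#' @param window a [window_spec()].
#' @param next_stim_time_s onset of the following stimulus; the window is
#'   truncated there so no spike is counted twice (default Inf).
#' @return an object of class `response_pattern`: `counts`
#'   (electrodes x bins integer matrix), `activation_ms` (per electrode;
#'   NA when the electrode fired no retained spike), `total` (per
#'   electrode) and the window.
#' @examples
#' sp <- spike_train_set(c(1, 1, 1), 5 + c(0.010, 0.030, 0.250))
#' r <- extract_response(sp, 5)
#' r$activation_ms[1]  # 30 (the 10 ms spike is non-synaptic)
#' r$total[1]          # 2
#' @export
extract_response <- function(spikes, stim_time_s, window = window_spec(),
                             next_stim_time_s = Inf) {
  ne <- n_electrodes(spikes$geometry)
  nb <- window$n_bins
  upper <- min(window$response_window_ms,
               (next_stim_time_s - stim_time_s) * 1000)
  # round to 1e-6 ms (sub-ns) so window boundaries are insensitive to
  # the binary representation of times stored in seconds
  lat <- round((spikes$spikes$time_s - stim_time_s) * 1000, 6)
  keep <- lat >= window$synaptic_onset_ms & lat < upper
  lat <- lat[keep]
  el <- spikes$spikes$electrode[keep]
  bin <- pmin(nb, floor(lat / window$bin_width_ms) + 1L)
  counts <- matrix(0L, ne, nb)
  if (length(el)) {
    tb <- table(factor(el, levels = seq_len(ne)),
                factor(bin, levels = seq_len(nb)))
    counts <- matrix(as.integer(tb), ne, nb)
  }
  activation <- rep(NA_real_, ne)
  if (length(el)) {
    first <- tapply(lat, factor(el, levels = seq_len(ne)), min)
    activation <- as.numeric(first)
  }
  structure(list(counts = counts, activation_ms = activation,
                 total = as.integer(rowSums(counts)), window = window),
            class = "response_pattern")
}

#' Extract all stimulus responses of a recording
#'
#' @param spikes a [spike_train_set()].
#' @param stims a [stimulation_log()].
#' @param window a [window_spec()].
#' @return an object of class `response_patterns`: `counts`
#'   (stimuli x electrodes x bins array), `activation_ms` and `total`
#'   (stimuli x electrodes matrices), `site` and `block` per stimulus,
#'   the window and geometry.
#' @export
extract_patterns <- function(spikes, stims, window = window_spec()) {
  stopifnot(inherits(stims, "stimulation_log"))
  ne <- n_electrodes(spikes$geometry)
  ns <- nrow(stims)
  nb <- window$n_bins
  counts <- array(0L, c(ns, ne, nb))
  activation <- matrix(NA_real_, ns, ne)
  total <- matrix(0L, ns, ne)
  nxt <- c(stims$time_s[-1L], Inf)
  for (k in seq_len(ns)) {
    r <- extract_response(spikes, stims$time_s[k], window, nxt[k])
    counts[k, , ] <- r$counts
    activation[k, ] <- r$activation_ms
    total[k, ] <- r$total
  }
  structure(list(counts = counts, activation_ms = activation, total = total,
                 site = stims$site, block = stims$block, window = window,
                 geometry = spikes$geometry),
            class = "response_patterns")
}

#' @export
print.response_patterns <- function(x, ...) {
  cat(sprintf("Response patterns: %d stimuli x %d electrodes x %d bins (sites: %s)\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              paste(sort(unique(x$site)), collapse = ", ")))
  invisible(x)
}

#' Population post-stimulus time histogram
#'
#' Total spike count over all electrodes within each post-stimulus bin,
#' either summed or averaged over stimuli.
#'
#' @param patterns a [extract_patterns()] result.
#' @param mode `"mean"` (per-stimulus average, default) or `"sum"`.
#' @param site optional site label to restrict to.
#' @return numeric vector of per-bin totals.
#' @export
population_psth <- function(patterns, mode = c("mean", "sum"), site = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(patterns, "response_patterns"))
  sel <- if (is.null(site)) seq_along(patterns$site)
         else which(patterns$site == site)
  if (!length(sel)) stop_param("no stimuli", if (!is.null(site)) paste0(" for site ", site))
  per_bin <- apply(patterns$counts[sel, , , drop = FALSE], 3L, sum)
  if (mode == "mean") per_bin / length(sel) else per_bin
}

#' Active electrodes
#'
#' Electrodes eliciting at least one spike within the response window in
#' MORE than `threshold_frac` of the stimuli (strict inequality). By
#' default the criterion must hold for each stimulation site separately.
#'
#' @param patterns a [extract_patterns()] result.
#' @param threshold_frac response-fraction threshold (default 0.8).
#' @param per_site require the criterion per site (default TRUE) or on
#'   the pooled stimuli.
#' @return sorted integer vector of active electrode ids.
#' @export
active_electrodes <- function(patterns, threshold_frac = 0.8,
                              per_site = TRUE) {
  responded <- patterns$total >= 1L
  groups <- if (per_site) unique(patterns$site) else "all"
  ok <- rep(TRUE, ncol(responded))
  for (g in groups) {
    rows <- if (identical(g, "all")) seq_along(patterns$site)
            else which(patterns$site == g)
    ok <- ok & colMeans(responded[rows, , drop = FALSE]) > threshold_frac
  }
  which(ok)
}

#' Stable (reproducible) time bins per electrode
#'
#' Bins in which AT LEAST `threshold_frac` of the stimuli evoked at
#' least one spike (inclusive inequality, unlike the strict
#' active-electrode criterion). Evaluated per site by default; a bin is
#' stable when it satisfies the criterion for every site.
#'
#' @param patterns a [extract_patterns()] result.
#' @param electrodes electrodes to evaluate (default the active set).
#' @param threshold_frac threshold (default 0.8).
#' @param per_site evaluate per site (default TRUE) or pooled.
#' @return named list mapping electrode id to an integer vector of
#'   stable bin indices.
#' @export
stable_bins <- function(patterns, electrodes = active_electrodes(patterns),
                        threshold_frac = 0.8, per_site = TRUE) {
  nb <- dim(patterns$counts)[3]
  groups <- if (per_site) unique(patterns$site) else "all"
  out <- lapply(electrodes, function(e) {
    ok <- rep(TRUE, nb)
    for (g in groups) {
      rows <- if (identical(g, "all")) seq_along(patterns$site)
              else which(patterns$site == g)
      frac <- colMeans(patterns$counts[rows, e, , drop = FALSE] >= 1L)
      ok <- ok & frac >= threshold_frac
    }
    which(ok)
  })
  names(out) <- as.character(electrodes)
  out
}

#' Stationarity filter across repeated stimulation blocks
#'
#' For each electrode and each site, the total spike counts of the first
#' and second stimulation block are compared with a two-sided
#' Mann-Whitney rank-sum test; an electrode is non-stationary if the
#' difference is significant for any site. Zero-count responses are
#' excluded from the comparison by default (only responses containing at
#' least one spike are considered); electrodes with fewer than 2 usable
#' responses in a block cannot be tested and are retained as stationary.
#'
#' @param patterns a [extract_patterns()] result with two blocks per site.
#' @param alpha significance level (default 0.05).
#' @param electrodes electrodes to test (default the active set).
#' @param nonzero_only drop zero-count responses before testing
#'   (default TRUE).
#' @return list with `stationary` and `nonstationary` electrode id
#'   vectors and the p-value matrix `p` (electrodes x sites).
#' @export
stationarity_filter <- function(patterns, alpha = 0.05,
                                electrodes = active_electrodes(patterns),
                                nonzero_only = TRUE) {
  sites <- sort(unique(patterns$site))
  for (s in sites)
    if (length(unique(patterns$block[patterns$site == s])) < 2L)
      stop_param("site ", s, " lacks a second stimulation block")
  p <- matrix(NA_real_, length(electrodes), length(sites),
              dimnames = list(as.character(electrodes), sites))
  for (i in seq_along(electrodes)) {
    e <- electrodes[i]
    for (j in seq_along(sites)) {
      rows1 <- patterns$site == sites[j] & patterns$block == 1L
      rows2 <- patterns$site == sites[j] & patterns$block == 2L
      x1 <- patterns$total[rows1, e]; x2 <- patterns$total[rows2, e]
      if (nonzero_only) { x1 <- x1[x1 > 0L]; x2 <- x2[x2 > 0L] }
      if (length(x1) >= 2L && length(x2) >= 2L)
        p[i, j] <- suppressWarnings(
          wilcox.test(x1, x2, exact = FALSE)$p.value)
    }
  }
  nonstat <- electrodes[apply(p, 1L, function(v) any(v < alpha, na.rm = TRUE))]
  list(stationary = setdiff(electrodes, nonstat),
       nonstationary = nonstat, p = p, alpha = alpha)
}

#' Combined inclusion-filter report
#'
#' Applies the activity, bin-stability and stationarity criteria and
#' summarizes what was excluded at each step.
#'
#' @param patterns a [extract_patterns()] result.
#' @param active_frac,stable_frac thresholds (default 0.8 each).
#' @param alpha stationarity test level (default 0.05).
#' @param per_site evaluate activity/stability per site (default TRUE).
#' @return an object of class `filter_report`: `active`, `stable_bins`
#'   (for active electrodes), `stationary` (subset of active),
#'   `nonstationary`, and exclusion counts.
#' @export
filter_report <- function(patterns, active_frac = 0.8, stable_frac = 0.8,
                          alpha = 0.05, per_site = TRUE) {
  ne <- dim(patterns$counts)[2]
  act <- active_electrodes(patterns, active_frac, per_site)
  sb <- stable_bins(patterns, act, stable_frac, per_site)
  st <- stationarity_filter(patterns, alpha, act)
  structure(list(active = act, stable_bins = sb,
                 stationary = st$stationary,
                 nonstationary = st$nonstationary,
                 stationarity_p = st$p,
                 excluded = list(inactive = ne - length(act),
                                 nonstationary = length(st$nonstationary))),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d active electrodes (%d excluded as inactive)\n",
              length(x$active), x$excluded$inactive))
  cat(sprintf("  stationary: %d (%d flagged non-stationary)\n",
              length(x$stationary), x$excluded$nonstationary))
  nb <- lengths(x$stable_bins)
  if (length(nb))
    cat(sprintf("  stable bins per active electrode: median %g (range %d-%d)\n",
                stats::median(nb), min(nb), max(nb)))
  invisible(x)
}
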