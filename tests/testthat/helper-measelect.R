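# Shared builders for the test suite. All fixtures are generated in
# code; sizes are kept small where the property under test allows it.

# A small array for cheap simulations (8 electrodes).
small_geometry <- function() array_geometry(n_rows = 2L, n_cols = 4L)

# Fast protocol: the standard 2 x 15 x 2 block structure with a fixed
# short inter-stimulus interval (timeline length is irrelevant to the
# stimulus-locked analyses; the renewal range is widened accordingly).
fast_protocol <- function(isi = 1)
  protocol_spec(inter_stimulus_interval_s = isi,
                interval_range_s = c(min(1, isi), 20))

# Small-array model without spontaneous contamination, defaults
# otherwise; `...` overrides default_response_model() arguments.
small_model <- function(geometry = small_geometry(), ...) {
  args <- list(...)
  args$geometry <- geometry
  if (is.null(args$n_active)) args$n_active <- n_electrodes(geometry)
  if (is.null(args$spontaneous))
    args$spontaneous <- spontaneous_spec(enabled = FALSE)
  do.call(default_response_model, args)
}

# Null model: no site effect anywhere (used by calibration tests).
null_model <- function(geometry = array_geometry(), ...)
  default_response_model(geometry = geometry, rate_ratio = 1,
                         latency_shift_ms = 0, ...)

# One small recording -> response_patterns, for feature-level tests.
small_patterns <- function(seed = 1, model = small_model(), ...) {
  rec <- generate_recording(geometry = model_geometry(model),
                            protocol = fast_protocol(), model = model,
                            seed = seed, warmup_s = 2, ...)
  extract_patterns(rec$spikes, rec$stims)
}

model_geometry <- function(model) {
  ne <- nrow(model$p)
  if (ne == 64L) array_geometry() else array_geometry(2L, ne %/% 2L)
}

# Hand-built response_patterns from a per-stimulus spike-latency list:
# lat[[k]] is a list mapping electrode id -> latencies (ms) for
# stimulus k. Used to test inclusion criteria at exact boundaries.
patterns_from_latencies <- function(lat, sites, geometry = small_geometry(),
                                    window = window_spec()) {
  isi <- 1
  times <- (seq_along(lat) - 1) * isi + 0.5
  el <- integer(0); tt <- numeric(0)
  for (k in seq_along(lat)) {
    for (e in names(lat[[k]])) {
      ms <- lat[[k]][[e]]
      el <- c(el, rep.int(as.integer(e), length(ms)))
      tt <- c(tt, times[k] + ms / 1000)
    }
  }
  sp <- spike_train_set(el, tt, geometry,
                        duration_s = max(times) + 0.5)
  extract_patterns(sp, stimulation_log(times, sites), window)
}

# feature_matrix built directly from a numeric matrix + labels, to test
# classifiers against analytic oracles without the generator.
fm_from_matrix <- function(X, y, feature = "total_count") {
  structure(list(x = as.matrix(X) * 1.0, y = factor(y), feature = feature,
                 electrodes = seq_len(ncol(as.matrix(X))), n_imputed = 0L),
            class = "feature_matrix")
}
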