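# Generator: determinism, null process, Poisson moment calibration,
# spontaneous renewal statistics, ground-truth bookkeeping, raw traces.

test_that("identical seeds give bit-identical recordings, different seeds differ", {
  m <- small_model()
  r1 <- generate_recording(small_geometry(), fast_protocol(), m, seed = 42)
  r2 <- generate_recording(small_geometry(), fast_protocol(), m, seed = 42)
  r3 <- generate_recording(small_geometry(), fast_protocol(), m, seed = 43)
  expect_identical(r1$spikes$spikes, r2$spikes$spikes)
  expect_identical(r1$truth$responsive, r2$truth$responsive)
  expect_false(identical(r1$spikes$spikes, r3$spikes$spikes))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_recording(small_geometry(),
                                            fast_protocol(), m, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("null process (p = 0, no spontaneous bursts) emits zero spikes", {
  m <- small_model()
  m$p[] <- 0
  rec <- generate_recording(small_geometry(), fast_protocol(), m, seed = 1)
  expect_identical(nrow(rec$spikes$spikes), 0L)
})

test_that("per-electrode response counts match the configured Poisson expectation", {
  # latency coupling and burst gain off -> thinned inhomogeneous Poisson
  # with bin 1 prorated to [15,20) ms; expectation p * sum(lambda_eff).
  m <- small_model(latency_coupled = FALSE, gain_spread = 0,
                   rate_ratio = 1, latency_shift_ms = 0)
  rec <- generate_recording(small_geometry(), fast_protocol(), m, seed = 11)
  pat <- extract_patterns(rec$spikes, rec$stims)
  for (e in c(1L, 5L)) {
    lam <- m$rate[e, 1L, ]
    lam_eff <- sum(lam) - lam[1] * 0.75   # bin 1 covers 5 of 20 ms
    p <- m$p[e, 1L]
    expectation <- p * lam_eff
    v <- p * lam_eff + p * (1 - p) * lam_eff^2   # Bernoulli-thinned Poisson
    obs <- mean(pat$total[, e])
    expect_lt(abs(obs - expectation), 3 * sqrt(v / nrow(pat$total)))
  }
})

test_that("per-bin counts are Poisson-consistent (Fano factor ~ 1) without jitter", {
  m <- small_model(latency_coupled = FALSE, gain_spread = 0,
                   rate_ratio = 1, latency_shift_ms = 0)
  m$p[] <- 1   # remove Bernoulli thinning so variance/mean is exactly 1
  rec <- generate_recording(small_geometry(), fast_protocol(), m, seed = 12)
  pat <- extract_patterns(rec$spikes, rec$stims)
  fano <- c()
  for (e in seq_len(8)) for (b in 2:8) {
    x <- pat$counts[, e, b]
    if (mean(x) > 0.5) fano <- c(fano, var(x) / mean(x))
  }
  expect_gt(length(fano), 20)
  expect_lt(abs(mean(fano) - 1), 0.15)
})

test_that("spontaneous-only run has a renewal-consistent burst count", {
  # 200 s of spontaneous activity with gaps uniform in [10, 20] s:
  # the count must lie in [200/20, 200/10] up to boundary effects.
  m <- small_model(n_sites = 1L, spontaneous = spontaneous_spec())
  m$p[] <- 0
  prot <- protocol_spec(n_sites = 1L, stimuli_per_block = 1L,
                        blocks_per_site = 1L,
                        inter_stimulus_interval_s = 10)
  for (seed in 1:5) {
    rec <- generate_recording(small_geometry(), prot, m,
                              seed = seed, warmup_s = 200, tail_s = 0)
    n_bursts <- sum(rec$truth$spont_burst_times_s <= 200)
    expect_gte(n_bursts, 9); expect_lte(n_bursts, 21)
    expect_gt(nrow(rec$spikes$spikes), 0)
  }
})

test_that("ground truth is empty iff the model has no site effect", {
  rec0 <- generate_recording(small_geometry(), fast_protocol(),
                             small_model(rate_ratio = 1, latency_shift_ms = 0),
                             seed = 1)
  expect_length(rec0$truth$selective_electrodes, 0)
  m1 <- small_model(selective_electrodes = c(2L, 3L), selective_bins = 2:4)
  rec1 <- generate_recording(small_geometry(), fast_protocol(), m1, seed = 1)
  expect_identical(rec1$truth$selective_electrodes, c(2L, 3L))
  expect_true(all(which(rowSums(rec1$truth$selective_rate_cells) > 0) %in%
                    c(2L, 3L)))
})

test_that("invalid model parameters are rejected", {
  m <- small_model()
  m$p[1, 1] <- 1.5
  expect_error(do.call(response_model, m[c("p", "rate", "latency_mean_ms",
                                           "latency_sd_ms")]),
               "must lie in")
  m2 <- small_model()
  m2$rate[1, 1, 1] <- -2
  expect_error(do.call(response_model, m2[c("p", "rate", "latency_mean_ms",
                                            "latency_sd_ms")]),
               "non-negative")
})

test_that("raw traces: noise floor, spike placement and amplitude range", {
  geom <- array_geometry(1L, 2L)
  # noise only: sample SD within 2 % of the configured value over 10 s
  empty <- spike_train_set(integer(0), numeric(0), geom, duration_s = 10)
  spec <- raw_trace_spec(noise_sd_uv = 3)
  raw <- generate_raw_trace(empty, spec, seed = 1, channels = 1L)
  expect_equal(dim(raw$data), c(1L, 200000L))
  expect_lt(abs(sd(raw$data[1, ]) - 3) / 3, 0.02)

  # a single 40 uV spike in 3 uV noise peaks within +/-1 sample
  one <- spike_train_set(1L, 0.5, geom, duration_s = 1)
  spec40 <- raw_trace_spec(noise_sd_uv = 3, amplitude_range_uv = c(40, 40))
  raw1 <- generate_raw_trace(one, spec40, seed = 2, channels = 1L)
  peak_idx <- which.max(abs(raw1$data[1, ]))
  expect_lte(abs(peak_idx - (round(0.5 * 20000) + 1)), 1)
  expect_lt(abs(max(abs(raw1$data[1, ])) - 40), 3 * 4)

  # amplitudes drawn within [10, 40] uV: noiseless trace peaks per spike
  many <- spike_train_set(rep(1L, 50), seq(0.05, by = 0.02, length.out = 50),
                          geom, duration_s = 1.2)
  spec0 <- raw_trace_spec(noise_sd_uv = 0)
  raw2 <- generate_raw_trace(many, spec0, seed = 3, channels = 1L)
  idx <- round(seq(0.05, by = 0.02, length.out = 50) * 20000) + 1
  peaks <- abs(raw2$data[1, idx])
  expect_true(all(peaks >= 10 - 1e-9 & peaks <= 40 + 1e-9))

  # spike beyond the duration is rejected
  expect_error(generate_raw_trace(one, spec, seed = 1, duration_s = 0.2),
               "beyond")
})
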