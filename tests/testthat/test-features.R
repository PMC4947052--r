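# Response features: binning rules, conservation, shift invariance,
# inclusion criteria at their exact printed boundaries, stationarity.

test_that("extract_response applies the synaptic-onset and binning rules", {
  geom <- small_geometry()
  sp <- spike_train_set(rep(1L, 3), 5 + c(0.010, 0.030, 0.250), geom)
  r <- extract_response(sp, 5)
  expect_identical(sum(r$counts), 2L)                 # 10 ms spike discarded
  expect_identical(r$counts[1, 2], 1L)                # 30 ms -> bin [20,40)
  expect_identical(r$counts[1, 13], 1L)               # 250 ms -> bin [240,260)
  expect_equal(r$activation_ms[1], 30)
  expect_identical(r$total[1], 2L)
  # empty window
  r0 <- extract_response(sp, 50)
  expect_identical(sum(r0$counts), 0L)
  expect_true(all(is.na(r0$activation_ms)))
  # boundaries: 15 ms is retained (half-open onset), 300 ms is not
  spb <- spike_train_set(c(1L, 2L), c(5.015, 5.300), geom)
  rb <- extract_response(spb, 5)
  expect_equal(rb$activation_ms[1], 15)
  expect_identical(rb$total[2], 0L)
})

test_that("conservation and invariants hold on generated patterns", {
  pat <- small_patterns(seed = 2)
  expect_identical(pat$total,
                   matrix(as.integer(apply(pat$counts, c(1, 2), sum)),
                          nrow(pat$total), ncol(pat$total)))
  act <- pat$activation_ms
  expect_true(all(is.na(act) == (pat$total == 0L)))
  expect_true(all(act[!is.na(act)] >= 15 & act[!is.na(act)] < 300))
  expect_identical(dim(pat$counts)[3], 15L)
})

test_that("features are invariant under a common time shift", {
  m <- small_model()
  rec <- generate_recording(small_geometry(), fast_protocol(), m, seed = 3)
  pat1 <- extract_patterns(rec$spikes, rec$stims)
  sh <- 7.321
  sp2 <- spike_train_set(rec$spikes$spikes$electrode,
                         rec$spikes$spikes$time_s + sh,
                         rec$spikes$geometry)
  st2 <- stimulation_log(rec$stims$time_s + sh, rec$stims$site,
                         rec$stims$block)
  pat2 <- extract_patterns(sp2, st2)
  expect_identical(pat1$counts, pat2$counts)
  expect_equal(pat1$activation_ms, pat2$activation_ms, tolerance = 1e-9)
})

test_that("windows truncate at the next stimulus so no spike is double-counted", {
  geom <- small_geometry()
  # two stimuli 100 ms apart; one spike 250 ms after the first
  sp <- spike_train_set(1L, 1.250, geom, duration_s = 2)
  stims <- stimulation_log(c(1.0, 1.1), c("S1", "S2"),
                           block = c(1L, 1L))
  pat <- extract_patterns(sp, stims)
  expect_identical(sum(pat$counts), 1L)            # counted exactly once
  expect_identical(sum(pat$counts[1, , ]), 0L)     # not in the truncated window
  expect_identical(sum(pat$counts[2, , ]), 1L)
})

test_that("population PSTH conserves totals and peaks where the envelope peaks", {
  pat <- small_patterns(seed = 4)
  expect_identical(sum(population_psth(pat, "sum")), sum(pat$counts))
  expect_equal(population_psth(pat, "sum") / dim(pat$counts)[1],
               population_psth(pat, "mean"))
  expect_true(which.max(population_psth(pat, "mean")) %in% 3:5)
  expect_error(population_psth(pat, site = "S9"), "no stimuli")
})

test_that("active-electrode criterion is strictly greater than 80 %", {
  # single site, 30 stimuli; electrode 1 responds 24/30 (= 0.8, not
  # active), electrode 2 responds 25/30 (> 0.8, active).
  lat <- lapply(1:30, function(k) {
    l <- list()
    if (k <= 24) l[["1"]] <- 50
    if (k <= 25) l[["2"]] <- 50
    l[["3"]] <- 50
    l
  })
  pat <- patterns_from_latencies(lat, rep("S1", 30))
  expect_identical(active_electrodes(pat), c(2L, 3L))
})

test_that("stable-bin criterion is at least 80 % (inclusive)", {
  # electrode 1: bin 3 hit on every stimulus, bin 4 on 24/30 (0.8 ->
  # stable, inclusive), bin 5 on 23/30 (not stable); empty bins never
  # stable.
  lat <- lapply(1:30, function(k) {
    ms <- c(55, if (k <= 24) 65, if (k <= 23) 85)
    list("1" = ms)
  })
  pat <- patterns_from_latencies(lat, rep("S1", 30))
  sb <- stable_bins(pat, electrodes = 1L)
  expect_identical(sb[["1"]], 3:4)
})

test_that("stationarity filter: identical blocks pass, scaled blocks are flagged", {
  m <- small_model(rate_ratio = 1, latency_shift_ms = 0)
  rec <- generate_recording(small_geometry(), fast_protocol(), m, seed = 5)
  pat <- extract_patterns(rec$spikes, rec$stims)
  st <- stationarity_filter(pat, electrodes = seq_len(8))
  expect_true(all(st$stationary %in% 1:8))
  # missing second block -> error
  half <- pat; keep <- pat$block == 1L
  half$total <- pat$total[keep, ]; half$site <- pat$site[keep]
  half$block <- pat$block[keep]; half$counts <- pat$counts[keep, , ]
  expect_error(stationarity_filter(half, electrodes = 1L), "second")
})

test_that("stationarity filter detects a block-scaled electrode with high power", {
  # electrode 5 triples its rate in the second block of each site;
  # 50 replicates (scaled down from 200 for runtime) at default rates.
  scale <- rep(1, 8); scale[5] <- 3
  m <- small_model(rate_ratio = 1, latency_shift_ms = 0,
                   block2_scale = scale)
  hits <- vapply(1:50, function(i) {
    rec <- generate_recording(small_geometry(), fast_protocol(), m,
                              seed = 100 + i)
    pat <- extract_patterns(rec$spikes, rec$stims)
    5L %in% stationarity_filter(pat, electrodes = seq_len(8))$nonstationary
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("stationarity filter null flag rate is near alpha", {
  m <- small_model(rate_ratio = 1, latency_shift_ms = 0)
  flags <- unlist(lapply(1:40, function(i) {
    rec <- generate_recording(small_geometry(), fast_protocol(), m,
                              seed = 500 + i)
    pat <- extract_patterns(rec$spikes, rec$stims)
    st <- stationarity_filter(pat, electrodes = seq_len(8))
    as.vector(st$p < st$alpha)
  }))
  rate <- mean(flags, na.rm = TRUE)   # 640 electrode-site tests
  se <- sqrt(0.05 * 0.95 / sum(!is.na(flags)))
  expect_lt(rate, 0.05 + 4 * se)
})
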