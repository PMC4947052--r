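# Overlap statistic and selectivity signatures.

test_that("overlap reproduces the worked definitions exactly", {
  # disjoint supports -> 0 %
  set.seed(1)
  a <- runif(15, 10, 20); b <- runif(15, 0, 5)
  r0 <- overlap(a, b)
  expect_identical(r0$overlap_percent, 0)
  expect_identical(r0$n_c, 0L)
  # 3 of 15 site-1 responses indistinguishable from site 2 -> 10 %
  a2 <- c(rep(10, 12), rep(1, 3)); b2 <- rep(1, 15)
  r10 <- overlap(a2, b2)
  expect_identical(r10$overlap_percent, 10)
  expect_identical(r10$n_b, 3L)   # set-A members captured by cluster B'
  expect_identical(r10$n_a, 0L)
  expect_identical(r10$n_total, 30L)
})

test_that("overlap respects its preconditions and degenerate contract", {
  expect_error(overlap(c(1, 2), numeric(0)), "non-empty")
  expect_error(overlap(1, 2), "at least 4")
  d <- overlap(rep(3, 10), rep(3, 10))
  expect_identical(d$overlap_percent, 50)
  expect_true(d$degenerate)
})

test_that("overlap stays in [0, 50] over a randomized stress suite", {
  set.seed(99)
  for (i in 1:300) {
    na <- sample(2:30, 1); nb <- sample(2:30, 1)
    kind <- sample(3, 1)
    a <- switch(kind, rnorm(na, 0, 1), rpois(na, 3), rep(2, na))
    b <- switch(sample(3, 1), rnorm(nb, sample(0:2, 1), 1),
                rpois(nb, 3), rep(2, nb))
    r <- overlap(a, b)
    expect_gte(r$overlap_percent, 0); expect_lte(r$overlap_percent, 50)
  }
  # multivariate patterns too
  for (i in 1:30) {
    A <- matrix(rnorm(20 * 3, 0), 20); B <- matrix(rnorm(20 * 3, 0.5), 20)
    r <- overlap(A, B, seed = i)
    expect_gte(r$overlap_percent, 0); expect_lte(r$overlap_percent, 50)
  }
})

test_that("overlap is invariant to relabelling and affine rescaling", {
  set.seed(7)
  a <- rpois(15, 4); b <- rpois(15, 6)
  r <- overlap(a, b)
  expect_equal(overlap(b, a)$overlap_percent, r$overlap_percent)
  expect_equal(overlap(3 * a + 2, 3 * b + 2)$overlap_percent,
               r$overlap_percent)
  expect_equal(overlap(-2 * a + 1, -2 * b + 1)$overlap_percent,
               r$overlap_percent)
})

test_that("mean overlap degrades monotonically with class separation", {
  set.seed(8)
  mean_ov <- vapply(c(0, 1, 2, 4), function(d)
    mean(replicate(150, overlap(rnorm(15), rnorm(15, d))$overlap_percent)),
    numeric(1))
  expect_true(all(diff(mean_ov) < 0))
  expect_gt(mean_ov[1], 25)    # identical distributions: high overlap
  expect_lt(mean_ov[4], 5)     # 4 sigma apart: nearly separable
})

test_that("rank-sum selectivity behaves at the extremes and under the null", {
  x <- rnorm(15)
  expect_false(statistical_selectivity(x, x, 0.001)$selective)
  # complete separation with ties: exact permutation p = 2/choose(30,15)
  s <- statistical_selectivity(rep(0, 15), rep(5, 15), 0.001)
  expect_true(s$selective)
  expect_lt(s$p.value, 0.001)
  expect_error(statistical_selectivity(numeric(0), x), "non-empty")
  # null calibration with continuous data (exact test, no ties)
  set.seed(9)
  rej <- mean(replicate(1000,
    statistical_selectivity(rnorm(15), rnorm(15), 0.05)$selective))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rej - 0.05), 4 * se)
})

test_that("selectivity and overlap agree in the extremes", {
  set.seed(10)
  a <- rnorm(20, 10, 0.5); b <- rnorm(20, 0, 0.5)
  expect_true(statistical_selectivity(a, b, 0.001)$selective)
  expect_identical(overlap(a, b)$overlap_percent, 0)
  c1 <- rnorm(20); c2 <- rnorm(20)
  expect_false(statistical_selectivity(c1, c2, 0.001)$selective)
  expect_gt(overlap(c1, c2)$overlap_percent, 20)
})

test_that("signatures have the right geometry and concentrate on true cells", {
  rec <- generate_recording(seed = 301)   # default 64-electrode world
  pat <- extract_patterns(rec$spikes, rec$stims)
  fr <- filter_report(pat)
  sig <- build_signatures(pat, fr, "bin_rate")
  expect_identical(dim(sig$flags), c(64L, 15L))
  expect_identical(dim(sig$overlaps), c(64L, 15L))
  defined <- !is.na(sig$overlaps)
  expect_true(all(sig$overlaps[defined] >= 0 & sig$overlaps[defined] <= 50))
  # flags only on stable bins of eligible electrodes
  expect_true(all(which(rowSums(defined) > 0) %in% fr$active))
  # recovery: most flagged cells are configured-selective cells
  truth <- rec$truth$selective_rate_cells
  tp <- sum(sig$flags & truth, na.rm = TRUE)
  expect_gt(tp / sum(sig$flags, na.rm = TRUE), 0.6)
  # whole-response signatures are per-electrode
  sigt <- build_signatures(pat, fr, "total_count")
  expect_identical(dim(sigt$overlaps), c(64L, 1L))
  siga <- build_signatures(pat, fr, "activation_time")
  expect_identical(dim(siga$flags), c(64L, 1L))
  # latency-selective electrodes are recovered by the activation feature
  expect_gt(sum(siga$flags[rec$truth$selective_latency_electrodes, 1],
                na.rm = TRUE), 6)
})

test_that("spatial overlap map arranges electrodes row-major on the grid", {
  geom <- array_geometry()
  sig <- list(overlaps = matrix(NA_real_, 64, 15), feature = "bin_rate")
  sig$overlaps[, 1] <- 30
  m <- spatial_overlap_map(sig, 1, geom)
  expect_identical(dim(m), c(8L, 8L))
  expect_true(all(m == 30))
  # electrode 10 is row 2, column 2 under row-major ids
  sig$overlaps[10, 1] <- 5
  expect_identical(spatial_overlap_map(sig, 1, geom)[2, 2], 5)
  expect_error(spatial_overlap_map(sig, 99, geom), "out of range")
})

test_that("low-overlap electrodes of a clustered subnetwork are spatially contiguous", {
  # selective electrodes 1..10 occupy rows 1-2 of the grid; the mean
  # nearest-neighbour distance among the 10 lowest-overlap electrodes
  # must beat the permutation null of random placement.
  rec <- generate_recording(model = default_response_model(
    selective_electrodes = 1:10), seed = 302)
  pat <- extract_patterns(rec$spikes, rec$stims)
  fr <- filter_report(pat)
  sig <- build_signatures(pat, fr, "total_count")
  ov <- sig$overlaps[, 1]
  k <- 10
  low <- order(ov)[seq_len(k)]
  pos <- electrode_positions(array_geometry())
  mean_nn <- function(ids) {
    d <- as.matrix(dist(pos[ids, c("row", "col")]))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  obs <- mean_nn(low)
  defined <- which(!is.na(ov))
  set.seed(11)
  null_d <- replicate(500, mean_nn(sample(defined, k)))
  # below the null expectation, and within the best decile of it
  expect_lt(obs, mean(null_d))
  expect_lte(obs, quantile(null_d, 0.1))
})
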