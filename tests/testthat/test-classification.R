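# Site decoding: the three classifiers against analytic oracles and
# constructed geometries, plus the electrode-exclusion curves.

test_that("well-separated classes are decoded perfectly by every method", {
  set.seed(41)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 8), 30))
  fm <- fm_from_matrix(X, rep(c("S1", "S2"), each = 30))
  expect_equal(kmeans_classify(fm, seed = 1)$accuracy, 100)
  expect_equal(kmeans_pc_classify(fm)$accuracy, 100)
  expect_equal(svc_classify(fm, seed = 1)$accuracy, 100)
})

test_that("classifiers validate their inputs", {
  fm <- fm_from_matrix(matrix(rnorm(10), 10), rep("S1", 10))
  expect_error(kmeans_classify(fm), "two site labels")
  fm2 <- fm_from_matrix(matrix(rnorm(12), 6),
                        c("S1", rep("S2", 5)))
  expect_error(svc_classify(fm2), "at least")
})

test_that("unsupervised k-means matches the midpoint-boundary oracle at d = 2 sigma", {
  # two 1-D Gaussians N(0,1), N(2,1): the k-means boundary converges to
  # the midpoint, so expected accuracy is Phi(1) ~ 84.1 %.
  set.seed(42)
  acc <- replicate(200, {
    x <- c(rnorm(30, 0), rnorm(30, 2))
    kmeans_classify(fm_from_matrix(x, rep(c("S1", "S2"), each = 30)),
                    seed = 1)$accuracy
  })
  expect_lt(abs(mean(acc) - 100 * pnorm(1)), 5)
})

test_that("matched k-means null accuracy equals the folded-binomial mean", {
  # identical feature distributions: after cluster-label matching the
  # accuracy is max(A, n-A)/n; for a noise split this concentrates at
  # the folded-binomial expectation, ~55 % for n = 60 (not 50).
  n <- 60
  folded <- 50 + 100 * sum(dbinom(0:n, n, 0.5) * abs(0:n / n - 0.5))
  set.seed(43)
  acc <- replicate(200, {
    x <- rnorm(n)
    kmeans_classify(fm_from_matrix(x, rep(c("S1", "S2"), each = 30)),
                    seed = 1)$accuracy
  })
  expect_lt(abs(mean(acc) - folded), 5)
})

test_that("kmeans_pc: no information gives chance on held-out data, separable gives 100", {
  set.seed(44)
  accs <- replicate(100, {
    X <- matrix(rnorm(60 * 5), 60)
    kmeans_pc_classify(fm_from_matrix(X, rep(c("S1", "S2"), each = 30)),
                       mode = "split", seed = 1)$accuracy
  })
  expect_lt(abs(mean(accs) - 50), 5)
  Xs <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 5, 0.3), 20))
  expect_equal(kmeans_pc_classify(
    fm_from_matrix(Xs, rep(c("S1", "S2"), each = 20)))$accuracy, 100)
})

test_that("kmeans_pc is at least as accurate as unsupervised k-means on moderate effects", {
  wins <- vapply(1:40, function(i) {
    rec <- generate_recording(model = small_model(), seed = 600 + i,
                              protocol = fast_protocol(),
                              geometry = small_geometry())
    pat <- extract_patterns(rec$spikes, rec$stims)
    fm <- feature_matrix(pat, "total_count")
    kmeans_pc_classify(fm)$accuracy >=
      kmeans_classify(fm, seed = i)$accuracy
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("the RBF SVM solves XOR geometry where linear methods are at chance", {
  set.seed(45)
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  X <- centers[rep(1:4, each = 15), ] + matrix(rnorm(120, 0, 0.05), 60)
  y <- rep(c("S1", "S1", "S2", "S2"), each = 15)
  fm <- fm_from_matrix(X, y)
  expect_gt(svc_classify(fm, seed = 2)$accuracy, 95)
  expect_lt(kmeans_pc_classify(fm)$accuracy, 65)
})

test_that("label permutation drives the cross-validated SVM to chance", {
  set.seed(46)
  acc <- replicate(30, {
    X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
    y <- sample(rep(c("S1", "S2"), each = 20))   # labels shuffled
    svc_classify(fm_from_matrix(X, y), seed = 3)$accuracy
  })
  expect_lt(abs(mean(acc) - 50), 7)
})

test_that("activation-time features impute silent electrodes with the window bound", {
  pat <- small_patterns(seed = 6, model = small_model(n_active = 4))
  fm <- feature_matrix(pat, "activation_time")
  expect_identical(fm$n_imputed, sum(is.na(pat$activation_ms)))
  expect_gt(fm$n_imputed, 0L)
  expect_true(all(fm$x[is.na(pat$activation_ms)] == 300))
  expect_false(any(!is.finite(fm$x)))
})

test_that("exclusion curve has n-1 points and honours the removal direction", {
  rec <- generate_recording(model = small_model(), seed = 7,
                            protocol = fast_protocol(),
                            geometry = small_geometry())
  pat <- extract_patterns(rec$spikes, rec$stims)
  ov <- c("1" = 40, "2" = 10, "3" = 30, "4" = 20, "5" = 5)
  curve <- electrode_exclusion_curve(pat, ov, "drop_lowest")
  expect_identical(nrow(curve), 4L)                       # 5 down to 2
  expect_identical(curve$n_electrodes, c(5L, 4L, 3L, 2L))
  expect_identical(curve$removed_electrode[-1], c(5L, 2L, 4L))
  curve_h <- electrode_exclusion_curve(pat, ov, "drop_highest")
  expect_identical(curve_h$removed_electrode[-1], c(1L, 3L, 4L))
  expect_error(electrode_exclusion_curve(pat, ov[1:2], "drop_lowest"),
               "at least 3")
})
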