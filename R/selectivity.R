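# Selectivity statistics: rank-sum statistical selectivity and the
# K-means misclassification "overlap".
#
# The overlap quantifies the DEGREE of selectivity of one electrode (or
# one electrode/time-bin cell): responses from both stimulation sites
# are pooled and split into two clusters by 2-means; clusters are then
# matched to the true site labels by the assignment that minimizes
# misclassification, and the overlap is the misclassified percentage
# 100 * N_c / n_total. It ranges from 0 % (perfectly separable response
# sets) to 50 % (chance; label matching makes larger values impossible).

# Exact optimal 2-means partition of scalar values: the optimal
# partition is a threshold split of the sorted values, found by
# scanning all n-1 splits with prefix sums. Deterministic and never
# worse than any Lloyd run.
kmeans2_scalar <- function(x) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  i <- seq_len(n - 1L)
  ss_left <- cs2[i] - cs[i]^2 / i
  ss_right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  tot <- ss_left + ss_right
  # only split between strictly different values (ties stay together)
  valid <- xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)  # degenerate: all values identical
  tot[!valid] <- Inf
  cut <- which.min(tot)
  cl <- integer(n)
  cl[o[seq_len(cut)]] <- 1L
  cl[o[(cut + 1L):n]] <- 2L
  list(cluster = cl, tot_withinss = tot[cut])
}

# Seeded k-means++ initialization + Lloyd iterations for k = 2 on rows
# of X; best of `nstart` restarts by within-cluster SS.
kmeans2_lloyd <- function(X, seed = 1L, nstart = 10L, iter_max = 100L) {
  n <- nrow(X)
  # degenerate: all rows identical
  if (all(abs(sweep(X, 2L, X[1L, ], `-`)) == 0)) return(NULL)
  with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      # k-means++ seeding
      c1 <- X[sample.int(n, 1L), , drop = FALSE]
      d2 <- rowSums(sweep(X, 2L, c1, `-`)^2)
      if (all(d2 == 0)) next  # seeded on a duplicated extreme; retry
      c2 <- X[sample.int(n, 1L, prob = d2), , drop = FALSE]
      centers <- rbind(c1, c2)
      cl <- integer(n)
      for (it in seq_len(iter_max)) {
        da <- rowSums(sweep(X, 2L, centers[1L, ], `-`)^2)
        db <- rowSums(sweep(X, 2L, centers[2L, ], `-`)^2)
        new_cl <- ifelse(da <= db, 1L, 2L)
        if (length(unique(new_cl)) < 2L) {
          far <- which.max(pmin(da, db))
          new_cl[far] <- 3L - new_cl[far]
        }
        if (identical(new_cl, cl)) break
        cl <- new_cl
        centers <- rbind(colMeans(X[cl == 1L, , drop = FALSE]),
                         colMeans(X[cl == 2L, , drop = FALSE]))
      }
      da <- rowSums(sweep(X, 2L, centers[1L, ], `-`)^2)
      db <- rowSums(sweep(X, 2L, centers[2L, ], `-`)^2)
      ss <- sum(ifelse(cl == 1L, da, db))
      if (is.null(best) || ss < best$tot_withinss)
        best <- list(cluster = cl, tot_withinss = ss)
    }
    best
  })
}

#' Statistical selectivity of two response sets
#'
#' Two-sided Mann-Whitney rank-sum test between the response feature
#' values evoked from two stimulation sites. An electrode (or time-bin
#' cell) is statistically selective when p < alpha; the conventional
#' levels are 0.001 for whole-response features per electrode and 0.05
#' for per-bin tests.
#'
#' @param values_a,values_b non-empty numeric samples.
#' @param alpha significance level (default 0.001).
#' @param method `"wilcox"` (default) or `"t"` (two-sample t test,
#'   provided for comparison only).
#' @return list with `selective` (logical) and `p.value`.
#' @export
statistical_selectivity <- function(values_a, values_b, alpha = 0.001,
                                    method = c("wilcox", "t")) {
  method <- match.arg(method)
  if (!length(values_a) || !length(values_b))
    stop_param("both samples must be non-empty")
  p <- if (method == "wilcox") {
    if (length(unique(c(values_a, values_b))) == 1L) 1.0
    else suppressWarnings(wilcox.test(values_a, values_b)$p.value)
  } else {
    if (stats::sd(c(values_a, values_b)) == 0) 1.0
    else stats::t.test(values_a, values_b)$p.value
  }
  list(selective = is.finite(p) && p < alpha, p.value = p)
}

#' Overlap between two response sets (K-means misclassification)
#'
#' Pools both sets, partitions the pooled responses into two clusters
#' (exact optimal 2-means for scalar values; seeded k-means++/Lloyd,
#' best of `nstart` restarts, for multivariate patterns with Euclidean
#' distance), matches clusters to the source sites by the assignment
#' minimizing misclassification, and reports the misclassified
#' percentage.
#'
#' @param values_a,values_b numeric vectors (scalar responses) or
#'   matrices (rows = patterns) from sites A and B; pooled size must be
#'   at least 4.
#' @param seed seed for the k-means++ restarts (multivariate case).
#' @param nstart number of restarts (default 10).
#' @return an object of class `overlap_result`: `overlap_percent` in
#'   the range 0--50; `n_a` (set-B patterns captured by cluster A'), `n_b`
#'   (set-A patterns captured by cluster B'), `n_c = n_a + n_b`,
#'   `n_total`, `degenerate` (TRUE when all pooled values are identical,
#'   in which case the overlap is the chance level 50), and the cluster
#'   assignment.
#' @examples
#' overlap(c(10, 11, 12, 13), c(1, 2, 2, 3))$overlap_percent  # 0
#' @export
overlap <- function(values_a, values_b, seed = 1L, nstart = 10L) {
  a_mat <- is.matrix(values_a) || is.matrix(values_b)
  if (a_mat) {
    values_a <- as.matrix(values_a); values_b <- as.matrix(values_b)
    if (ncol(values_a) != ncol(values_b))
      stop_param("pattern dimensions differ between sets")
    pooled <- rbind(values_a, values_b)
    na <- nrow(values_a); nb <- nrow(values_b)
  } else {
    pooled <- c(values_a, values_b)
    na <- length(values_a); nb <- length(values_b)
  }
  n <- na + nb
  if (na < 1L || nb < 1L || n < 4L)
    stop_param("need at least 4 pooled responses with both sets non-empty")
  if (any(!is.finite(pooled))) stop_param("non-finite response values")
  km <- if (a_mat) {
    if (ncol(pooled) == 1L) kmeans2_scalar(pooled[, 1L])
    else kmeans2_lloyd(pooled, seed = seed, nstart = nstart)
  } else kmeans2_scalar(pooled)
  src <- rep(c("A", "B"), c(na, nb))
  if (is.null(km)) {
    res <- list(overlap_percent = 50, n_a = NA_integer_, n_b = NA_integer_,
                n_c = NA_integer_, n_total = n, degenerate = TRUE,
                cluster = rep(1L, n))
    class(res) <- "overlap_result"
    return(res)
  }
  cl <- km$cluster
  # assignment 1: cluster 1 is A'; assignment 2: cluster 2 is A'.
  mis1 <- sum(cl == 1L & src == "B") + sum(cl == 2L & src == "A")
  mis2 <- sum(cl == 2L & src == "B") + sum(cl == 1L & src == "A")
  if (mis1 <= mis2) {  # ties break toward cluster 1 = A'
    n_a <- sum(cl == 1L & src == "B"); n_b <- sum(cl == 2L & src == "A")
  } else {
    n_a <- sum(cl == 2L & src == "B"); n_b <- sum(cl == 1L & src == "A")
  }
  res <- list(overlap_percent = 100 * (n_a + n_b) / n,
              n_a = n_a, n_b = n_b, n_c = n_a + n_b, n_total = n,
              degenerate = FALSE, cluster = cl)
  class(res) <- "overlap_result"
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: %.2f %% (%s of %d responses misassigned%s)\n",
              x$overlap_percent,
              if (x$degenerate) "degenerate; chance" else x$n_c,
              x$n_total,
              if (x$degenerate) "; all values identical" else ""))
  invisible(x)
}

#' Statistical-selectivity and overlap signatures
#'
#' Builds the electrodes x bins signatures for the spike-rate-pattern
#' feature, or the per-electrode signatures for whole-response features
#' (activation time, total spike count). For the per-bin feature every
#' (active and stationary electrode, stable bin) cell is tested with the
#' rank-sum test (alpha = 0.05) and characterized by its overlap;
#' zero-count responses ARE part of the samples (an active electrode's
#' silence in a bin is informative). For whole-response features one
#' value per electrode is computed at alpha = 0.001; missing activation
#' times (no retained spike on that stimulus) are dropped from the two
#' samples.
#'
#' @param patterns a [extract_patterns()] result with exactly two sites.
#' @param filters a [filter_report()]; defaults to computing one.
#' @param feature `"bin_rate"` (default), `"activation_time"` or
#'   `"total_count"`.
#' @param alpha per-bin significance level (default 0.05).
#' @param alpha_whole whole-response significance level (default 0.001).
#' @param seed seed forwarded to [overlap()].
#' @param method test passed to [statistical_selectivity()].
#' @return an object of class `mea_signatures`: matrices `flags`,
#'   `p` and `overlaps` (electrodes x bins; electrodes x 1 for
#'   whole-response features) with NA for not-applicable cells, plus the
#'   feature name, alpha and the eligible electrode set.
#' @export
build_signatures <- function(patterns, filters = filter_report(patterns),
                             feature = c("bin_rate", "activation_time",
                                         "total_count"),
                             alpha = 0.05, alpha_whole = 0.001, seed = 1L,
                             method = "wilcox") {
  feature <- match.arg(feature)
  sites <- sort(unique(patterns$site))
  if (length(sites) != 2L)
    stop_param("signatures are defined for exactly two stimulation sites")
  ra <- patterns$site == sites[1L]; rb <- patterns$site == sites[2L]
  ne <- dim(patterns$counts)[2L]; nb <- dim(patterns$counts)[3L]
  eligible <- filters$stationary
  if (feature == "bin_rate") {
    flags <- p <- ov <- matrix(NA_real_, ne, nb)
    n_cells <- 0L
    for (e in eligible) {
      bins <- filters$stable_bins[[as.character(e)]]
      for (b in bins) {
        va <- patterns$counts[ra, e, b]; vb <- patterns$counts[rb, e, b]
        st <- statistical_selectivity(va, vb, alpha, method)
        flags[e, b] <- as.numeric(st$selective)
        p[e, b] <- st$p.value
        ov[e, b] <- overlap(va, vb, seed = sub_seed(seed, e * nb + b))$overlap_percent
        n_cells <- n_cells + 1L
      }
    }
    alpha_used <- alpha
  } else {
    flags <- p <- ov <- matrix(NA_real_, ne, 1L)
    n_cells <- 0L
    vals <- if (feature == "activation_time") patterns$activation_ms
            else patterns$total
    for (e in eligible) {
      va <- vals[ra, e]; vb <- vals[rb, e]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) < 2L || length(vb) < 2L) next
      st <- statistical_selectivity(va, vb, alpha_whole, method)
      flags[e, 1L] <- as.numeric(st$selective)
      p[e, 1L] <- st$p.value
      ov[e, 1L] <- overlap(va, vb, seed = sub_seed(seed, e))$overlap_percent
      n_cells <- n_cells + 1L
    }
    alpha_used <- alpha_whole
  }
  if (n_cells == 0L)
    warning("no eligible electrode/bin cells; signatures are empty")
  structure(list(flags = flags == 1, p = p, overlaps = ov,
                 feature = feature, alpha = alpha_used,
                 electrodes = eligible, test = method,
                 n_cells = n_cells),
            class = "mea_signatures")
}

#' @export
print.mea_signatures <- function(x, ...) {
  cat(sprintf("Signatures (%s, %s test, alpha = %g): %d cells on %d electrodes\n",
              x$feature, x$test, x$alpha, x$n_cells, length(x$electrodes)))
  if (x$n_cells > 0) {
    cat(sprintf("  statistically selective cells: %d (%.1f %%)\n",
                sum(x$flags, na.rm = TRUE),
                100 * mean(x$flags, na.rm = TRUE)))
    cat(sprintf("  overlap: median %.1f %%, min %.1f %%\n",
                stats::median(x$overlaps, na.rm = TRUE),
                min(x$overlaps, na.rm = TRUE)))
  }
  invisible(x)
}

#' Arrange an overlap signature on the electrode grid
#'
#' @param signature a [build_signatures()] result.
#' @param bin time-bin index for per-bin signatures (ignored, and may be
#'   NULL, for whole-response signatures).
#' @param geometry an [array_geometry()].
#' @return a `n_rows x n_cols` matrix of overlap percentages; NA marks
#'   not-applicable electrodes.
#' @export
spatial_overlap_map <- function(signature, bin = 1L,
                                geometry = array_geometry()) {
  vals <- if (ncol(signature$overlaps) == 1L) signature$overlaps[, 1L]
          else {
            if (is.null(bin) || bin < 1L || bin > ncol(signature$overlaps))
              stop_param("bin index out of range")
            signature$overlaps[, bin]
          }
  ne <- n_electrodes(geometry)
  if (length(vals) != ne)
    stop_param("signature electrode count does not match geometry")
  matrix(vals, geometry$n_rows, geometry$n_cols, byrow = TRUE)
}
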