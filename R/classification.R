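# Stimulus-site decoding from population response patterns.
#
# Three methods of increasing supervision: unsupervised 2-means over all
# patterns with clusters matched to the site labels by maximum
# agreement; nearest class centroid ("K-means with predefined
# centroids"), where each site's centroid is the mean of its responses;
# and a supervised RBF-kernel support-vector machine with nested
# fivefold cross-validation. Accuracies are percentages of correctly
# assigned patterns.

#' Build a feature matrix from response patterns
#'
#' One row per stimulus. Feature choices: `"activation_time"`
#' (per-electrode first-spike latency; electrodes silent on a stimulus
#' are imputed with the window upper bound, "no response" being
#' informatively late), `"total_count"` (per-electrode total spike
#' count), `"first_bin"` (spike rate of the first 20 ms bin per
#' electrode), `"full"` (the flattened electrodes x bins spike-rate
#' pattern).
#'
#' @param patterns a [extract_patterns()] result.
#' @param feature feature type (see above).
#' @param electrodes electrode subset (default all electrodes; pass the
#'   active set to mirror the filtered analysis).
#' @return an object of class `feature_matrix`: numeric matrix `x`,
#'   factor `y` of site labels, feature name, electrode ids and the
#'   number of imputed activation times.
#' @export
feature_matrix <- function(patterns,
                           feature = c("activation_time", "total_count",
                                       "first_bin", "full"),
                           electrodes = NULL) {
  feature <- match.arg(feature)
  ne <- dim(patterns$counts)[2L]
  electrodes <- electrodes %||% seq_len(ne)
  n_imputed <- 0L
  x <- switch(feature,
    activation_time = {
      m <- patterns$activation_ms[, electrodes, drop = FALSE]
      n_imputed <- sum(is.na(m))
      m[is.na(m)] <- patterns$window$response_window_ms
      m
    },
    total_count = patterns$total[, electrodes, drop = FALSE] * 1.0,
    first_bin = patterns$counts[, electrodes, 1L, drop = TRUE] * 1.0,
    full = {
      d <- dim(patterns$counts)
      m <- patterns$counts[, electrodes, , drop = FALSE]
      matrix(m, d[1L], length(electrodes) * d[3L])
    })
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop_param("non-finite features after imputation")
  structure(list(x = x, y = factor(patterns$site), feature = feature,
                 electrodes = electrodes, n_imputed = n_imputed),
            class = "feature_matrix")
}

check_two_classes <- function(y, min_per_class = 2L) {
  tab <- table(y)
  if (length(tab) != 2L)
    stop_param("exactly two site labels required, got: ",
               paste(names(tab), collapse = ", "))
  if (any(tab < min_per_class))
    stop_param("each site needs at least ", min_per_class, " patterns")
  invisible(tab)
}

new_report <- function(method, feature, correct, total, extra = list()) {
  structure(c(list(method = method, feature = feature,
                   accuracy = 100 * correct / total,
                   correct = correct, total = total), extra),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s on %s features: accuracy %.2f %% (%d/%d)\n",
              x$method, x$feature, x$accuracy, x$correct, x$total))
  if (!is.null(x$fold_accuracy))
    cat("  per-fold accuracy (%):",
        paste(sprintf("%.1f", x$fold_accuracy), collapse = ", "), "\n")
  if (!is.null(x$mode)) cat("  mode:", x$mode, "\n")
  invisible(x)
}

#' Unsupervised K-means site classification
#'
#' Clusters all patterns into two groups (seeded k-means++/Lloyd, best
#' of `nstart` restarts, Euclidean distance on the raw features) and
#' matches the clusters to the site labels by maximum agreement. The
#' matched fraction is the classification accuracy; matching makes it
#' at least 50 % by construction.
#'
#' @param fm a [feature_matrix()].
#' @param seed,nstart clustering seed and restarts.
#' @return a `classification_report`.
#' @export
kmeans_classify <- function(fm, seed = 1L, nstart = 10L) {
  check_two_classes(fm$y)
  n <- nrow(fm$x)
  km <- if (ncol(fm$x) == 1L) kmeans2_scalar(fm$x[, 1L])
        else kmeans2_lloyd(fm$x, seed = seed, nstart = nstart)
  if (is.null(km)) {  # degenerate features: chance
    cl <- rep(1L, n)
  } else cl <- km$cluster
  lev <- levels(fm$y)
  agree1 <- sum((cl == 1L) == (fm$y == lev[1L]))
  correct <- max(agree1, n - agree1)
  conf <- table(cluster = cl, site = fm$y)
  new_report("kmeans", fm$feature, correct, n,
             list(confusion = conf, cluster = cl))
}

#' Nearest-class-centroid classification (K-means with predefined centroids)
#'
#' Each site's centroid is the mean of that site's response patterns;
#' every pattern is assigned to the nearest centroid by Euclidean
#' distance. `mode = "resubstitution"` (default) computes centroids from
#' all patterns, exactly as the procedure is usually described; note
#' that this is optimistically biased on high-dimensional features
#' because each pattern contributes to its own class centroid.
#' `mode = "split"` computes centroids on a random half of each class
#' and scores only the held-out half.
#'
#' @param fm a [feature_matrix()].
#' @param mode `"resubstitution"` or `"split"`.
#' @param seed seed for the split.
#' @return a `classification_report` (field `mode` records the variant).
#' @export
kmeans_pc_classify <- function(fm, mode = c("resubstitution", "split"),
                               seed = 1L) {
  mode <- match.arg(mode)
  check_two_classes(fm$y)
  lev <- levels(fm$y)
  if (mode == "resubstitution") {
    train <- test <- seq_len(nrow(fm$x))
  } else {
    train <- with_local_seed(seed, {
      unlist(lapply(lev, function(l) {
        i <- which(fm$y == l); sample(i, floor(length(i) / 2))
      }))
    })
    test <- setdiff(seq_len(nrow(fm$x)), train)
  }
  cen <- rbind(colMeans(fm$x[intersect(train, which(fm$y == lev[1L])), ,
                             drop = FALSE]),
               colMeans(fm$x[intersect(train, which(fm$y == lev[2L])), ,
                             drop = FALSE]))
  d1 <- rowSums(sweep(fm$x[test, , drop = FALSE], 2L, cen[1L, ], `-`)^2)
  d2 <- rowSums(sweep(fm$x[test, , drop = FALSE], 2L, cen[2L, ], `-`)^2)
  pred <- ifelse(d1 <= d2, lev[1L], lev[2L])
  correct <- sum(pred == fm$y[test])
  new_report("kmeans_pc", fm$feature, correct, length(test),
             list(mode = mode,
                  confusion = table(pred = pred, site = fm$y[test])))
}

# ---- RBF support-vector machine (SMO) ------------------------------------

rbf_kernel <- function(X, Y = X, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * X %*% t(Y)
  exp(-gamma * pmax(d2, 0))
}

svm_train <- function(X, y01, gamma, cost) {
  K <- rbf_kernel(X, gamma = gamma)
  y <- ifelse(y01 == 1L, 1, -1)
  fit <- .cpp_smo_train(K, y, cost)
  list(X = X, y = y, alpha = fit$alpha, b = fit$b, gamma = gamma)
}

svm_predict <- function(fit, Xnew) {
  K <- rbf_kernel(Xnew, fit$X, fit$gamma)
  f <- K %*% (fit$alpha * fit$y) + fit$b
  as.integer(f >= 0)
}

stratified_folds <- function(y, folds, seed) {
  with_local_seed(seed, {
    f <- integer(length(y))
    for (l in levels(y)) {
      i <- sample(which(y == l))
      f[i] <- rep_len(seq_len(folds), length(i))
    }
    f
  })
}

# Median-heuristic RBF widths: gamma = 1/(2 s^2) with s the median
# pairwise distance, scaled by `factors`.
gamma_grid <- function(X, factors = c(0.1, 1, 10)) {
  d <- stats::median(dist(X))
  if (!is.finite(d) || d <= 0) d <- 1
  1 / (2 * (d * factors)^2)
}

#' RBF support-vector classification with nested cross-validation
#'
#' Gaussian-kernel SVM decoding of the stimulation site. Features are
#' standardized per column using training-fold statistics. The kernel
#' width (median heuristic scaled by `gamma_factors`) and box constraint
#' `cost_grid` are selected by an inner fivefold cross-validation within
#' each outer training set; the reported accuracy is the outer
#' cross-validated fraction correct.
#'
#' @param fm a [feature_matrix()].
#' @param folds number of outer (and inner) folds, default 5; each class
#'   must have at least `folds` patterns.
#' @param seed seed for fold assignment.
#' @param cost_grid box-constraint grid (default 0.1, 1, 10, 100).
#' @param gamma_factors multipliers of the median-heuristic kernel width.
#' @return a `classification_report` with per-fold accuracies and the
#'   selected hyper-parameters.
#' @export
svc_classify <- function(fm, folds = 5L, seed = 1L,
                         cost_grid = c(0.1, 1, 10, 100),
                         gamma_factors = c(0.1, 1, 10)) {
  tab <- check_two_classes(fm$y, min_per_class = folds)
  y01 <- as.integer(fm$y == levels(fm$y)[1L])
  fold_id <- stratified_folds(fm$y, folds, sub_seed(seed, 1L))
  fold_acc <- numeric(folds)
  chosen <- vector("list", folds)
  correct <- 0L
  for (k in seq_len(folds)) {
    tr <- which(fold_id != k); te <- which(fold_id == k)
    mu <- colMeans(fm$x[tr, , drop = FALSE])
    sg <- apply(fm$x[tr, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    Xtr <- sweep(sweep(fm$x[tr, , drop = FALSE], 2L, mu), 2L, sg, `/`)
    Xte <- sweep(sweep(fm$x[te, , drop = FALSE], 2L, mu), 2L, sg, `/`)
    gg <- gamma_grid(Xtr, gamma_factors)
    inner_id <- stratified_folds(droplevels(fm$y[tr]), folds,
                                 sub_seed(seed, 100L + k))
    best <- NULL
    for (g in gg) for (C in cost_grid) {
      acc <- 0L
      for (j in seq_len(folds)) {
        itr <- which(inner_id != j); ite <- which(inner_id == j)
        if (length(unique(y01[tr][itr])) < 2L || !length(ite)) next
        fit <- svm_train(Xtr[itr, , drop = FALSE], y01[tr][itr], g, C)
        acc <- acc + sum(svm_predict(fit, Xtr[ite, , drop = FALSE]) ==
                           y01[tr][ite])
      }
      if (is.null(best) || acc > best$acc)
        best <- list(acc = acc, gamma = g, cost = C)
    }
    fit <- svm_train(Xtr, y01[tr], best$gamma, best$cost)
    pred <- svm_predict(fit, Xte)
    fold_acc[k] <- 100 * mean(pred == y01[te])
    correct <- correct + sum(pred == y01[te])
    chosen[[k]] <- c(gamma = best$gamma, cost = best$cost)
  }
  new_report("svc", fm$feature, correct, length(y01),
             list(fold_accuracy = fold_acc, folds = folds,
                  hyperparameters = do.call(rbind, chosen)))
}

#' Decode the site with all three classifiers
#'
#' @param fm a [feature_matrix()].
#' @param seed master seed.
#' @param ... forwarded to [svc_classify()].
#' @return named list of `classification_report`s
#'   (`kmeans`, `kmeans_pc`, `svc`).
#' @export
classify_all <- function(fm, seed = 1L, ...) {
  list(kmeans = kmeans_classify(fm, seed = sub_seed(seed, 1L)),
       kmeans_pc = kmeans_pc_classify(fm),
       svc = svc_classify(fm, seed = sub_seed(seed, 2L), ...))
}

#' Electrode-exclusion accuracy curve
#'
#' Starting from a set of electrodes with known per-electrode overlaps,
#' iteratively removes the electrode with the lowest (direction
#' `"drop_lowest"`, i.e. most selective first) or highest
#' (`"drop_highest"`) overlap and recomputes the nearest-centroid
#' (K-means p.c., total-spike-count feature) decoding accuracy after
#' each removal, down to 2 electrodes.
#'
#' @param patterns a [extract_patterns()] result.
#' @param overlaps named numeric vector of per-electrode overlap
#'   percentages (names = electrode ids), e.g. from a total-count
#'   signature.
#' @param direction `"drop_lowest"` or `"drop_highest"`.
#' @param mode forwarded to [kmeans_pc_classify()].
#' @param seed seed for the split mode.
#' @return data.frame with one row per evaluation: `n_electrodes`,
#'   `accuracy`, `removed_electrode` (NA for the initial full set).
#' @export
electrode_exclusion_curve <- function(patterns, overlaps,
                                      direction = c("drop_lowest",
                                                    "drop_highest"),
                                      mode = "resubstitution", seed = 1L) {
  direction <- match.arg(direction)
  el <- as.integer(names(overlaps))
  if (!length(el) || anyNA(el))
    stop_param("overlaps must be named by electrode id")
  if (length(el) < 3L) stop_param("need at least 3 electrodes to start")
  acc_for <- function(keep) {
    fm <- feature_matrix(patterns, "total_count", electrodes = keep)
    kmeans_pc_classify(fm, mode = mode, seed = seed)$accuracy
  }
  res <- data.frame(n_electrodes = length(el), accuracy = acc_for(el),
                    removed_electrode = NA_integer_)
  ov <- overlaps
  while (length(el) > 2L) {
    pick <- if (direction == "drop_lowest") which.min(ov) else which.max(ov)
    removed <- el[pick]
    el <- el[-pick]; ov <- ov[-pick]
    res <- rbind(res, data.frame(n_electrodes = length(el),
                                 accuracy = acc_for(el),
                                 removed_electrode = removed))
  }
  res
}
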