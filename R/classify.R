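#' Random forest hyperparameters
#'
#' The three tuned dimensions are the number of trees, the maximum tree
#' depth, and the random state.  The random state is both a grid dimension
#' and the forest's RNG seed — intentionally faithful to the evaluation
#' protocol this package mirrors, even though treating a seed as a tunable
#' is statistically unusual.  Depth is enforced through the maximum number
#' of terminal nodes (`2^max_depth`).
#'
#' @param n_estimators number of trees (>= 1).
#' @param max_depth maximum tree depth (>= 1).
#' @param random_state integer seed.
#' @return object of class `rf_hyperparams`.
#' @export
rf_hyperparams <- function(n_estimators, max_depth, random_state) {
  if (n_estimators < 1L || max_depth < 1L)
    stop("rf_hyperparams: n_estimators and max_depth must be >= 1")
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 random_state = as.integer(random_state)),
            class = "rf_hyperparams")
}

#' The six-setting default hyperparameter grid
#' @return list of [rf_hyperparams()].
#' @export
default_rf_grid <- function() {
  list(rf_hyperparams(10, 2, 10), rf_hyperparams(25, 3, 30),
       rf_hyperparams(15, 4, 65), rf_hyperparams(22, 5, 80),
       rf_hyperparams(22, 6, 80), rf_hyperparams(22, 6, 90))
}

rf_fit <- function(X, y, hp, seed_offset = 0L) {
  set.seed(hp$random_state * 1000L + seed_offset)
  # depth enforced through terminal-node count; a tree cannot carry more
  # leaves than training cases, so cap there
  randomForest::randomForest(x = as.data.frame(X), y = factor(y, levels = 0:1),
                             ntree = hp$n_estimators,
                             maxnodes = min(2L^hp$max_depth, nrow(X)))
}

rf_score <- function(fit, X) {
  unname(stats::predict(fit, as.data.frame(X), type = "prob")[, "1"])
}

#' Cohen's kappa for binary predictions
#' @param pred,y aligned 0/1 vectors.
#' @return kappa in \[-1, 1\]; degenerate marginals (chance agreement 1)
#'   return 0 with a warning.
#' @export
cohen_kappa <- function(pred, y) {
  stopifnot(length(pred) == length(y))
  n <- length(y)
  po <- mean(pred == y)
  pe <- sum(vapply(unique(c(pred, y)), function(k)
    mean(pred == k) * mean(y == k), 0))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("cohen_kappa: degenerate marginals; returning 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Case-resampled bootstrap summary of a cross-validated accuracy
#'
#' A single LOOCV pass yields one prediction per case; the accuracy
#' distribution is obtained by resampling the case-level (prediction,
#' label) pairs with replacement.
#'
#' @param pred,y aligned 0/1 vectors.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed RNG seed for resampling.
#' @return list with `median`, `iqr_low`, `iqr_high` (25th/75th
#'   percentiles), `boot_acc` (the replicate accuracies) and
#'   `boot_kappa`.
#' @export
accuracy_summary <- function(pred, y, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L) stop("accuracy_summary: n_boot must be >= 100")
  set.seed(seed)
  n <- length(y)
  acc <- numeric(n_boot); kap <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    acc[b] <- mean(pred[idx] == y[idx])
    kap[b] <- suppressWarnings(cohen_kappa(pred[idx], y[idx]))
  }
  qs <- stats::quantile(acc, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = qs[2], iqr_low = qs[1], iqr_high = qs[3],
       boot_acc = acc, boot_kappa = kap)
}

#' Two-sample t-test between two bootstrap accuracy distributions
#' @param boot_a,boot_b bootstrap accuracy vectors from
#'   [accuracy_summary()].
#' @return list with `t` and two-tailed `p`.
#' @export
paired_accuracy_ttest <- function(boot_a, boot_b) {
  if (stats::sd(boot_a) < 1e-12 && stats::sd(boot_b) < 1e-12) {
    # both distributions degenerate (e.g. every replicate at accuracy 1)
    d <- mean(boot_a) - mean(boot_b)
    if (abs(d) < 1e-12) return(list(t = 0, p = 1))
    return(list(t = sign(d) * Inf, p = 0))
  }
  tt <- stats::t.test(boot_a, boot_b, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Precision-recall curve and average precision
#'
#' Step-wise interpolated AP: `sum((R_k - R_{k-1}) * P_k)` over
#' descending-score thresholds.
#'
#' @param scores real-valued classifier scores (higher = more positive).
#' @param y binary labels.
#' @return list with `precision`, `recall`, `thresholds`, `ap`.
#' @export
pr_curve_ap <- function(scores, y) {
  if (length(unique(y)) < 2L) stop("pr_curve_ap: need both classes")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  # evaluate at the last index of each distinct score (threshold = score)
  last <- which(!duplicated(ss, fromLast = TRUE))
  P <- tp[last] / (tp[last] + fp[last])
  R <- tp[last] / sum(ys)
  ap <- sum(diff(c(0, R)) * P)
  list(precision = P, recall = R, thresholds = ss[last], ap = ap)
}

#' Per-feature two-sided Wilcoxon rank-sum tests
#'
#' Exact null when both groups have <= 10 cases and no ties; normal
#' approximation with tie correction otherwise.  Raw p-values by default;
#' `adjust = "BH"` applies Benjamini-Hochberg.
#'
#' @param X cases x features matrix.
#' @param y binary group labels (>= 2 cases per group).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with feature, statistic (W), p.
#' @export
per_feature_wilcoxon <- function(X, y, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  g1 <- y == sort(unique(y))[1]
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop("per_feature_wilcoxon: need >= 2 cases per group")
  res <- apply(X, 2, function(col) {
    if (stats::sd(col) == 0) {
      warning("per_feature_wilcoxon: constant column; p = 1")
      return(c(W = NA_real_, p = 1))
    }
    a <- col[g1]; b <- col[!g1]
    exact <- length(a) <= 10 && length(b) <= 10 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    c(W = unname(wt$statistic), p = wt$p.value)
  })
  p <- res["p", ]
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  data.frame(feature = colnames(X, do.NULL = FALSE), W = res["W", ], p = p,
             row.names = NULL)
}

#' Leave-one-out cross-validated random forest
#'
#' For each case, a forest is fitted on all other cases and the held-out
#' case is scored (forest vote fraction for the malignant class).
#' Accuracy is summarised by a case-level bootstrap (median and IQR), and
#' Cohen's kappa by the mean and standard deviation over the same
#' replicates.
#'
#' @param X cases x features matrix.
#' @param y binary labels (0 = benign, 1 = malignant), >= 2 per class.
#' @param hp an [rf_hyperparams()].
#' @param n_boot bootstrap replicates for the accuracy summary.
#' @param feature_set tag recorded in the result (`"conv"`, `"deep"`,
#'   `"conv+deep"` or free-form).
#' @return object of class `cv_result`.
#' @export
loocv_rf <- function(X, y, hp, n_boot = 1000L, feature_set = "features") {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L)
    stop("loocv_rf: need both classes present")
  if (min(table(y)) < 2L) stop("loocv_rf: need >= 2 cases per class")
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- rf_fit(X[-i, , drop = FALSE], y[-i], hp, seed_offset = i)
    scores[i] <- rf_score(fit, X[i, , drop = FALSE])
  }
  finalize_cv_result(scores, y, hp, n_boot, feature_set)
}

finalize_cv_result <- function(scores, y, hp, n_boot, feature_set) {
  pred <- as.integer(scores >= 0.5)
  summ <- accuracy_summary(pred, y, n_boot = n_boot,
                           seed = hp$random_state + 7919L)
  ap <- pr_curve_ap(scores, y)$ap
  structure(list(pred = pred, scores = scores, y = y, hp = hp,
                 feature_set = feature_set,
                 accuracy_median = summ$median,
                 accuracy_iqr_low = summ$iqr_low,
                 accuracy_iqr_high = summ$iqr_high,
                 kappa_mean = mean(summ$boot_kappa),
                 kappa_std = stats::sd(summ$boot_kappa),
                 average_precision = ap,
                 boot_acc = summ$boot_acc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV random forest [%s]  trees=%d depth=%d state=%d\n",
    x$feature_set, x$hp$n_estimators, x$hp$max_depth, x$hp$random_state))
  cat(sprintf("  accuracy %.1f%% (%.1f-%.1f)  kappa %.1f%% (+/- %.1f)  AP %.1f%%\n",
              100 * x$accuracy_median, 100 * x$accuracy_iqr_low,
              100 * x$accuracy_iqr_high, 100 * x$kappa_mean,
              100 * x$kappa_std, 100 * x$average_precision))
  invisible(x)
}

#' Evaluate a hyperparameter grid on the three radiomic feature sets
#'
#' Runs [loocv_rf()] for every grid setting on the conventional embedding,
#' the deep latent features, and their concatenation.  Each non-reference
#' row is compared with the maximal-accuracy row by a two-sample t-test on
#' the bootstrap accuracy distributions.
#'
#' @param X_conv cases x 12 conventional (embedded) features.
#' @param X_deep cases x 4 deep latent features.
#' @param y binary labels, aligned with both matrices.
#' @param grid list of [rf_hyperparams()]; defaults to [default_rf_grid()].
#' @param n_boot bootstrap replicates per cell.
#' @return data.frame with one row per (setting, feature set) and the full
#'   metric panel; the `cv` attribute carries the `cv_result` objects.
#' @export
grid_evaluate <- function(X_conv, X_deep, y, grid = default_rf_grid(),
                          n_boot = 1000L) {
  if (nrow(X_conv) != nrow(X_deep) || nrow(X_conv) != length(y))
    stop("grid_evaluate: misaligned rows between feature sets and labels")
  sets <- list(conv = X_conv, deep = X_deep,
               `conv+deep` = cbind(X_conv, X_deep))
  cvs <- list()
  rows <- list()
  for (hp in grid) for (fs in names(sets)) {
    cv <- loocv_rf(sets[[fs]], y, hp, n_boot = n_boot, feature_set = fs)
    cvs[[length(cvs) + 1L]] <- cv
    rows[[length(rows) + 1L]] <- data.frame(
      n_estimators = hp$n_estimators, max_depth = hp$max_depth,
      random_state = hp$random_state, feature_set = fs,
      accuracy_median = cv$accuracy_median,
      accuracy_iqr_low = cv$accuracy_iqr_low,
      accuracy_iqr_high = cv$accuracy_iqr_high,
      kappa_mean = cv$kappa_mean, kappa_std = cv$kappa_std,
      average_precision = cv$average_precision,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  best <- which.max(tab$accuracy_median)
  tab$t_vs_max <- NA_real_; tab$p_vs_max <- NA_real_
  for (r in seq_len(nrow(tab))) {
    if (r == best) next
    tt <- paired_accuracy_ttest(cvs[[r]]$boot_acc, cvs[[best]]$boot_acc)
    tab$t_vs_max[r] <- tt$t; tab$p_vs_max[r] <- tt$p
  }
  attr(tab, "cv") <- cvs
  tab
}

#' K-fold grid search for random forest hyperparameters
#'
#' @param X cases x features matrix.
#' @param y binary labels.
#' @param grid list of [rf_hyperparams()].
#' @param k number of folds (k <= n).
#' @param seed fold-assignment seed.
#' @return the winning [rf_hyperparams()] (highest mean fold accuracy;
#'   ties resolve to fewer trees, then shallower depth).
#' @export
kfold_grid_search <- function(X, y, grid = default_rf_grid(), k = 5L,
                              seed = 1L) {
  n <- nrow(X)
  if (k > n) stop("kfold_grid_search: k exceeds the number of cases")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  accs <- vapply(grid, function(hp) {
    mean(vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- rf_fit(X[tr, , drop = FALSE], y[tr], hp, seed_offset = f)
      mean((rf_score(fit, X[!tr, , drop = FALSE]) >= 0.5) == y[!tr])
    }, 0))
  }, 0)
  ne <- vapply(grid, `[[`, 0L, "n_estimators")
  md <- vapply(grid, `[[`, 0L, "max_depth")
  best <- order(-accs, ne, md)[1]
  grid[[best]]
}

#' Leakage-free end-to-end LOOCV through embedding and forest
#'
#' For each left-out case the spectral embedding (on the raw radiomic
#' matrix), the latent-feature filter and the forest are all fitted on the
#' remaining cases only; the held-out case is embedded by the Nystrom
#' extension and its latent columns selected by the training-fold filter.
#'
#' @param X_raw cases x p raw conventional radiomic matrix (e.g. 354-wide).
#' @param latent cases x latent_dim deep feature matrix (e.g. 16-wide).
#' @param y binary labels.
#' @param hp an [rf_hyperparams()].
#' @param n_components embedding width (12).
#' @param k_latent latent features to keep (4).
#' @param k_neighbors affinity neighbourhood.
#' @param n_boot bootstrap replicates for the summary.
#' @return a `cv_result` (feature set `"conv+deep"`).
#' @export
loocv_pipeline_rf <- function(X_raw, latent, y, hp = rf_hyperparams(22, 5, 80),
                              n_components = 12L, k_latent = 4L,
                              k_neighbors = 10L, n_boot = 1000L) {
  n <- nrow(X_raw)
  if (n != nrow(latent) || n != length(y))
    stop("loocv_pipeline_rf: misaligned inputs")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    emb <- spectral_embed(X_raw[-i, , drop = FALSE], n_components,
                          k_neighbors)
    conv_tr <- emb$embedding
    conv_te <- predict(emb, X_raw[i, , drop = FALSE])
    fl <- suppressWarnings(filter_latent(latent[-i, , drop = FALSE], k_latent))
    Xtr <- cbind(conv_tr, latent[-i, fl$indices, drop = FALSE])
    Xte <- cbind(conv_te, latent[i, fl$indices, drop = FALSE])
    fit <- rf_fit(Xtr, y[-i], hp, seed_offset = i)
    scores[i] <- rf_score(fit, Xte)
  }
  finalize_cv_result(scores, y, hp, n_boot, "conv+deep")
}
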