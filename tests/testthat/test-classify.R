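sep_gaussians <- function(n_per = 20L, gap = 3, p = 4L, seed = 7L) {
  set.seed(seed)
  list(X = rbind(matrix(rnorm(n_per * p, 0), n_per, p),
                 matrix(rnorm(n_per * p, gap), n_per, p)),
       y = rep(0:1, each = n_per))
}

test_that("LOOCV separates 3-sigma Gaussians and returns one score per case", {
  d <- sep_gaussians()
  for (hp in list(rf_hyperparams(10, 2, 10), rf_hyperparams(22, 5, 80))) {
    cv <- loocv_rf(d$X, d$y, hp, n_boot = 200L)
    expect_length(cv$pred, 40L)
    expect_gte(mean(cv$pred == d$y), 0.95)
    expect_true(cv$kappa_mean >= -1 && cv$kappa_mean <= 1)
    expect_true(cv$accuracy_iqr_low <= cv$accuracy_median &&
                  cv$accuracy_median <= cv$accuracy_iqr_high)
  }
  expect_error(loocv_rf(d$X, rep(0, 40), rf_hyperparams(5, 2, 1)), "classes")
})

test_that("label-permuted LOOCV accuracy sits in the binomial null band", {
  set.seed(31)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y <- sample(rep(0:1, 30))    # independent of X by construction
  cv <- loocv_rf(X, y, rf_hyperparams(15, 4, 65), n_boot = 200L)
  acc <- mean(cv$pred == y)
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("grid evaluation covers 6 settings x 3 feature sets", {
  d <- sep_gaussians(n_per = 15L, gap = 1.5, p = 12L, seed = 13L)
  set.seed(13)
  Xdeep <- d$X[, 1:4] + matrix(rnorm(30 * 4, sd = 0.5), 30, 4)
  tab <- grid_evaluate(d$X, Xdeep, d$y, n_boot = 200L)
  expect_identical(nrow(tab), 18L)
  expect_identical(sort(unique(tab$feature_set)),
                   sort(c("conv", "deep", "conv+deep")))
  expect_equal(sum(is.na(tab$t_vs_max)), 1L)  # reference row only

  # duplicated settings give identical rows (determinism)
  hp <- rf_hyperparams(10, 2, 10)
  tab2 <- grid_evaluate(d$X, Xdeep, d$y, grid = list(hp, hp), n_boot = 200L)
  metric_cols <- c("accuracy_median", "accuracy_iqr_low", "accuracy_iqr_high",
                   "kappa_mean", "kappa_std", "average_precision")
  expect_equal(tab2[tab2$feature_set == "conv", ][1, metric_cols],
               tab2[tab2$feature_set == "conv", ][2, metric_cols],
               ignore_attr = TRUE)
  expect_error(grid_evaluate(d$X[-1, ], Xdeep, d$y), "misaligned")
})

test_that("k-fold grid search prefers depth on XOR structure", {
  set.seed(5)
  n <- 120L
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(x1, x2))
  X <- cbind(x1 + rnorm(n, sd = 0.05), x2 + rnorm(n, sd = 0.05))
  grid <- list(rf_hyperparams(25, 1, 10), rf_hyperparams(25, 5, 10))
  best <- kfold_grid_search(X, y, grid, k = 5L, seed = 2L)
  expect_identical(best$max_depth, 5L)
  best2 <- kfold_grid_search(X, y, grid, k = 5L, seed = 2L)
  expect_identical(best, best2)
  one <- kfold_grid_search(X, y, list(rf_hyperparams(7, 3, 1)), seed = 1L)
  expect_identical(one$n_estimators, 7L)
  expect_error(kfold_grid_search(X[1:3, ], y[1:3], grid, k = 5L), "exceeds")
})

test_that("kappa follows the chance-corrected agreement formula", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(cohen_kappa(y, y), 1)
  expect_warning(k0 <- cohen_kappa(rep(1, 100), rep(1, 100)), "degenerate")
  expect_equal(k0, 0)
  expect_equal(cohen_kappa(rep(c(0, 1), 50), y), 0)
  # TP=40 TN=40 FP=10 FN=10: po = 0.8, pe = 0.5, kappa = 0.6
  truth <- rep(c(1, 0), each = 50)
  pred <- c(rep(1, 40), rep(0, 10), rep(0, 40), rep(1, 10))
  expect_equal(cohen_kappa(pred, truth), 0.6)
})

test_that("bootstrap accuracy summary and t-test behave sanely", {
  y <- rep(0:1, each = 20)
  s <- accuracy_summary(y, y, n_boot = 200L, seed = 1L)
  expect_equal(s$median, 1)
  expect_error(accuracy_summary(y, y, n_boot = 50L), "n_boot")
  set.seed(2)
  a <- rnorm(500, 0.8, 0.02); b <- rnorm(500, 0.7, 0.02)
  tt <- paired_accuracy_ttest(a, b)
  expect_gt(tt$t, 10)
  expect_lt(tt$p, 1e-10)
})

test_that("average precision matches exhaustive threshold enumeration", {
  expect_equal(pr_curve_ap(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0))$ap, 1)
  set.seed(11)
  scores <- 10:1                      # reversed ranking, 5 pos / 5 neg
  y <- c(rep(0, 5), rep(1, 5))
  expect_equal(pr_curve_ap(scores, y)$ap, oracle_ap(scores, y),
               tolerance = 1e-12)
  for (k in 1:5) {                    # randomized scores vs oracle
    sc <- runif(30); yy <- rbinom(30, 1, 0.4)
    if (length(unique(yy)) < 2) next
    expect_equal(pr_curve_ap(sc, yy)$ap, oracle_ap(sc, yy), tolerance = 1e-12)
  }
  # null scores: AP concentrates near prevalence
  set.seed(12)
  sc <- runif(2000); yy <- rbinom(2000, 1, 0.3)
  expect_lt(abs(pr_curve_ap(sc, yy)$ap - mean(yy)), 0.1)
  expect_error(pr_curve_ap(runif(5), rep(1, 5)), "both classes")
})

test_that("rank-sum tests give exact small-sample p-values", {
  w <- per_feature_wilcoxon(cbind(f = c(1, 2, 3, 10, 11, 12)),
                            c(0, 0, 0, 1, 1, 1))
  expect_equal(w$W, 0)
  expect_equal(w$p, 0.1)            # smallest achievable at n = 3 vs 3
  expect_warning(
    wc <- per_feature_wilcoxon(cbind(f = rep(1, 8)), rep(0:1, each = 4)),
    "constant")
  expect_equal(wc$p, 1)
})
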