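test_that("an informative feature outranks pure noise almost surely", {
  hits <- 0L
  for (seed in 1:100) {
    ds <- simulated_dataset(n = 60, p = 10, n_informative = 1, effect = 2,
                            seed = seed)
    rk <- rank_features(ds, subsample_fraction = 1, seed = seed)
    hits <- hits + (rk$feature[1] == "f01")
  }
  expect_gte(hits, 99)
})

test_that("ranking is invariant to per-feature affine rescaling", {
  ds <- simulated_dataset(n = 80, p = 8, n_informative = 3, seed = 4)
  ds2 <- ds
  ds2$x <- sweep(sweep(ds2$x, 2, c(2, 5, 0.1, 3, 7, 1, 9, 4), "*"),
                 2, seq_len(8), "+")
  r1 <- rank_features(ds, subsample_fraction = 1, seed = 2)
  r2 <- rank_features(ds2, subsample_fraction = 1, seed = 2)
  expect_identical(r1$feature, r2$feature)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("constant features get p = 1 and rank last", {
  ds <- simulated_dataset(n = 40, p = 5, n_informative = 1, seed = 3)
  ds$x[, 5] <- 2
  rk <- rank_features(ds, subsample_fraction = 1, seed = 1)
  expect_identical(rk$feature[5], "f05")
  expect_equal(rk$p_value[5], 1)
})

test_that("backward elimination bookkeeping holds for any step", {
  ds <- simulated_dataset(n = 60, p = 12, n_informative = 3, seed = 5)
  sp <- split_dataset(ds, 0.665, seed = 1)
  rk <- rank_features(ds, subsample_fraction = 1, seed = 1)
  tr <- backward_elimination(sp$train, sp$test, sp$test, rk, step = 5L)
  expect_identical(tr$n_features, c(12L, 7L, 2L, 1L))
  expect_true(all(tr$acc_internal >= 0 & tr$acc_internal <= 1))
  expect_true(all(diff(tr$n_features) < 0))
  tr1 <- backward_elimination(sp$train, sp$test, sp$test, rk, step = 1L)
  expect_identical(nrow(tr1), 12L)
})

test_that("the accuracy trace peaks near the informative feature set", {
  ds <- simulated_dataset(n = 250, p = 40, n_informative = 5, effect = 1.2,
                          seed = 11)
  sp <- split_dataset(ds, 0.665, seed = 2)
  ext <- simulated_dataset(n = 250, p = 40, n_informative = 5, effect = 1.2,
                           seed = 99)
  rk <- rank_features(ds, subsample_fraction = 1, seed = 3)
  tr <- backward_elimination(sp$train, sp$test, ext, rk)
  at5 <- tr$acc_external[tr$n_features == 5]
  expect_gte(at5, max(tr$acc_external) - 0.02)
})

test_that("the cubic fit finds the accuracy optimum", {
  k <- seq(40, 1, by = -1)
  parab <- 0.9 - 0.0004 * (k - 20)^2
  tr <- data.frame(n_features = k, acc_internal = parab,
                   acc_external = parab)
  opt <- fit_optimum(tr)
  expect_lte(abs(opt$n_features - 20), 1)
  # monotone increasing accuracy: optimum at the maximum observed count
  mono <- data.frame(n_features = k, acc_internal = NA,
                     acc_external = 0.5 + 0.005 * k)
  expect_equal(fit_optimum(mono)$n_features, 40)
  # short traces fall back to the empirical argmax
  short <- data.frame(n_features = 3:1, acc_internal = NA,
                      acc_external = c(0.7, 0.9, 0.6))
  os <- fit_optimum(short)
  expect_true(os$fallback)
  expect_identical(os$n_features, 2L)
})

test_that("the fitted optimum tolerates noise around a peak", {
  k <- seq(40, 1, by = -1)
  hit <- 0L
  for (seed in 1:100) {
    acc <- 0.9 - 0.0004 * (k - 18)^2 +
      melmark:::with_seed(seed, rnorm(length(k), 0, 0.01))
    tr <- data.frame(n_features = k, acc_internal = acc, acc_external = acc)
    if (abs(fit_optimum(tr)$n_features - 18) <= 3) hit <- hit + 1L
  }
  expect_gte(hit, 90)
})

test_that("per-feature AUC equals the pairwise-comparison oracle", {
  ds <- simulated_dataset(n = 100, p = 3, n_informative = 1, effect = 1,
                          seed = 21)
  roc <- per_feature_roc(ds)
  pos <- ds$y == "melanoma"
  for (f in colnames(ds$x)) {
    v <- ds$x[, f]
    wins <- 0
    for (i in which(pos)) {
      wins <- wins + sum(v[i] > v[!pos]) + 0.5 * sum(v[i] == v[!pos])
    }
    a <- wins / (sum(pos) * sum(!pos))
    expect_equal(roc$auc[roc$feature == f], max(a, 1 - a), tolerance = 1e-12)
  }
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  a_ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(ds$y, ds$x[, "f01"], quiet = TRUE,
                        levels = c("other", "melanoma"),
                        direction = "<"))))
  expect_equal(roc$auc[roc$feature == "f01"], max(a_ref, 1 - a_ref),
               tolerance = 1e-12)
})

test_that("separating and constant features hit the AUC anchors", {
  x <- cbind(sep = c(rep(1, 20), rep(0, 20)), cst = rep(2, 40))
  ds <- cell_dataset(x, rep(c("melanoma", "other"), each = 20))
  roc <- per_feature_roc(ds)
  expect_equal(roc$auc[roc$feature == "sep"], 1)
  expect_equal(roc$auc[roc$feature == "cst"], 0.5)
  expect_true(roc$constant[roc$feature == "cst"])
})
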