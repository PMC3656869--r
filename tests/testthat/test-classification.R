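toy_separable <- function(n = 40, seed = 1) {
  melmark:::with_seed(seed, {
    x <- cbind(a = c(rnorm(n, 3), rnorm(n, -3)), b = rnorm(2 * n))
    cell_dataset(x, rep(c("melanoma", "other"), each = n))
  })
}

test_that("all learners separate a trivially separable set", {
  ds <- toy_separable()
  for (alg in c("svm", "random_forest", "naive_bayes")) {
    model <- train_classifier(ds, alg, seed = 4)
    rep <- evaluate_classifier(model, ds)
    expect_equal(rep$accuracy, 1, info = alg)
    p <- predict_prob(model, ds)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(train_classifier(ds, "svm"), NA)
  bad <- cell_dataset(matrix(1, 10, 2, dimnames = list(NULL, c("a", "b"))),
                      rep(c("melanoma", "other"), 5))
  expect_error(train_classifier(bad, "svm"), "degenerate")
})

test_that("training and prediction are deterministic under a fixed seed", {
  ds <- simulated_dataset(n = 100, p = 6, n_informative = 2, seed = 8)
  probe <- simulated_dataset(n = 30, p = 6, n_informative = 2, seed = 9)
  for (alg in c("svm", "random_forest", "naive_bayes")) {
    m1 <- train_classifier(ds, alg, seed = 5)
    m2 <- train_classifier(ds, alg, seed = 5)
    expect_identical(predict_prob(m1, probe), predict_prob(m2, probe),
                     info = alg)
  }
})

test_that("prediction refuses mismatched feature sets", {
  ds <- toy_separable()
  model <- train_classifier(ds, "svm")
  wrong <- ds$x[, c("b", "a")]
  expect_error(predict_prob(model, wrong), "feature set")
})

test_that("evaluation metrics hit their closed forms", {
  ds <- toy_separable()
  model <- train_classifier(ds, "svm")
  rep <- evaluate_classifier(model, ds)
  expect_equal(rep$tp_rate, 1)
  expect_equal(rep$fp_rate, 0)
  expect_equal(rep$f_measure, 1)
  expect_equal(rep$roc_auc, 1)
  # an all-positive predictor on balanced data
  rep0 <- evaluate_classifier(model, ds, threshold = 0)
  expect_equal(rep0$tp_rate, 1)
  expect_equal(rep0$fp_rate, 1)
  expect_equal(rep0$precision, 0.5)
})

test_that("metrics are recomputable from the stored confusion matrix", {
  ds <- simulated_dataset(n = 80, p = 4, n_informative = 1, effect = 0.8,
                          seed = 14)
  model <- train_classifier(ds, "naive_bayes")
  rep <- evaluate_classifier(model, ds)
  cm <- rep$confusion
  tp <- cm["melanoma", "melanoma"]; fn <- cm["melanoma", "other"]
  fp <- cm["other", "melanoma"]; tn <- cm["other", "other"]
  expect_equal(rep$tp_rate, tp / (tp + fn))
  expect_equal(rep$fp_rate, fp / (fp + tn))
  expect_equal(rep$precision, tp / (tp + fp))
  expect_equal(rep$accuracy, (tp + tn) / sum(cm))
  f <- 2 * rep$precision * rep$recall / (rep$precision + rep$recall)
  expect_equal(rep$f_measure, f)
})

test_that("threshold sweep endpoints and AUC are consistent", {
  ds <- simulated_dataset(n = 150, p = 4, n_informative = 2, effect = 1,
                          seed = 6)
  model <- train_classifier(ds, "svm")
  sw <- threshold_sweep(model, ds, grid = c(0, seq(0.01, 0.99, 0.01), 1.01))
  expect_equal(unlist(sw$points[1, c("fp_rate", "tp_rate")]),
               c(fp_rate = 1, tp_rate = 1))
  last <- nrow(sw$points)
  expect_equal(unlist(sw$points[last, c("fp_rate", "tp_rate")]),
               c(fp_rate = 0, tp_rate = 0))
  # trapezoid over the dense sweep approximates the rank AUC
  pts <- sw$points[order(sw$points$fp_rate, sw$points$tp_rate), ]
  trap <- sum(diff(pts$fp_rate) * (head(pts$tp_rate, -1) + tail(pts$tp_rate, -1)) / 2)
  expect_lt(abs(trap - sw$auc), 1 / (2 * 150))
  # reversing the score orientation flips the AUC
  p <- predict_prob(model, ds)
  pos <- ds$y == "melanoma"
  expect_equal(auc_score(-p, pos), 1 - auc_score(p, pos), tolerance = 1e-12)
})

test_that("the learners reach benchmark accuracy on the separable benchmark", {
  train <- simulated_dataset(n = 2000, p = 10, n_informative = 5,
                             effect = 1.5, seed = 31)
  test <- simulated_dataset(n = 700, p = 10, n_informative = 5,
                            effect = 1.5, seed = 32)
  cmp <- compare_algorithms(train, test, test, seed = 3)
  s <- cmp$summary
  expect_gte(s$acc_internal[s$algorithm == "svm"], 0.95)
  expect_gte(s$acc_internal[s$algorithm == "random_forest"], 0.95)
  expect_gte(s$acc_internal[s$algorithm == "naive_bayes"], 0.85)
})

test_that("label permutation drives every learner to chance AUC", {
  # permuting the labels removes all feature-class association, in the
  # training and the held-out data alike
  ds <- simulated_dataset(n = 600, p = 10, n_informative = 5, effect = 1.5,
                          seed = 41)
  test <- simulated_dataset(n = 600, p = 10, n_informative = 5, effect = 1.5,
                            seed = 42)
  perm <- ds
  perm$y <- melmark:::with_seed(7, sample(perm$y))
  permt <- test
  permt$y <- melmark:::with_seed(8, sample(permt$y))
  for (alg in c("svm", "random_forest", "naive_bayes")) {
    model <- train_classifier(perm, alg, seed = 11)
    rep <- evaluate_classifier(model, permt)
    expect_lt(abs(rep$roc_auc - 0.5), 0.05, label = alg)
  }
})

test_that("single-class evaluation flags an undefined AUC", {
  ds <- toy_separable()
  model <- train_classifier(ds, "svm")
  onecls <- melmark:::ds_subset(ds, which(ds$y == "melanoma"))
  rep <- evaluate_classifier(model, onecls)
  expect_true(rep$auc_undefined)
})
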