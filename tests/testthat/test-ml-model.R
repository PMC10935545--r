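# synthetic feature matrix with a known generative law
synth_matrix <- function(n = 300, law = c("barrier", "noise", "linear"),
                         seed = 1) {
  law <- match.arg(law)
  set.seed(seed)
  man <- feature_manifest()
  fm <- as.data.frame(matrix(rnorm(n * 126), n, 126))
  names(fm) <- man$feature
  fm$external_c0 <- rep(c(37.5, 50, 62.5, 75, 100), length.out = n)
  fm$grxa_peak <- switch(law,
    barrier = 1000 + 300 * fm$barrier_cum_length.mean.treated +
      rnorm(n, 0, 5),
    linear = 1000 + 250 * fm$mother_length.mean.treated +
      rnorm(n, 0, 5),
    noise = 1000 + rnorm(n, 0, 100))
  attr(fm, "manifest") <- man
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

test_that("split_train_test is seeded, disjoint and complete", {
  fm <- synth_matrix(1000)
  sp <- split_train_test(fm, fraction = 0.2, seed = 9)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$test), 200)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(1000))
  sp2 <- split_train_test(fm, fraction = 0.2, seed = 9)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_error(split_train_test(fm[1:30, ]), "at least 50")
})

test_that("prediction accuracy equals the normalised-error formula", {
  expect_equal(prediction_accuracy(c(10, 10), c(10, 10)), 1)
  expect_equal(prediction_accuracy(0.9 * c(5, 50), c(5, 50)), 0.9)
  expect_equal(prediction_accuracy(c(8, 12), c(10, 10)), 0.8)
  set.seed(10)
  for (i in 1:10) {
    obs <- runif(50, 1, 100); pred <- obs + rnorm(50, 0, 10)
    expect_equal(prediction_accuracy(pred, obs),
                 1 - mean(abs(pred - obs) / obs), tolerance = 1e-12)
  }
  expect_error(prediction_accuracy(1, 0), "positive")
})

test_that("the regressor learns constructed mappings and not noise", {
  # label a function of a single feature: near-perfect accuracy and
  # importance concentrated in that feature's group
  fm <- synth_matrix(400, "barrier")
  rep <- fit_peak_regressor(fm, seed = 2)
  expect_gt(rep$accuracy, 0.93)
  expect_gt(rep$importances$barrier_share, 0.9)
  expect_equal(rep$importances$top_features[1],
               "barrier_cum_length.mean.treated")
  expect_gt(rep$importances$top_k_share, 0.5)
  # pure-noise labels: no better than predicting the mean, and no
  # feature dominates (importances near-uniform)
  fmn <- synth_matrix(400, "noise")
  repn <- fit_peak_regressor(fmn, seed = 2)
  base <- 1 - mean(abs(mean(fmn$grxa_peak) - fmn$grxa_peak) /
                     fmn$grxa_peak)
  expect_lt(repn$accuracy, base + 0.03)
  expect_lt(max(repn$importances$per_feature), 3 / 126)
  # importances are non-negative and sum to one
  expect_true(all(repn$importances$per_feature >= 0))
  expect_equal(sum(repn$importances$per_feature), 1, tolerance = 1e-9)
  expect_equal(repn$importances$mother_share +
                 repn$importances$barrier_share, 1, tolerance = 1e-9)
})

test_that("model reports are deterministic given matrix and seed", {
  fm <- synth_matrix(200, "barrier")
  a <- fit_peak_regressor(fm, seed = 5)
  b <- fit_peak_regressor(fm, seed = 5)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$importances$per_feature, b$importances$per_feature)
  expect_identical(a$predicted, b$predicted)
})

test_that("missing features and values are rejected by name", {
  fm <- synth_matrix(100, "barrier")
  fm$mother_length.mean.treated[3] <- NA
  sp <- split_train_test(fm, seed = 1)
  expect_error(train_regressor(sp$train), "mother_length.mean.treated")
  fm2 <- synth_matrix(100, "barrier")
  fm2$barrier_count.mean.treated <- NULL
  expect_error(fit_peak_regressor(fm2, seed = 1), "lacks")
})

test_that("barrier_only_model uses exactly the 56 barrier columns", {
  fm <- synth_matrix(300, "barrier")
  bo <- barrier_only_model(fm, seed = 3)
  expect_equal(bo$n_features, 56)
  expect_gt(bo$accuracy, 0.9)     # the law is barrier-driven
  expect_equal(bo$importances$barrier_share, 1)
  stripped <- synth_matrix(300, "barrier")
  stripped$barrier_cum_sav.mean.treated <- NULL
  expect_error(barrier_only_model(stripped), "barrier")
})

test_that("the classifier separates separable classes only", {
  fm <- synth_matrix(400, "noise", seed = 7)
  # make two widely separated classes through one feature
  fm$external_c0 <- rep(c(50, 100), each = 200)
  fm$mother_area.mean.treated <-
    ifelse(fm$external_c0 == 100, 8, -8) + rnorm(400)
  cl <- train_classifier(fm, seed = 4)
  expect_gt(min(diag(cl$confusion)), 0.95)
  expect_equal(rowSums(cl$counts)[["100"]] + rowSums(cl$counts)[["50"]],
               nrow(fm) * 0.2)
  # a single class is rejected
  fm$external_c0 <- 100
  expect_error(train_classifier(fm), "2 concentration classes")
  # class imbalance below the minimum is rejected
  fm$external_c0 <- c(rep(50, 390), rep(100, 10))
  expect_error(train_classifier(fm), "below the minimum")
})
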