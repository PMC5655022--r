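test_that("confidence_interval matches the closed form", {
  expect_equal(confidence_interval(rep(0.7, 10)), 0)
  # {0.6, 0.8}: t_{0.975,1} * sd / sqrt(2) = 12.706 * 0.1414 / 1.414
  expect_equal(confidence_interval(c(0.6, 0.8)),
               qt(0.975, 1) * sd(c(0.6, 0.8)) / sqrt(2))
  expect_equal(confidence_interval(c(0.6, 0.8)), 1.2706, tolerance = 1e-4)
  # n = 10, sd = 0.05 -> 2.262 * 0.05 / sqrt(10)
  acc <- c(0.5, 0.55) # construct a vector with sd exactly 0.05, n = 10
  acc <- 0.7 + 0.05 * scale(rnorm(10))[, 1]
  expect_equal(confidence_interval(acc), qt(0.975, 9) * 0.05 / sqrt(10))
  expect_equal(confidence_interval(acc), 0.0358, tolerance = 1e-3)
  expect_error(confidence_interval(0.5), "values")
})

test_that("class_metrics computes per-class precision/recall/F", {
  m <- class_metrics(tp = 8, fn = 2, fp = 3, tn = 7)
  expect_equal(m$progress[["recall"]], 0.800)
  expect_equal(m$progress[["precision"]], 8 / 11, tolerance = 1e-6)
  expect_equal(m$progress[["f"]], 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8))
  perfect <- class_metrics(10, 0, 0, 10)
  expect_equal(unname(c(perfect$progress, perfect$no_progress)), rep(1, 6))
  # no positive predictions: precision not available, recall zero
  none <- class_metrics(0, 5, 0, 5)
  expect_true(is.na(none$progress[["precision"]]))
  expect_equal(none$progress[["recall"]], 0)
})

test_that("train_model is deterministic and fits separable data", {
  d <- separable_matrix(n = 40, sep = 3, seed = 2)
  for (m in playprogress:::MODEL_NAMES) {
    f1 <- train_model(model_spec(m, seed = 9), d$x, d$y)
    f2 <- train_model(model_spec(m, seed = 9), d$x, d$y)
    expect_identical(predict(f1, d$x), predict(f2, d$x), label = m)
  }
  # a decision tree separates a linearly separable toy set perfectly
  toy_x <- matrix(c(1:10), ncol = 1, dimnames = list(NULL, "v"))
  toy_y <- factor(rep(c("no_progress", "progress"), each = 5),
                  levels = c("no_progress", "progress"))
  fit <- train_model(model_spec("decision_tree"), toy_x, toy_y)
  expect_equal(predict(fit, toy_x), toy_y)
  expect_error(train_model(model_spec("decision_tree"), toy_x,
                           factor(rep("progress", 10))), "single-class")
})

test_that("ensembles beat the majority baseline on synthetic signal", {
  d <- separable_matrix(n = 40, p = 8, sep = 1.5, seed = 4)
  for (m in c("rotation_forest", "random_forest", "adaboost_trees")) {
    fit <- train_model(model_spec(m, seed = 1), d$x, d$y)
    acc <- mean(predict(fit, d$x) == d$y)
    expect_gte(acc, max(table(d$y)) / length(d$y))
  }
})

test_that("stratified folds preserve class proportions within one sample", {
  set.seed(6)
  y <- factor(c(rep("no_progress", 23), rep("progress", 37)),
              levels = c("no_progress", "progress"))
  fold <- playprogress:::stratified_folds(y, 10)
  for (f in 1:10) {
    n_pos <- sum(y[fold == f] == "progress")
    expect_lte(abs(n_pos - 3.7), 1)
    n_neg <- sum(y[fold == f] == "no_progress")
    expect_lte(abs(n_neg - 2.3), 1)
  }
})

test_that("repeated CV pools fold counts and reports a t interval", {
  d <- separable_matrix(n = 40, p = 6, sep = 2, seed = 7)
  cv <- repeated_stratified_cv(model_spec("naive_bayes"), d$x, d$y,
                               folds = 5, repetitions = 4, seed = 3)
  expect_length(cv$accuracies, 4)
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 1))
  expect_equal(cv$mean_accuracy, mean(cv$accuracies))
  expect_equal(cv$ci_halfwidth, confidence_interval(cv$accuracies))
  # pooled confusion sums to repetitions * n
  expect_equal(sum(cv$confusion), 4 * 40)
  # constant accuracies give a +/- 0.00 interval
  if (sd(cv$accuracies) == 0) expect_equal(cv$ci_halfwidth, 0)
  # reproducible with the same seed
  cv2 <- repeated_stratified_cv(model_spec("naive_bayes"), d$x, d$y,
                                folds = 5, repetitions = 4, seed = 3)
  expect_identical(cv$accuracies, cv2$accuracies)
  expect_error(repeated_stratified_cv(model_spec("naive_bayes"),
                                      d$x[1:4, ], d$y[1:4], folds = 10),
               "smaller")
})

test_that("CV handles NA features via fold-fitted imputation", {
  d <- separable_matrix(n = 30, p = 5, sep = 2, seed = 8)
  d$x[sample(length(d$x), 20)] <- NA
  cv <- repeated_stratified_cv(model_spec("decision_tree"), d$x, d$y,
                               folds = 5, repetitions = 2, seed = 1,
                               variant = "norm")
  expect_true(is.finite(cv$mean_accuracy))
})
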