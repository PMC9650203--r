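# Coarse classification tree, cross-validation, FMA threshold classifier
# and confusion arithmetic.

test_that("a 1-D separable problem splits at the midpoint of the gap", {
  d <- data.frame(x = c(1, 2, 3, 10, 11),
                  cls = c("a", "a", "a", "b", "b"))
  fit <- fit_coarse_tree(d, features = "x", label = "cls")
  expect_equal(fit$n_splits, 1L)
  expect_equal(fit$nodes$threshold[1], (3 + 10) / 2)
  expect_equal(fit$nodes$threshold[1], oracle_best_threshold(d$x, d$cls))
  expect_identical(predict_tree(fit, d), d$cls)
})

test_that("single-class data yields a single predicting leaf", {
  d <- data.frame(x = rnorm(10), cls = "only")
  fit <- fit_coarse_tree(d, features = "x", label = "cls")
  expect_equal(fit$n_splits, 0L)
  expect_identical(predict_tree(fit, d), rep("only", 10))
})

test_that("the published-cutoff fixture tree reproduces the decision rule", {
  fig_tree <- coarse_tree_from_rules(
    list(feature = "asymm_crp", threshold = 0.27,
         left = "two_modules",
         right = list(feature = "asymm_cst", threshold = -0.02,
                      left = "two_modules", right = "more_than_two")))
  probes <- data.frame(
    asymm_crp = c(0.20, 0.50, 0.50, 0.27, 0.26999),
    asymm_cst = c(0.50, -0.10, 0.50, -0.02, 10))
  expect_identical(
    predict_tree(fig_tree, probes),
    c("two_modules",    # severe CRP asymmetry
      "two_modules",    # moderate CRP but negative CST asymmetry
      "more_than_two",  # neither cut region
      "more_than_two",  # boundary: strict less-than on both features
      "two_modules"))
})

test_that("tree training is invariant to record order", {
  set.seed(6)
  d <- data.frame(asymm_cst = rnorm(40), asymm_crp = rnorm(40),
                  pattern_class = sample(c("two_modules", "more_than_two"),
                                         40, replace = TRUE))
  f1 <- fit_coarse_tree(d)
  f2 <- fit_coarse_tree(d[sample(40), ])
  expect_equal(f1$nodes, f2$nodes)
})

test_that("the tree never exceeds four splits", {
  set.seed(7)
  d <- data.frame(asymm_cst = rnorm(120), asymm_crp = rnorm(120),
                  pattern_class = sample(c("two_modules", "more_than_two"),
                                         120, replace = TRUE))
  fit <- fit_coarse_tree(d)
  expect_lte(fit$n_splits, 4L)
  expect_lte(sum(!fit$nodes$is_leaf), 4L)
})

test_that("tree predictions agree with an independent CART on clean data", {
  skip_if_not_installed("rpart")
  set.seed(8)
  d <- data.frame(asymm_cst = c(rnorm(25, -1), rnorm(25, 2)),
                  asymm_crp = rnorm(50),
                  pattern_class = rep(c("two_modules", "more_than_two"),
                                      each = 25))
  ours <- fit_coarse_tree(d)
  ref <- rpart::rpart(pattern_class ~ asymm_cst + asymm_crp, d,
                      method = "class",
                      control = rpart::rpart.control(minsplit = 2, cp = 0))
  expect_identical(predict_tree(ours, d),
                   as.character(predict(ref, d, type = "class")))
})

test_that("cross-validation is seeded, stratified and exact on separable data", {
  d <- data.frame(asymm_cst = c(rnorm(20, -3), rnorm(20, 3)),
                  asymm_crp = rnorm(40),
                  pattern_class = rep(c("two_modules", "more_than_two"),
                                      each = 20))
  cv1 <- cross_validate_tree(d, seed = 5)
  cv2 <- cross_validate_tree(d, seed = 5)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$cv_accuracy, cv2$cv_accuracy)
  expect_equal(cv1$cv_accuracy, 100)
  expect_equal(cv1$resub_accuracy, 100)
  # each fold holds ~1/5 of each class
  expect_true(all(table(cv1$folds, d$pattern_class) == 4))
})

test_that("permuted labels cross-validate near the majority-class rate", {
  set.seed(9)
  n <- 60
  d <- data.frame(asymm_cst = rnorm(n), asymm_crp = rnorm(n),
                  pattern_class = sample(rep(c("two_modules",
                                               "more_than_two"),
                                             c(20, 40))))
  cv <- cross_validate_tree(d, seed = 2)
  majority <- 100 * 40 / 60
  # out-of-fold accuracy of noise features stays within binomial noise
  expect_lt(abs(cv$cv_accuracy - majority), 3 * 100 * sqrt(0.33 * 0.67 / n))
})

test_that("the FMA-LE synergy cutoff classifies with strict inequality", {
  expect_equal(fma_threshold_classifier(14), "two_modules")
  expect_equal(fma_threshold_classifier(15), "more_than_two")
  expect_equal(fma_threshold_classifier(22), "more_than_two")
  expect_equal(fma_threshold_classifier(0), "two_modules")
  expect_error(fma_threshold_classifier(23), class = "invalid_input")
  expect_error(fma_threshold_classifier(-1), class = "invalid_input")
})

test_that("confusion percentages are exact functions of the counts", {
  truth <- rep(c("more_than_two", "two_modules"), c(30, 13))
  pred <- c(rep("more_than_two", 28), rep("two_modules", 2),
            rep("two_modules", 7), rep("more_than_two", 6))
  cs <- confusion_report(truth, pred)
  expect_equal(cs$overall_pct, 100 * 35 / 43)
  expect_equal(cs$display$overall_pct, 81)
  expect_equal(unname(cs$per_class_pct["more_than_two"]), 100 * 28 / 30)
  expect_equal(unname(cs$display$per_class_pct["more_than_two"]), 93)
  expect_equal(unname(cs$display$per_class_pct["two_modules"]), 53)
  expect_equal(cs$fpr_positive, 100 * 2 / 30)
  all_right <- confusion_report(truth, truth)
  expect_equal(all_right$overall_pct, 100)
  expect_true(all(all_right$per_class_pct == 100))
  expect_error(confusion_report(truth, pred[-1]), class = "invalid_input")
})
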