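test_that("metrics reproduce the hand-tallied confusion example", {
  r <- compute_metrics(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 1))
  expect_identical(c(r$tp, r$fp, r$tn, r$fn), c(1L, 1L, 2L, 1L))
  expect_equal(r$accuracy, 0.6)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$precision, 0.5)
  expect_equal(r$f1, 0.5)
  expect_equal(r$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(r$balanced_accuracy, (0.5 + 2 / 3) / 2, tolerance = 1e-12)
})

test_that("perfect predictions score one on every metric", {
  y <- rep(c("0", "1"), c(7, 3))
  r <- compute_metrics(y, y)
  for (m in c("accuracy", "sensitivity", "specificity", "precision", "f1",
              "balanced_accuracy")) {
    expect_equal(r[[m]], 1)
  }
})

test_that("all-majority predictions on the 1489:491 imbalance degrade as expected", {
  y <- rep(c("0", "1"), c(1489, 491))
  # both the precision and the F1 ratios degenerate and warn
  expect_warning(expect_warning(r <- compute_metrics(y, rep("0", 1980)),
                                "precision undefined"), "F1 undefined")
  expect_equal(r$sensitivity, 0)
  expect_equal(r$specificity, 1)
  expect_equal(r$balanced_accuracy, 0.5)
  expect_equal(r$accuracy, 1489 / 1980, tolerance = 1e-12)
  expect_equal(r$precision, 0)  # zero denominator convention
  expect_equal(r$f1, 0)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    y <- sample(c("0", "1"), n, replace = TRUE, prob = c(0.7, 0.3))
    p <- sample(c("0", "1"), n, replace = TRUE)
    r <- suppressWarnings(compute_metrics(y, p))
    expect_equal(r$balanced_accuracy, (r$sensitivity + r$specificity) / 2,
                 tolerance = 1e-12)
    if (r$precision + r$sensitivity > 0) {
      expect_equal(r$f1,
                   2 * r$precision * r$sensitivity /
                     (r$precision + r$sensitivity), tolerance = 1e-12)
    }
    expect_identical(r$tp + r$fp + r$tn + r$fn, n)
  }
})

test_that("metrics reject malformed label vectors", {
  expect_error(compute_metrics(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(compute_metrics(c(0, 1, 2), c(0, 1, 2)), "at most two")
  expect_error(compute_metrics(c("a", "b"), c("a", "b"), positive = "1"),
               "absent")
})

test_that("stratified folds hit the documented per-fold class counts", {
  y <- rep(c("0", "1"), c(1489, 491))
  f <- stratified_folds(y, k = 10, seed = 4)
  tab <- table(f, y)
  expect_true(all(tab[, "0"] %in% c(148, 149)))
  expect_true(all(tab[, "1"] %in% c(49, 50)))
  expect_identical(sum(tab), 1980L)

  # small exact case: every fold one of each class
  f2 <- stratified_folds(c(0, 0, 1, 1), k = 2, seed = 1)
  expect_identical(unname(table(f2, c(0, 0, 1, 1)))[, 1], c(1L, 1L))
})

test_that("fold assignment partitions the samples deterministically", {
  y <- rep(c("0", "1"), c(120, 40))
  f1 <- stratified_folds(y, k = 8, seed = 99)
  f2 <- stratified_folds(y, k = 8, seed = 99)
  expect_identical(f1, f2)
  f3 <- stratified_folds(y, k = 8, seed = 100)
  expect_false(identical(f1, f3))
  expect_setequal(unique(f1), 1:8)
  expect_length(f1, 160)
  # per-class proportion off global by at most one sample per fold
  tab <- table(f1, y)
  expect_true(all(abs(tab[, "1"] - 40 / 8) < 1))
})

test_that("folds require every class to fill k folds", {
  expect_error(stratified_folds(rep(c(0, 1), c(30, 4)), k = 5), "fewer than k")
  expect_error(stratified_folds(rep(0:1, 10), k = 1), "at least 2")
})

test_that("a single fold over all samples equals direct evaluation", {
  tabs <- random_tables(3, 60, 2, seed = 8)
  set.seed(8)
  y <- sample(c("0", "1"), 60, replace = TRUE)
  acc <- c(0.8, 0.75, 0.7)
  cv <- suppressWarnings(
    cross_validate_ensemble(tabs, y, folds = rep(1L, 60), accuracies = acc,
                            accuracy_policy = "manifest"))
  fit <- dsfuse(tabs, accuracies = acc)
  direct <- suppressWarnings(compute_metrics(y, fit$labels))
  expect_equal(unname(cv$mean["accuracy"]), direct$accuracy, tolerance = 1e-12)
  expect_equal(unname(cv$mean["f1"]), direct$f1, tolerance = 1e-12)
})

test_that("one-hot oracle scores cross-validate to perfect accuracy", {
  y <- rep(c("0", "1"), c(40, 20))
  onehot <- prob_matrix(cbind(as.numeric(y == "0"), as.numeric(y == "1")),
                        sample_ids = paste0("s", 1:60),
                        class_labels = c("0", "1"))
  cv <- cross_validate_ensemble(list(onehot, onehot), y, k = 5, seed = 2)
  expect_equal(unname(cv$mean["accuracy"]), 1)
  expect_equal(unname(cv$mean["sensitivity"]), 1)
  expect_identical(cv$accuracy_policy, "out-of-fold")
})

test_that("cross-validation validates its inputs", {
  tabs <- random_tables(2, 30, 2, seed = 12)
  y <- rep(c("0", "1"), 15)
  expect_error(cross_validate_ensemble(tabs, y[-1]), "30 samples")
  expect_error(cross_validate_ensemble(tabs, y, folds = rep(1L, 10)),
               "cover all samples")
  expect_error(cross_validate_ensemble(tabs, y, accuracy_policy = "manifest"),
               "requires")
})

test_that("the weighted-average baseline fuses and tie-breaks as documented", {
  t1 <- prob_matrix(rbind(c(0.6, 0.4)), "a", c("0", "1"))
  t2 <- prob_matrix(rbind(c(0.8, 0.2)), "a", c("0", "1"))
  expect_identical(unname(weighted_average_baseline(list(t1, t2))), "0")

  # weight concentrated on one classifier reproduces its labels
  tabs <- random_tables(2, 50, 3, seed = 21)
  lab1 <- colnames(tabs[[1]])[max.col(unclass(tabs[[1]]),
                                      ties.method = "first")]
  expect_identical(unname(weighted_average_baseline(tabs, c(1, 0))), lab1)

  # ties go to the lowest class index
  tie <- prob_matrix(rbind(c(0.5, 0.5)), "a", c("0", "1"))
  expect_identical(unname(weighted_average_baseline(list(tie))), "0")

  expect_error(weighted_average_baseline(tabs, c(0, 0)), "not all be zero")
  expect_error(weighted_average_baseline(tabs, c(1, -1)), "non-negative")
  expect_error(weighted_average_baseline(tabs, c(1, 1, 1)), "3 weights")
})

test_that("baseline and fuzzy ensemble labels can be compared on simulated data", {
  coh <- simulate_cohort(simulation_config(n_samples = 300, seed = 14))
  fit <- dsfuse(coh$score_tables, accuracies = coh$realized_accuracies)
  base <- weighted_average_baseline(coh$score_tables,
                                    coh$realized_accuracies)
  disagreement <- mean(fit$labels != base)
  expect_gte(disagreement, 0)
  expect_lt(disagreement, 0.5)  # both track the same signal
})
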