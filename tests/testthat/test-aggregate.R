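test_that("Choquet integral reproduces the worked examples", {
  # idempotency: equal inputs return the common value
  m <- lambda_measure(densities = c(0.2, 0.3, 0.1))
  for (v in c(0, 0.25, 0.9)) {
    expect_equal(choquet_integral(rep(v, 3), m), v, tolerance = 1e-12)
  }

  # additive case equals the weighted mean
  m0 <- lambda_measure(densities = c(0.5, 0.5))
  expect_equal(choquet_integral(c(0.3, 0.1), m0), 0.2, tolerance = 1e-15)

  # non-additive case against the hand-evaluated sorted sum
  m2 <- lambda_measure(densities = c(0.2, 0.3))
  expect_equal(choquet_integral(c(0.4, 0.9), m2), 0.55, tolerance = 1e-12)
  expect_equal(choquet_integral(c(0.4, 0.9), m2),
               oracle_choquet(c(0.4, 0.9), c(0.2, 0.3), m2$lambda),
               tolerance = 1e-14)
})

test_that("Choquet integral matches the brute-force oracle on random inputs", {
  set.seed(5)
  for (i in 1:200) {
    C <- sample(1:5, 1)
    g <- runif(C, 0.05, 0.6)
    if (C == 1) g <- 1
    m <- lambda_measure(densities = g)
    v <- runif(C)
    expect_equal(choquet_integral(v, m), oracle_choquet(v, g, m$lambda),
                 tolerance = 1e-12)
  }
})

test_that("Choquet integral validates its inputs", {
  m <- lambda_measure(densities = c(0.5, 0.5))
  expect_error(choquet_integral(c(0.1, 0.2, 0.3), m), "3 values .* 2")
  expect_error(choquet_integral(c(0.1, NA), m), "finite")
  expect_error(choquet_integral(c(0.1, 1.2), m), "\\[0, 1\\]")
})

test_that("per-class aggregation reduces to the transforms for one classifier", {
  pm <- random_tables(1, 10, 3, seed = 3)[[1]]
  m <- lambda_measure(densities = 1)
  agg <- aggregate_per_class(list(transform_scores(pm)), m)
  expect_equal(agg$deviation, deviation_scores(pm), tolerance = 1e-15)
  expect_equal(agg$support, support_scores(pm), tolerance = 1e-15)
})

test_that("per-class aggregation reproduces the two-classifier worked example", {
  p1 <- prob_matrix(matrix(c(0.9, 0.1), 1), "x", c("0", "1"))
  p2 <- prob_matrix(matrix(c(0.4, 0.6), 1), "x", c("0", "1"))
  m <- lambda_measure(densities = c(0.5, 0.5))
  agg <- aggregate_per_class(list(p1, p2), m)

  # independent hand evaluation: additive measure, so aggregates are means
  dev_hand <- (oracle_deviation(c(0.9, 0.1)) + oracle_deviation(c(0.4, 0.6))) / 2
  sup_hand <- (oracle_support(c(0.9, 0.1)) + oracle_support(c(0.4, 0.6))) / 2
  expect_equal(unname(agg$deviation[1, ]), dev_hand, tolerance = 1e-14)
  expect_equal(unname(agg$support[1, ]), sup_hand, tolerance = 1e-14)
  # frozen decimals from that evaluation
  expect_equal(unname(agg$deviation[1, ]), c(0.0848587, 0.2049534),
               tolerance = 1e-6)
  expect_equal(unname(agg$support[1, ]), c(0.9084596, 0.7679756),
               tolerance = 1e-6)

  # the end-to-end decision agrees on class 0
  fit <- dsfuse(list(p1, p2), measure = m)
  expect_identical(fit$labels, "0")
  expect_true(fit$decisions$agreed)
})

test_that("identical classifiers aggregate to the single-classifier transforms", {
  pm <- random_tables(1, 25, 2, seed = 9)[[1]]
  m <- lambda_measure(accuracies = rep(0.8, 4))
  agg <- aggregate_per_class(list(pm, pm, pm, pm), m)
  expect_equal(agg$deviation, deviation_scores(pm), tolerance = 1e-12)
  expect_equal(agg$support, support_scores(pm), tolerance = 1e-12)
})

test_that("aggregates stay within the transform ranges", {
  set.seed(17)
  for (i in 1:5) {
    tabs <- random_tables(4, 30, 3, seed = i)
    m <- lambda_measure(accuracies = runif(4, 0.5, 0.95))
    agg <- aggregate_per_class(tabs, m)
    expect_true(all(agg$deviation >= 0 & agg$deviation <= 1 - exp(-1 / 2)))
    expect_true(all(agg$support >= 1 - tanh(1 / 2) & agg$support <= 1))
  }
})

test_that("additive measures collapse the aggregation to weighted means", {
  for (seed in 1:5) {
    tabs <- random_tables(4, 40, 2, seed = seed + 100)
    set.seed(seed)
    acc <- runif(4, 0.5, 0.95)
    m <- lambda_measure(accuracies = acc)
    g <- m$densities
    agg <- aggregate_per_class(tabs, m)
    dev_wm <- Reduce(`+`, Map(function(t, w) w * deviation_scores(t), tabs, g))
    sup_wm <- Reduce(`+`, Map(function(t, w) w * support_scores(t), tabs, g))
    expect_equal(agg$deviation, dev_wm, tolerance = 1e-12)
    expect_equal(agg$support, sup_wm, tolerance = 1e-12)
  }
})

test_that("decisions follow argmin deviation with deviation-priority on clashes", {
  agg <- structure(list(
    deviation = rbind(c(0.1, 0.3), c(0.20, 0.25), c(0.2, 0.2)),
    support = rbind(c(0.9, 0.6), c(0.70, 0.80), c(0.8, 0.8))),
    class = "aggregated_scores")
  dimnames(agg$deviation) <- list(c("a", "b", "c"), c("0", "1"))
  dimnames(agg$support) <- dimnames(agg$deviation)

  d <- decide_labels(agg)
  # agreement case
  expect_identical(d$label[1], "0")
  expect_true(d$agreed[1])
  # clash: support prefers class 1, deviation wins with class 0
  expect_identical(d$label[2], "0")
  expect_false(d$agreed[2])
  expect_identical(d$support_choice[2], "1")
  # ties break to the lowest class index
  expect_identical(d$label[3], "0")
  expect_identical(d$support_choice[3], "0")
})

test_that("the final label always equals the deviation argmin", {
  set.seed(19)
  for (i in 1:5) {
    tabs <- random_tables(3, 100, 4, seed = i + 40)
    fit <- dsfuse(tabs, accuracies = runif(3, 0.5, 0.9))
    expect_identical(fit$labels,
                     colnames(fit$deviation)[apply(fit$deviation, 1, which.min)])
    expect_identical(fit$labels, fit$decisions$deviation_choice)
  }
})

test_that("a single classifier reduces to argmax of raw probabilities", {
  pm <- random_tables(1, 200, 3, seed = 77)[[1]]
  fit <- dsfuse(list(pm), accuracies = 0.8)
  expect_identical(fit$labels,
                   colnames(pm)[max.col(unclass(pm), ties.method = "first")])
  # the binary spot check: P = (0.3, 0.7) predicts class 1
  one <- dsfuse(list(prob_matrix(matrix(c(0.3, 0.7), 1), "a", c("0", "1"))),
                accuracies = 0.9)
  expect_identical(one$labels, "1")
})

test_that("the fitted object carries its methods", {
  tabs <- random_tables(2, 15, 2, seed = 55)
  fit <- dsfuse(tabs, accuracies = c(0.8, 0.7))
  expect_s3_class(fit, "dsfuse")
  expect_named(fitted(fit), paste0("s", 1:15))
  expect_identical(unname(fitted(fit)), fit$labels)
  expect_output(print(fit), "Deviation-support fuzzy ensemble")
  s <- summary(fit)
  expect_s3_class(s, "summary.dsfuse")
  expect_output(print(s), "agreement")
  expect_identical(unname(predict(fit)), fit$labels)
  expect_identical(predict(fit, type = "deviation"), fit$deviation)
  # predicting on new tables reuses the measure
  new_tabs <- random_tables(2, 6, 2, seed = 56)
  pr <- predict(fit, new_tabs)
  expect_length(pr, 6)
  refit <- dsfuse(new_tabs, measure = fit$measure)
  expect_identical(unname(pr), refit$labels)
  # plot runs silently to a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("misaligned or mismatched inputs are rejected", {
  tabs <- random_tables(2, 10, 2, seed = 60)
  expect_error(dsfuse(tabs, accuracies = c(0.8, 0.7, 0.6)), "3 accuracies")
  expect_error(dsfuse(tabs), "supply")
  m3 <- lambda_measure(accuracies = c(0.8, 0.7, 0.6))
  expect_error(dsfuse(tabs, measure = m3), "measure over 3")
  bad <- tabs
  rownames(bad[[2]]) <- rev(rownames(bad[[2]]))
  expect_error(dsfuse(bad, accuracies = c(0.8, 0.7)), "sample identifiers")
})
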