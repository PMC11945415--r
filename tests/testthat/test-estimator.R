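# The features -> circumference regressors and the evaluation metrics.

# cheap synthetic feature model: circumference drives all three features
# through a smooth map, mimicking the geometry without rendering
fake_dataset <- function(n, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    circ <- runif(n, 22, 38)
    r_cm <- circ / (2 * pi)
    data.frame(
      left_height_cm = r_cm * 0.9 + rnorm(n, 0, noise),
      right_height_cm = r_cm * 1.05 + rnorm(n, 0, noise),
      top_arc_length_cm = circ * 0.45 + rnorm(n, 0, noise),
      truth_cm = circ)
  })
}

feature_cols <- c("left_height_cm", "right_height_cm", "top_arc_length_cm")

test_that("constant targets are reproduced with zero training error", {
  d <- fake_dataset(30)
  for (alg in c("random_forest", "decision_tree", "extra_trees", "adaboost")) {
    # randomForest advises against degenerate responses; the edge case is
    # intentional here
    m <- suppressWarnings(
      hc_train(d[feature_cols], rep(33, 30), algorithm = alg, seed = 2))
    expect_equal(predict(m, d[feature_cols]), rep(33, 30), tolerance = 1e-9)
  }
})

test_that("training is deterministic for a fixed seed", {
  d <- fake_dataset(60, noise = 0.3)
  for (alg in c("random_forest", "decision_tree", "extra_trees", "adaboost")) {
    m1 <- hc_train(d[feature_cols], d$truth_cm, algorithm = alg, seed = 9)
    m2 <- hc_train(d[feature_cols], d$truth_cm, algorithm = alg, seed = 9)
    expect_identical(predict(m1, d[feature_cols]), predict(m2, d[feature_cols]))
  }
})

test_that("a fully grown decision tree memorizes its training set", {
  d <- fake_dataset(40)
  m <- hc_train(d[feature_cols], d$truth_cm, algorithm = "decision_tree")
  expect_equal(predict(m, d[feature_cols]), d$truth_cm, tolerance = 1e-9)
})

test_that("tree ensembles do not extrapolate beyond observed targets", {
  d <- fake_dataset(80, noise = 0.1)
  m <- hc_train(d[feature_cols], d$truth_cm, algorithm = "random_forest")
  far <- data.frame(left_height_cm = c(0.01, 50), right_height_cm = c(0.01, 50),
                    top_arc_length_cm = c(0.1, 100))
  p <- predict(m, far)
  expect_true(all(p >= min(d$truth_cm) & p <= max(d$truth_cm)))
})

test_that("training input is validated", {
  d <- fake_dataset(20)
  expect_error(hc_train(d[feature_cols], d$truth_cm[1:10]), "lengths differ")
  expect_error(hc_train(d[feature_cols], -d$truth_cm), "positive")
  expect_error(hc_train(d[feature_cols][1:5, ], d$truth_cm[1:5]), "at least 10")
  expect_error(hc_train(d[feature_cols], d$truth_cm, algorithm = "svm"))
  m <- hc_train(d[feature_cols], d$truth_cm)
  expect_error(predict(m, d[c("left_height_cm", "right_height_cm")]),
               "missing feature")
})

test_that("persisted models predict identically after reload", {
  d <- fake_dataset(60, noise = 0.2)
  probe <- fake_dataset(100, noise = 0.2, seed = 99)
  for (alg in c("random_forest", "adaboost")) {
    m <- hc_train(d[feature_cols], d$truth_cm, algorithm = alg, seed = 5)
    f <- withr::local_tempfile(fileext = ".rds")
    hc_save_model(m, f)
    m2 <- hc_load_model(f)
    expect_identical(predict(m, probe[feature_cols]),
                     predict(m2, probe[feature_cols]))
  }
})

test_that("the MAE matches a brute-force oracle and the hand example", {
  # truths (30, 32, 34) vs predictions (31, 31, 35): (1 + 1 + 1) / 3 = 1
  ev <- hc_evaluate(c(31, 31, 35), c(30, 32, 34))
  expect_equal(ev$mae_cm, 1, tolerance = 1e-12)

  withr::with_seed(14, {
    for (k in 1:10) {
      y <- runif(50, 20, 40); p <- y + rnorm(50)
      acc <- 0
      for (i in seq_along(y)) acc <- acc + abs(y[i] - p[i])
      ev <- hc_evaluate(p, y)
      expect_equal(ev$mae_cm, acc / 50, tolerance = 1e-12)
      # permutation invariance of paired entries
      o <- sample.int(50)
      expect_equal(hc_evaluate(p[o], y[o])$mae_cm, ev$mae_cm, tolerance = 1e-12)
      expect_equal(sum(ev$bins), 1)
    }
  })

  ev0 <- hc_evaluate(c(30, 31), c(30, 31))
  expect_equal(ev0$mae_cm, 0)
  expect_equal(unname(ev0$bins["<=1cm"]), 1)
  expect_error(hc_evaluate(1:3, 1:2), "length")
  expect_error(hc_evaluate(numeric(0), numeric(0)), "empty")
})

test_that("held-out error does not degrade as the training set grows", {
  probe <- fake_dataset(120, noise = 0.05, seed = 77)
  maes <- vapply(c(30, 150), function(n) {
    d <- fake_dataset(n, noise = 0.05, seed = 10)
    m <- hc_train(d[feature_cols], d$truth_cm, seed = 10)
    hc_evaluate(predict(m, probe[feature_cols]), probe$truth_cm)$mae_cm
  }, numeric(1))
  expect_lte(maes[2], maes[1] * 1.1)  # decreasing or statistically flat
})

test_that("algorithm comparison runs all four on one reproducible split", {
  d <- fake_dataset(80, noise = 0.3)
  cmp <- hc_compare(d[feature_cols], d$truth_cm, seed = 3)
  expect_equal(nrow(cmp), 4L)
  expect_true(all(is.finite(cmp$mae_cm)))
  cmp2 <- hc_compare(d[feature_cols], d$truth_cm, seed = 3)
  expect_identical(as.data.frame(cmp), as.data.frame(cmp2))
  expect_warning(
    cmp3 <- hc_compare(d[feature_cols], d$truth_cm,
                       algorithms = c("random_forest", "random_forest"),
                       seed = 3),
    "duplicate")
  expect_equal(nrow(cmp3), 1L)
})
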