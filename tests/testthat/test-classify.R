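test_that("kNN majority vote and tie-breaks follow the stated rules", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  y <- rep(c("A", "B"), each = 3)
  expect_equal(knn_predict(x, y, 1.5, k = 5), "A")
  expect_equal(knn_predict(x, y, x[4, ], k = 1), "B")
  # 2-2-1 three-class vote: nearest tied-class neighbour decides
  x3 <- matrix(c(0, 0.4, 1, 1.1, 5), ncol = 1)
  y3 <- c("A", "A", "B", "B", "C")
  expect_equal(knn_predict(x3, y3, 0.1, k = 5), "A")
  expect_equal(knn_predict(x3, y3, 1.05, k = 5), "B")
  expect_error(knn_predict(x, y, 1, k = 7), "exceeds")
})

test_that("kNN agrees with the exhaustive oracle on random instances", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:20, 1)
    d <- sample(1:4, 1)
    k <- sample(1:min(7, n), 1)
    x <- matrix(round(rnorm(n * d), 2), n, d) # rounding induces ties
    y <- sample(c("A", "B", "C"), n, replace = TRUE)
    q <- round(rnorm(d), 2)
    expect_identical(knn_predict(x, y, q, k), knn_oracle(x, y, q, k))
  }
})

test_that("LOOCV separates clear clusters and stays at chance on noise", {
  set.seed(32)
  cfg <- classifier_config("knn")
  # two tight clusters, gap >> spread
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 10, 0.1), 20, 2))
  y <- rep(c("low", "high"), each = 20)
  expect_equal(loocv_evaluate(x, y, cfg)$accuracy, 100)
  # labels shuffled against features: inside the binomial 99% band
  xr <- matrix(rnorm(80), 40, 2)
  yr <- sample(y)
  acc <- loocv_evaluate(xr, yr, cfg)$accuracy
  expect_gte(acc, 22.5)  # qbinom(0.005, 40, ~0.487)-ish band at n=40
  expect_lte(acc, 72.5)
  expect_error(loocv_evaluate(x, rep("low", 40), cfg), "degenerate")
})

test_that("LOOCV fold predictions equal a brute-force oracle on a worked set", {
  x <- matrix(c(0, 1, 2, 6, 7, 8), ncol = 1)
  y <- c("A", "A", "A", "B", "B", "B")
  cfg <- classifier_config("knn", k = 3, standardize = FALSE)
  ev <- loocv_evaluate(x, y, cfg)
  oracle <- vapply(1:6, function(i) {
    knn_oracle(x[-i, , drop = FALSE], y[-i], x[i, ], k = 3)
  }, "")
  expect_equal(ev$predictions, oracle)
  expect_equal(ev$accuracy, 100)
})

test_that("held-out trials never influence scaler statistics", {
  set.seed(33)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("low", "high"), 10)
  cfg <- classifier_config("knn")
  base <- loocv_evaluate(x, y, cfg)
  x2 <- x
  x2[7, ] <- x2[7, ] + 1e6 # extreme-valued held-out trial
  pert <- loocv_evaluate(x2, y, cfg)
  expect_identical(base$fold_scalers[[7]], pert$fold_scalers[[7]])
})

test_that("SVM tuning sees only training folds and is seed-deterministic", {
  set.seed(34)
  x <- rbind(matrix(rnorm(24, 0), 12, 2), matrix(rnorm(24, 4), 12, 2))
  y <- rep(c("low", "high"), each = 12)
  cfg <- classifier_config("svm_rbf", tuner = "grid", grid_points = 3,
                           inner_folds = 3, tuner_seed = 5)
  ev1 <- loocv_evaluate(x, y, cfg)
  # linearly separable standardized toy reaches 100% within the ranges
  expect_equal(ev1$accuracy, 100)
  ev2 <- loocv_evaluate(x, y, cfg)
  expect_identical(ev1$predictions, ev2$predictions)
  expect_identical(ev1$fold_hyper, ev2$fold_hyper)
  # perturbing the held-out trial leaves that fold's tuning unchanged
  x2 <- x
  x2[5, ] <- x2[5, ] + 500
  ev3 <- loocv_evaluate(x2, y, cfg)
  expect_identical(ev1$fold_hyper[[5]], ev3$fold_hyper[[5]])
  expect_identical(ev1$fold_scalers[[5]], ev3$fold_scalers[[5]])
})

test_that("the Bayesian tuner is deterministic and finds a separating model", {
  set.seed(35)
  x <- rbind(matrix(rnorm(16, 0, 0.5), 8, 2), matrix(rnorm(16, 5, 0.5), 8, 2))
  y <- rep(c("low", "high"), each = 8)
  cfg <- classifier_config("svm_rbf", tuner = "bayesian", tuner_iters = 6,
                           inner_folds = 2, tuner_seed = 9)
  ev1 <- loocv_evaluate(x, y, cfg)
  ev2 <- loocv_evaluate(x, y, cfg)
  expect_identical(ev1$fold_hyper, ev2$fold_hyper)
  expect_equal(ev1$accuracy, 100)
})

test_that("cohort aggregation is the unweighted mean to two decimals", {
  expect_equal(aggregate_cohort(c(100, 90)), 95)
  expect_equal(aggregate_cohort(c(97.5, 92.5, 90)), 93.33)
  expect_equal(aggregate_cohort(rep(97.1875, 3)), 97.19) # half away from zero
  expect_error(aggregate_cohort(numeric(0)), "at least one")
})

test_that("the LOOCV chance band centres on the hypergeometric null", {
  band <- loocv_chance_band(c(20, 20), k = 5, n_subjects = 1)
  # exact null success probability for 20/20 classes, k = 5:
  # P(>=3 of 5 same | 19 same, 20 other among 39)
  p0 <- sum(dhyper(3:5, 19, 20, 5))
  expect_equal(unname(band["p0"]), p0)
  expect_lt(band["p0"], 0.5)
  wide <- loocv_chance_band(c(20, 20), n_subjects = 1)
  narrow <- loocv_chance_band(c(20, 20), n_subjects = 32)
  expect_lt(narrow["upper"] - narrow["lower"],
            wide["upper"] - wide["lower"])
})
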