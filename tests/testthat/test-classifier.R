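# two tight, well-separated, label-pure clusters
pure_clusters <- function(n_per = 10, seed = 20) {
  pnnclass:::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n_per, sd = 0.05), n_per, 2),
               matrix(rnorm(2 * n_per, sd = 0.05) + 5, n_per, 2))
    list(x = x, y = rep(c("a", "b"), each = n_per))
  })
}

test_that("per-rank predictive distribution follows the score formula", {
  # query far from three training points: captured sets empty, scores are
  # pure neighbor-label indicators
  x <- cbind(c(0, 1, 3)); y <- c(1L, 2L, 2L)
  fit <- pnnclass(x, y, k_max = 2)
  prof <- pnnclass:::predict_profile(fit, fit$y, fit$L, abs(c(0, 1, 3) - 100))
  for (r in 1:2) {
    nb_lab <- fit$y[order(abs(c(0, 1, 3) - 100))[r]]
    s <- as.numeric(seq_len(2) == nb_lab)
    expect_equal(prof[r, ], exp(fit$beta[r] * s) / sum(exp(fit$beta[r] * s)),
                 tolerance = 1e-14)
  }

  # beta = 0 gives the uniform distribution
  expect_equal(prof[which(fit$beta == 0), , drop = FALSE][1, ], c(0.5, 0.5),
               tolerance = 0, ignore_attr = TRUE)
})

test_that("predictive scores: neighbor indicator at beta = ln 2, and ties", {
  # hand-built rank-1 model on two units with beta = ln 2
  core <- list(d = rbind(c(0, 2), c(2, 0)), beta = log(2), k_max = 1L)
  # distant query: nearest neighbor is unit 1 (label 1), nobody captured
  # (each unit keeps its old nearest neighbor) -> probs (2/3, 1/3)
  prof <- pnnclass:::predict_profile(core, c(1L, 2L), 2L, c(3, 3.5))
  expect_equal(prof[1, ], c(2 / 3, 1 / 3), tolerance = 1e-14)

  # query between the units captures both (0.9 < 2 and 1.1 < 2) and its
  # nearest neighbor is unit 1: scores (2, 1) -> probs (4, 2)/6
  prof <- pnnclass:::predict_profile(core, c(1L, 2L), 2L, c(0.9, 1.1))
  expect_equal(prof[1, ], c(2 / 3, 1 / 3), tolerance = 1e-14)

  # opposing evidence: nearest neighbor has label 1, the single captured
  # unit has label 2 -> scores tie at 1, distribution uniform
  core3 <- list(d = distance_matrix(cbind(c(0, 1, 5))), beta = log(2),
                k_max = 1L)
  prof <- pnnclass:::predict_profile(core3, c(1L, 1L, 2L), 2L, c(2, 1, 3))
  expect_equal(prof[1, ], c(0.5, 0.5), tolerance = 1e-14)
})

test_that("aggregation averages the leading per-rank distributions", {
  P <- rbind(c(1, 0), c(0, 1), c(0.25, 0.75))
  expect_identical(aggregate_predictive(P, 1), c(1, 0))
  expect_equal(aggregate_predictive(P, 2), c(0.5, 0.5))
  expect_equal(sum(aggregate_predictive(P, 3)), 1)
  expect_error(aggregate_predictive(P, 0), "range")
  set.seed(21)
  Q <- matrix(rexp(20), 5); Q <- Q / rowSums(Q)
  expect_equal(aggregate_predictive(Q, 4), colMeans(Q[1:4, ]))
  expect_equal(aggregate_predictive(Q[, c(2, 1, 3, 4)], 4),
               aggregate_predictive(Q, 4)[c(2, 1, 3, 4)])
})

test_that("LOOCV error curve matches a full hand trace on a 3-point set", {
  x <- cbind(c(0, 1, 3)); y <- c(1L, 1L, 2L)
  fit <- pnnclass(x, y, k_max = 2)
  # rank 1: unit 3 is predicted from its nearest neighbor (unit 2, label 1)
  # and misclassified; units 1 and 2 reinforce each other -> error 1/3.
  # rank 2: T_2 = 0 so beta_2 = 0 and p_2 is uniform; aggregation keeps the
  # same argmax labels -> error stays 1/3; ties pick k = 1.
  expect_equal(fit$T, c(2L, 0L))
  expect_equal(fit$beta[2], 0)
  expect_gt(fit$beta[1], 0)
  expect_equal(fit$loocv_error, c(1 / 3, 1 / 3))
  expect_identical(fit$k, 1L)
})

test_that("pure clusters give zero LOO error and confident predictions", {
  dat <- pure_clusters()
  fit <- pnnclass(dat$x, dat$y, k_max = 10)
  expect_equal(fit$loocv_error[fit$k], 0)
  expect_identical(fit$k, 1L)                     # ties -> smallest k
  expect_identical(predict(fit, dat$x), dat$y)    # error 0 on training points
  P <- predict(fit, dat$x[1, , drop = FALSE], type = "prob")
  expect_gt(P[1, "a"], 0.9)
})

test_that("label-noise data yields LOO error near the majority-class rate", {
  # under exact per-fold refitting the LOO error on labels independent of
  # the features sits near the 50% majority-class rate, pushed slightly
  # above it because holding a unit out makes its own class the rarer one
  # in the fold (19/39 here), an anti-correlation that aggregation amplifies
  set.seed(22)
  vals <- replicate(4, {
    n <- 40
    x <- matrix(rnorm(2 * n), n, 2)
    y <- rep(c(1L, 2L), each = n / 2)[sample.int(n)]
    fit <- pnnclass(x, y, k_max = 15, refit_loocv = TRUE)
    mean(fit$loocv_error)
  })
  expect_gt(mean(vals), 0.45)
  expect_lt(mean(vals), 0.68)

  # the fast mode reuses full-sample estimates across folds and is
  # optimistically biased on null data: bounded away from the degenerate
  # extremes, but below 1/2
  set.seed(22)
  n <- 60
  x <- matrix(rnorm(2 * n), n, 2)
  y <- rep(c(1L, 2L), each = n / 2)[sample.int(n)]   # independent of x
  fit <- pnnclass(x, y, k_max = 30)
  expect_true(all(fit$loocv_error > 0.1 & fit$loocv_error <= 0.6))
})

test_that("fit contract: estimates bounded, permutation invariance, determinism", {
  set.seed(23)
  dat <- random_dataset(10, 2, 2)
  fit <- pnnclass(dat$x, dat$y)
  expect_length(fit$beta, 9)
  expect_true(all(fit$beta >= 0 & fit$beta <= fit$beta_max))
  expect_true(all(is.finite(vapply(fit$fits, `[[`, numeric(1), "log_Z"))))
  expect_warning(pnnclass(dat$x, dat$y, k_max = 50), "clipped")
  expect_error(pnnclass(dat$x, rep(1, 10)), "single class")

  sim <- ripley_like(n_train = 40, n_test = 30, seed = 3)
  fit1 <- pnnclass(sim$train$x, sim$train$y)
  perm <- sample.int(40)
  fit2 <- pnnclass(sim$train$x[perm, ], sim$train$y[perm])
  expect_identical(fit1$k, fit2$k)
  expect_identical(fit1$loocv_error, fit2$loocv_error)
  expect_identical(predict(fit1, sim$test$x), predict(fit2, sim$test$x))

  # batch prediction equals one-at-a-time; repeated runs are bit-identical
  P <- predict(fit1, sim$test$x, type = "prob")
  P1 <- t(vapply(seq_len(30), function(i)
    predict(fit1, sim$test$x[i, , drop = FALSE], type = "prob")[1, ],
    numeric(2)))
  expect_identical(unname(P), unname(P1))
  fit1b <- pnnclass(sim$train$x, sim$train$y)
  expect_identical(predict(fit1b, sim$test$x, type = "prob"), P)
})

test_that("formula interface and S3 methods work", {
  sim <- ripley_like(n_train = 40, n_test = 10, seed = 4)
  df <- data.frame(x1 = sim$train$x[, 1], x2 = sim$train$x[, 2], y = sim$train$y)
  fit <- pnnclass(y ~ x1 + x2, data = df, k_max = 15)
  fitm <- pnnclass(sim$train$x, sim$train$y, k_max = 15)
  expect_identical(fit$k, fitm$k)
  expect_identical(coef(fit), coef(fitm))
  expect_output(print(fit), "Probabilistic nearest neighbors")
  expect_output(print(summary(fit)), "interaction strengths")
  F <- fitted(fit)
  expect_equal(unname(rowSums(F)), rep(1, 40), tolerance = 1e-12)
  expect_equal(residuals(fit), 1 - F[cbind(1:40, fit$y)])
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("exact per-fold refit mode agrees qualitatively on easy data", {
  dat <- pure_clusters(n_per = 6, seed = 24)
  fast <- pnnclass(dat$x, dat$y, k_max = 5)
  slow <- pnnclass(dat$x, dat$y, k_max = 5, refit_loocv = TRUE)
  expect_equal(slow$loocv_error[slow$k], 0)
  expect_identical(fast$k, slow$k)
})
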