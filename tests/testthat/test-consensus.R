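test_that("member predictions are plain linear algebra", {
  X <- cbind(a = c(1, 2, 3, 5), b = c(0, 1, 0, 1))
  y <- 2 + 0.5 * X[, "a"] - X[, "b"]
  model <- suppressWarnings(fit_mlr(X, y, c("a", "b")))
  m <- as_wm(X, y)
  P <- predict_members(list(model, model), m)
  expect_equal(dim(P), c(4, 2))
  expect_equal(P[, 1], P[, 2])
  expect_equal(unname(P[, 1]), unname(y), tolerance = 1e-12)

  m2 <- as_wm(cbind(a = c(0, 10), b = c(1, -1)), c(1, 1))
  expect_equal(unname(predict_members(list(model), m2)[, 1]),
               c(2 - 1, 2 + 5 + 1), tolerance = 1e-12)

  # a model whose feature is absent from the matrix names the column
  mbad <- as_wm(cbind(a = c(1, 2, 3)), y)
  expect_error(predict_members(list(model), mbad), "b")
})

test_that("local model quality is the mean LOO error over nearest neighbours", {
  set.seed(5)
  X <- cbind(f = c(1:12))
  y <- 2 + 0.4 * X[, "f"] + rnorm(12, sd = 0.2)
  train <- as_wm(X, y)
  member <- consensus_member(fit_mlr(X, y, "f"), train)

  got <- per_record_model_quality(member, c(f = 3.2), n_similar = 3)
  # naive oracle: z-score, rank distances, average the 3 LOO errors
  loo_err <- abs(y - naive_loo_oracle(X, y, "f"))
  z <- (X[, "f"] - mean(X[, "f"])) / sd(X[, "f"])
  zq <- (3.2 - mean(X[, "f"])) / sd(X[, "f"])
  nn <- order(abs(z - zq))[1:3]
  expect_equal(got, mean(loo_err[nn]), tolerance = 1e-12)

  # a test record equal to a training record keeps it in its neighbourhood
  got1 <- per_record_model_quality(member, c(f = 7), n_similar = 1)
  expect_equal(got1, loo_err[7], tolerance = 1e-12)

  # perfect LOO predictions give zero local MAE everywhere
  ylin <- 1 + 2 * X[, "f"]
  mlin <- consensus_member(suppressWarnings(fit_mlr(X, ylin, "f")),
                           as_wm(X, ylin))
  expect_equal(per_record_model_quality(mlin, c(f = 5), n_similar = 4), 0,
               tolerance = 1e-10)
})

test_that("consensus of clones returns the member prediction for every method", {
  set.seed(6)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  y <- 1 + X[, "a"] + 0.5 * X[, "b"] + rnorm(30, sd = 0.05)
  train <- as_wm(X, y)
  model <- fit_mlr(X, y, c("a", "b"))
  members <- list(consensus_member(model, train),
                  consensus_member(model, train))
  test <- as_wm(X[1:10, ], y[1:10])
  single <- predict(model, test)
  for (method in c("CM0", "CM1", "CM2", "CM3")) {
    res <- consensus_predict(consensus_config(members, method), test)
    expect_equal(res$table$prediction, unname(single), tolerance = 1e-12,
                 label = method)
  }
})

test_that("equally qualified members with perfect training fits average evenly", {
  # both members reproduce training exactly (cv_mae_similar = 0 for both,
  # so CM2 falls back to uniform weights); on a test record where their
  # predictions diverge, CM0 = CM1 = CM2 = the midpoint
  f <- seq(0.5, 2, length.out = 12)
  X <- cbind(d1 = f, d2 = f)
  y <- f
  train <- as_wm(X, y)
  members <- suppressWarnings(
    list(consensus_member(fit_mlr(X, y, "d1"), train),
         consensus_member(fit_mlr(X, y, "d2"), train)))
  test <- as_wm(cbind(d1 = 1.0, d2 = 1.2), 1.1)
  for (method in c("CM0", "CM1", "CM2")) {
    res <- consensus_predict(consensus_config(members, method, n_similar = 5),
                             test)
    expect_equal(res$table$prediction, 1.1, tolerance = 1e-10,
                 label = method)
  }
})

test_that("CM3 tracks the regional expert and beats plain averaging", {
  for (seed in 1:20) {
    fx <- region_fixture(seed)
    cm0 <- consensus_predict(consensus_config(fx$members, "CM0"), fx$test)
    cm3 <- consensus_predict(consensus_config(fx$members, "CM3"), fx$test)
    mae <- function(res) mean(abs(fx$test$y - res$table$prediction))
    expect_lte(mae(cm3), mae(cm0))
  }
})

test_that("consensus predictions are convex and CM2 weights normalized", {
  fx <- region_fixture(99)
  for (method in c("CM0", "CM1", "CM2", "CM3")) {
    res <- consensus_predict(consensus_config(fx$members, method), fx$test)
    P <- res$predictions
    lo <- pmin(P[, 1], P[, 2])
    hi <- pmax(P[, 1], P[, 2])
    expect_true(all(res$table$prediction >= lo - 1e-12 &
                      res$table$prediction <= hi + 1e-12), label = method)
  }
  cm2 <- consensus_predict(consensus_config(fx$members, "CM2"), fx$test)
  wsum <- rowSums(cm2$weights)
  expect_equal(wsum, rep(1, nrow(fx$test$X)), tolerance = 1e-12)
  cm3 <- consensus_predict(consensus_config(fx$members, "CM3"), fx$test)
  # chosen member is always one of the qualified (or fallback) set
  expect_true(all(!is.na(cm3$table$chosen_member)))
  expect_true(all(cm3$table$chosen_member %in% 1:2))
})
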