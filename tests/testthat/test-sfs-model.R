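test_that("correlation prefilter removes the later member of offending pairs", {
  set.seed(3)
  base <- rnorm(30)
  X <- cbind(a = base, b = 2 * base + 1,          # r = 1 with a
             c = rnorm(30), d = -base + rnorm(30, sd = 0.01))
  out <- prefilter_correlated(X, 0.95)
  expect_equal(colnames(out$X), c("a", "c"))
  expect_true(all(c("b", "d") %in% out$removed$removed))
  # after filtering no surviving pair exceeds the cutoff
  C <- abs(cor(out$X))
  expect_lt(max(C[upper.tri(C)]), 0.95)

  # below-threshold matrices pass unchanged
  set.seed(4)
  Y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("p", "q", "r")))
  expect_equal(prefilter_correlated(Y, 0.95)$X, Y)

  # three mutually correlated columns: exactly one survives
  Z <- cbind(x1 = base, x2 = base + rnorm(30, sd = 1e-3),
             x3 = 3 * base + rnorm(30, sd = 1e-3))
  expect_equal(colnames(prefilter_correlated(Z, 0.95)$X), "x1")

  expect_error(prefilter_correlated(cbind(k = rep(1, 5), j = rnorm(5))),
               "drop_degenerate_columns")
})

test_that("scoring functions match their definitions", {
  y <- c(1, 2, 3)
  expect_equal(score_predictions(y, y, "R2"), 1)
  expect_equal(score_predictions(y, y, "NMAE"), 0)
  expect_equal(score_predictions(y, y, "NMPD"), 0)
  expect_equal(score_predictions(y, c(1, 2, 4), "NMAE"), -1/3)
  # the mean predictor scores R2 = 0
  expect_equal(score_predictions(y, rep(mean(y), 3), "R2"), 0)
  # Poisson deviance against a hand evaluation
  yhat <- c(1.5, 2, 2.5)
  expect_equal(score_predictions(y, yhat, "NMPD"),
               -mean(2 * (y * log(y / yhat) - y + yhat)))
  expect_error(score_predictions(c(-1, 2, 3), yhat, "NMPD"), "positive")
})

test_that("fit_mlr agrees with the normal equations and reports diagnostics", {
  x <- c(0, 1, 2, 3)
  y <- 3 + 2 * x
  fit <- suppressWarnings(fit_mlr(cbind(f = x), y, "f"))
  expect_equal(unname(fit$coefficients), c(3, 2))
  expect_equal(fit$r2, 1)

  rr <- random_regression(n = 25, p = 2, seed = 5)
  fit2 <- fit_mlr(rr$X, rr$y, colnames(rr$X))
  X1 <- cbind(1, rr$X)
  beta_ne <- solve(t(X1) %*% X1, t(X1) %*% rr$y)  # normal-equation oracle
  expect_equal(unname(fit2$coefficients), unname(drop(beta_ne)),
               tolerance = 1e-10)

  # orthogonal features -> zero max intercorrelation
  Xo <- cbind(u = c(1, 1, -1, -1), v = c(1, -1, 1, -1))
  fo <- fit_mlr(Xo, c(1, 2, 3, 5), c("u", "v"))
  expect_equal(fo$max_intercorrelation, 0)

  # exact collinearity is an error naming the offender
  Xc <- cbind(a = rr$X[, 1], b = 2 * rr$X[, 1])
  expect_error(fit_mlr(Xc, rr$y, c("a", "b")), "b")
})

test_that("SFS recovers a planted two-feature signal and stops on noise", {
  set.seed(9)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- 2 * X[, "f1"] - 3 * X[, "f2"] + rnorm(n, sd = 0.05)
  sel <- sfs_mlr(X, y, sfs_config())
  expect_setequal(sel$features, c("f1", "f2"))
  # larger contribution enters first
  expect_equal(sel$features[1], "f2")
  # the accepted trace decreases MAE_LOO by at least the configured factor
  acc <- sel$trace[sel$trace$accepted, ]
  expect_true(all(acc$mae_loo_after <= 0.95 * acc$mae_loo_before))

  # pure noise response: nothing qualifies, intercept-only model
  ynoise <- rnorm(n)
  expect_warning(s0 <- sfs_mlr(X, ynoise, sfs_config()), "intercept-only")
  expect_length(s0$features, 0)
  expect_equal(unname(s0$model$coefficients), mean(ynoise))
})

test_that("with the stopping rule disabled SFS equals brute-force greedy selection", {
  rr <- random_regression(n = 40, p = 8, seed = 12, noise = 0.5)
  cfg <- sfs_config(pct_mae_reduction = 0, max_steps = 5)
  sel <- sfs_mlr(rr$X, rr$y, cfg)
  expect_equal(sel$features, greedy_sfs_oracle(rr$X, rr$y, 5))

  # growing max_steps extends the accepted prefix without reordering
  cfg2 <- sfs_config(pct_mae_reduction = 0, max_steps = 8)
  sel2 <- sfs_mlr(rr$X, rr$y, cfg2)
  expect_equal(sel2$features[seq_along(sel$features)], sel$features)
})

test_that("cross-validated scoring is seeded and reproducible", {
  rr <- random_regression(n = 60, p = 6, seed = 21, noise = 0.3)
  cfg <- sfs_config(scoring = "NMAE", cv_folds = 5, cv_seed = 7)
  s1 <- sfs_mlr(rr$X, rr$y, cfg)
  s2 <- sfs_mlr(rr$X, rr$y, cfg)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$trace, s2$trace)
})
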