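test_that("hat-matrix LOO equals the naive refit loop", {
  rr <- random_regression(n = 20, p = 3, seed = 31)
  loo <- loo_cv(rr$X, rr$y, colnames(rr$X))
  expect_equal(loo$predictions,
               naive_loo_oracle(rr$X, rr$y, colnames(rr$X)),
               tolerance = 1e-12)

  # n = 5 single-feature fixture against the explicit 5-refit loop
  X5 <- cbind(f = c(1, 2, 4, 7, 8))
  y5 <- c(1.1, 1.9, 4.2, 7.1, 7.7)
  loo5 <- loo_cv(X5, y5, "f")
  expect_equal(loo5$predictions, naive_loo_oracle(X5, y5, "f"),
               tolerance = 1e-12)

  # exact linear noise-free data: Q2 = 1, MAE = 0
  yl <- 2 + 3 * X5[, "f"]
  lool <- loo_cv(X5, yl, "f")
  expect_equal(lool$q2_loo, 1)
  expect_equal(lool$mae_loo, 0, tolerance = 1e-12)
})

test_that("leave-chemical-out matches the naive removal loop in both passes", {
  # 3 HBA x 2 HBD toy fixture
  set.seed(17)
  comp1 <- rep(c("H1", "H2", "H3"), each = 4)
  comp2 <- rep(c("D1", "D2"), 6)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + X[, "a"] - 0.5 * X[, "b"] + rnorm(12, sd = 0.2)
  m <- as_wm(X, y, comp1, comp2)

  lco <- lco_cv(m, c("a", "b"))
  p1 <- naive_lco_oracle(X, y, comp1, c("a", "b"))
  p2 <- naive_lco_oracle(X, y, comp2, c("a", "b"))
  expect_equal(lco$detail$comp1$predictions, p1, tolerance = 1e-12)
  expect_equal(lco$detail$comp2$predictions, p2, tolerance = 1e-12)
  ym <- mean(y)
  q2 <- function(p) 1 - sum((y - p)^2) / sum((y - ym)^2)
  expect_equal(lco$q2_lco, (q2(p1) + q2(p2)) / 2, tolerance = 1e-12)
  expect_equal(lco$mae_lco,
               (mean(abs(y - p1)) + mean(abs(y - p2))) / 2,
               tolerance = 1e-12)

  # noise-free linear data: perfect leave-chemical-out prediction
  ylin <- 1 + 2 * X[, "a"]
  mlin <- as_wm(X, ylin, comp1, comp2)
  lcol <- lco_cv(mlin, "a")
  expect_equal(lcol$q2_lco, 1)
  expect_equal(lcol$mae_lco, 0, tolerance = 1e-12)

  # un-evaluable removal errors unless skipping is requested
  tiny <- as_wm(X[1:5, ], y[1:5], c("H1", "H1", "H1", "H1", "H2"),
                comp2[1:5])
  expect_error(lco_cv(tiny, c("a", "b")), "H1")
})

test_that("a chemical carrying unique signal degrades LCO but not LOO", {
  # one HBD has a descriptor that is near-zero for everyone else and
  # drives the response; removing that chemical makes its coefficient
  # unidentifiable from the remaining (weak) variation
  set.seed(23)
  n_per <- 6
  comp2 <- rep(c("D1", "D2", "D3"), each = n_per)
  comp1 <- rep(sprintf("H%d", 1:6), 3)
  special <- ifelse(comp2 == "D3", 5, 0) + rnorm(18, sd = 0.05)
  base <- rnorm(18)
  X <- cbind(base = base, special = special)
  y <- 1 + 0.5 * base + 0.4 * special + rnorm(18, sd = 0.05)
  m <- as_wm(X, y, comp1, comp2)

  loo <- loo_cv(m, features = c("base", "special"))
  lco <- lco_cv(m, c("base", "special"))
  expect_lt(lco$q2_lco, loo$q2_loo)
})

test_that("external metrics center on the training mean", {
  ext <- external_metrics(y_train = c(0.9, 1.0, 1.1),
                          y_test = c(1.1, 1.2),
                          yhat_test = c(1.0, 1.1))
  expect_equal(ext$mae_test, 0.1)
  expect_equal(ext$aard_pct, 50 * (0.1 / 1.1 + 0.1 / 1.2))
  expect_equal(ext$r2_pred, 1 - 0.02 / 0.05)

  # perfect prediction
  p <- external_metrics(c(1, 2), c(1.5, 2.5), c(1.5, 2.5))
  expect_equal(unlist(p), c(r2_pred = 1, mae_test = 0, aard_pct = 0))

  # the constant training-mean predictor scores exactly zero
  y_tr <- c(0.8, 1.0, 1.2)
  y_te <- c(0.9, 1.3)
  null <- external_metrics(y_tr, y_te, rep(mean(y_tr), 2))
  expect_identical(null$r2_pred, 0)

  expect_error(external_metrics(c(1, 1), c(1, 1), c(1, 1)), "undefined")
})

test_that("rm2 metrics penalize scale offsets and match a brute-force oracle", {
  y <- c(1, 2, 3)
  expect_equal(rm2_metrics(y, y)$rm2, 1)
  expect_equal(rm2_metrics(y, y)$delta_rm2, 0)

  yp <- c(1.1, 1.9, 3.2)
  got <- rm2_metrics(y, yp)
  # oracle: both regression lines made explicit with lm()
  oracle_one <- function(obs, prd) {
    r2 <- cor(obs, prd)^2
    r02 <- 1 - sum(residuals(lm(obs ~ prd + 0))^2) / sum((obs - mean(obs))^2)
    r2 * (1 - sqrt(max(r2 - r02, 0)))
  }
  a <- oracle_one(y, yp)
  b <- oracle_one(yp, y)
  expect_equal(got$rm2, (a + b) / 2, tolerance = 1e-12)
  expect_equal(got$delta_rm2, abs(a - b), tolerance = 1e-12)

  # constant shift: correlation stays 1 but rm2 drops below r2
  sh <- rm2_metrics(y, y + 0.8)
  expect_lt(sh$rm2, 1)
  expect_lt(sh$rm2, cor(y, y + 0.8)^2)

  # range scaling changes the metric deterministically and stays in [0, 1]
  sc <- rm2_metrics(y, yp, scaled = TRUE)
  expect_true(sc$rm2 <= 1 && sc$rm2 >= 0)

  expect_error(rm2_metrics(y, rep(1, 3)), "degenerate")
})

test_that("Y-randomization is seeded, destroys shuffled fits and matches Eq. forms", {
  rr <- random_regression(n = 50, p = 3, seed = 41, noise = 0.1)
  r1 <- y_randomization(rr$X, rr$y, colnames(rr$X), n_runs = 30, rng_seed = 5)
  r2 <- y_randomization(rr$X, rr$y, colnames(rr$X), n_runs = 30, rng_seed = 5)
  expect_identical(r1$r2_randomized, r2$r2_randomized)

  # strong signal: randomized fits collapse, cRp2 clears 0.5
  expect_gt(r1$crp2, 0.5)
  expect_lt(r1$mean_rr2, 0.3)

  # the reported value follows the declared variant formula
  expect_equal(r1$crp2, sqrt(r1$r2_original) *
                 (r1$r2_original - r1$mean_rr2))
  rs <- y_randomization(rr$X, rr$y, colnames(rr$X), n_runs = 30,
                        rng_seed = 5, variant = "sqrt")
  expect_equal(rs$crp2, sqrt(rs$r2_original) *
                 sqrt(rs$r2_original - rs$mean_rr2))
})

test_that("validate_model assembles the full battery consistently", {
  g <- generate_mixture_data(recovery_spec(2))
  m <- suppressMessages(drop_degenerate_columns(wm_features(g$dataset)))
  idx <- seq_len(nrow(m$X))
  tr <- wm_subset(m, idx[idx %% 4 != 0])
  te <- wm_subset(m, idx[idx %% 4 == 0])
  model <- fit_mlr(tr$X, tr$y,
                   c(g$truth$spec$true_features, "T_K"))
  rep <- validate_model(model, tr, te, skip_unevaluable = TRUE)
  expect_gt(rep$q2_loo, 0.9)
  expect_true(rep$mae_loo >= 0 && rep$mae_lco >= 0 && rep$mae_test >= 0)
  expect_lte(rep$q2_loo, 1)
  expect_lte(rep$q2_lco, 1)
  # report values agree with the standalone operations
  expect_equal(rep$q2_loo, loo_cv(tr, features = model$features)$q2_loo)
  expect_equal(rep$mae_test,
               external_metrics(tr$y, te$y, predict(model, te))$mae_test)
})
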