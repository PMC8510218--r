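# Internal and external validation battery: LOO and leave-chemical-out
# cross-validation, external prediction metrics, rm2 metrics, %AARD and
# Y-randomization.

#' Leave-one-out cross-validation of a fixed descriptor set
#'
#' Each training point is predicted by the model refit without it (the
#' exact hat-matrix identity is used; it equals the naive refit loop for
#' OLS).  Reports
#' \eqn{Q^2_{LOO} = 1 - \sum(y - \hat y_{(-i)})^2 / \sum(y - \bar y)^2}
#' and \eqn{MAE_{LOO} = \frac{1}{n}\sum |y - \hat y_{(-i)}|}.
#'
#' @param X numeric feature matrix (training rows) or a \code{wm_matrix}.
#' @param y training response (ignored when \code{X} is a
#'   \code{wm_matrix}).
#' @param features descriptor column names (frozen; no reselection).
#' @return list with \code{q2_loo}, \code{mae_loo} and the per-record
#'   \code{predictions}.
#' @export
loo_cv <- function(X, y = NULL, features) {
  if (inherits(X, "wm_matrix")) {
    y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  n <- length(y)
  if (n <= length(features) + 2) {
    stop("need n > p + 2 training rows for leave-one-out", call. = FALSE)
  }
  loo <- ols_loo(X[, features, drop = FALSE], y)
  list(q2_loo = 1 - sum(loo$errors^2) / sum((y - mean(y))^2),
       mae_loo = mean(abs(loo$errors)),
       predictions = loo$predictions)
}

#' Leave-chemical-out cross-validation
#'
#' Two passes over the training set.  Component-1 pass: for each unique
#' component-1 chemical (HBA), all its records are removed, the model is
#' refit on the remainder with the same descriptor set, and the removed
#' records are predicted.  The component-2 (HBD) pass is analogous.  Each
#' pass predicts every training record exactly once.  With \eqn{Y_m} the
#' full training-set mean (fixed across removals) and \eqn{N} the number of
#' training points,
#' \deqn{Q^2_{LCO} = \frac{1}{2}\left[\left(1 - \frac{\sum_i (Y_i -
#'   \hat Y_{L(HBA)O})^2}{\sum_i (Y_i - Y_m)^2}\right) + \left(1 -
#'   \frac{\sum_i (Y_i - \hat Y_{L(HBD)O})^2}{\sum_i (Y_i -
#'   Y_m)^2}\right)\right]}
#' \deqn{MAE_{LCO} = \frac{1}{2}\left[\frac{\sum_i |Y_i -
#'   \hat Y_{L(HBA)O}|}{N} + \frac{\sum_i |Y_i - \hat Y_{L(HBD)O}|}{N}\right]}
#' A large gap between the LOO and LCO metrics indicates the fit depends on
#' individual chemicals rather than on transferable structure.
#'
#' @param m a \code{wm_matrix} of the training rows (its \code{meta}
#'   supplies the component ids).
#' @param features descriptor column names (frozen).
#' @param skip_unevaluable if \code{TRUE}, chemicals whose removal leaves
#'   fewer than \code{length(features) + 2} records (or a rank-deficient
#'   refit) are skipped and reported instead of raising an error; the
#'   affected pass then averages over the records it could predict.
#' @return list with \code{q2_lco}, \code{mae_lco} and a \code{detail} list
#'   (per-pass predictions, skipped chemicals, \code{ym}, \code{n}).
#' @export
lco_cv <- function(m, features, skip_unevaluable = FALSE) {
  stopifnot(inherits(m, "wm_matrix"))
  X <- m$X
  y <- m$y
  n <- length(y)
  p <- length(features)
  ym <- mean(y)

  one_pass <- function(ids, slot) {
    pred <- rep(NA_real_, n)
    skipped <- character(0)
    for (ch in unique(ids)) {
      out <- which(ids == ch)
      inn <- which(ids != ch)
      fit <- if (length(inn) >= p + 2) {
        tryCatch(ols_fit(X[inn, features, drop = FALSE], y[inn]),
                 error = function(e) NULL)
      }
      if (is.null(fit)) {
        if (!skip_unevaluable) {
          stop("leave-chemical-out removal of ", slot, " chemical '", ch,
               "' leaves an unevaluable refit", call. = FALSE)
        }
        skipped <- c(skipped, ch)
        next
      }
      pred[out] <- drop(cbind(1, X[out, features, drop = FALSE]) %*% fit$beta)
    }
    ok <- !is.na(pred)
    list(predictions = pred, skipped = skipped,
         q2 = 1 - sum((y[ok] - pred[ok])^2) / sum((y[ok] - ym)^2),
         mae = sum(abs(y[ok] - pred[ok])) / sum(ok))
  }

  p1 <- one_pass(m$meta$comp1_id, "component-1")
  p2 <- one_pass(m$meta$comp2_id, "component-2")
  list(q2_lco = (p1$q2 + p2$q2) / 2,
       mae_lco = (p1$mae + p2$mae) / 2,
       detail = list(comp1 = p1, comp2 = p2, ym = ym, n = n))
}

#' External (test-set) prediction metrics
#'
#' \eqn{R^2_{pred}} (also written \eqn{Q^2_{F1}}) is
#' \eqn{1 - \sum(y_{test} - \hat y)^2 / \sum(y_{test} - \bar y_{train})^2};
#' note the denominator centers on the \emph{training} mean, so the
#' constant \eqn{\bar y_{train}} predictor scores exactly 0.
#' \eqn{\%AARD = \frac{100}{n}\sum |y - \hat y| / y}.
#'
#' @param y_train training response (only its mean is used).
#' @param y_test,yhat_test observed and predicted test responses.
#' @return list with \code{r2_pred}, \code{mae_test}, \code{aard_pct}.
#' @export
external_metrics <- function(y_train, y_test, yhat_test) {
  stopifnot(length(y_test) == length(yhat_test), length(y_test) >= 1)
  denom <- sum((y_test - mean(y_train))^2)
  if (denom == 0) {
    stop("test responses show no variance around the training mean; ",
         "R2_pred is undefined", call. = FALSE)
  }
  if (any(y_test <= 0)) {
    stop("%AARD requires strictly positive observed values", call. = FALSE)
  }
  err <- y_test - yhat_test
  list(r2_pred = 1 - sum(err^2) / denom,
       mae_test = mean(abs(err)),
       aard_pct = 100 * mean(abs(err) / y_test))
}

# One direction of the rm2 computation: r2 is the squared Pearson
# correlation; r02 the determination coefficient of the least-squares line
# of y on x forced through the origin.
rm2_one <- function(y, x) {
  r2 <- cor(y, x)^2
  k <- sum(x * y) / sum(x * x)
  r02 <- 1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
  rad <- r2 - r02
  clamped <- rad < 0
  if (clamped) rad <- 0
  list(rm2 = r2 * (1 - sqrt(rad)), r2 = r2, r02 = r02, clamped = clamped)
}

#' rm2 predictivity metrics
#'
#' Based on the observed-vs-predicted regression lines with and without
#' intercept: \eqn{r_m^2 = r^2 (1 - \sqrt{r^2 - r_0^2})}, where \eqn{r^2}
#' is the squared correlation and \eqn{r_0^2} the determination coefficient
#' of the through-origin line.  Both directions (observed on predicted and
#' the reverse) are computed; the average and the absolute difference
#' \eqn{\Delta r_m^2} are reported.  A systematic offset or scaling between
#' observed and predicted values depresses \eqn{r_0^2} and hence
#' \eqn{r_m^2} even when the correlation is high.  Negative radicands
#' (possible numerically) are clamped at zero and flagged.
#'
#' @param y_obs,y_pred observed and predicted values (at least 3 points,
#'   non-degenerate variance).
#' @param scaled if \code{TRUE}, both vectors are first range-scaled to
#'   [0, 1] using the observed minimum and maximum.
#' @return list with \code{rm2} (average), \code{delta_rm2},
#'   the directional \code{rm2_fwd} / \code{rm2_rev}, and \code{clamped}.
#' @export
rm2_metrics <- function(y_obs, y_pred, scaled = FALSE) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3)
  if (sd(y_obs) == 0 || sd(y_pred) == 0) {
    stop("rm2 metrics undefined for degenerate (constant) vectors",
         call. = FALSE)
  }
  if (scaled) {
    lo <- min(y_obs)
    hi <- max(y_obs)
    y_obs <- (y_obs - lo) / (hi - lo)
    y_pred <- (y_pred - lo) / (hi - lo)
  }
  fwd <- rm2_one(y_obs, y_pred)
  rev <- rm2_one(y_pred, y_obs)
  list(rm2 = (fwd$rm2 + rev$rm2) / 2,
       delta_rm2 = abs(fwd$rm2 - rev$rm2),
       rm2_fwd = fwd$rm2, rm2_rev = rev$rm2,
       clamped = fwd$clamped || rev$clamped)
}

#' Y-randomization (response scrambling) robustness check
#'
#' The response is shuffled \code{n_runs} times; the model is refit on the
#' \emph{same} descriptor set each time and the randomized determination
#' coefficients \eqn{R_r^2} collected.  The robustness metric is
#' \eqn{{}^cR_P^2 = R (R^2 - \bar R_r^2)} with \eqn{R = \sqrt{R^2}}
#' (variant \code{"as_printed"}); the literature variant
#' \eqn{R \sqrt{R^2 - \bar R_r^2}} is available as \code{variant = "sqrt"}.
#' Values above 0.5 indicate the original fit is unlikely to be chance.
#'
#' @param X numeric feature matrix (training rows) or \code{wm_matrix}.
#' @param y training response (ignored for a \code{wm_matrix}).
#' @param features descriptor column names (frozen).
#' @param n_runs number of randomized refits (default 100).
#' @param rng_seed seed for the shuffles (bit-reproducible).
#' @param variant which cRp2 formula to report.
#' @return Object of class \code{randomization_report}: \code{n_runs},
#'   \code{r2_original}, per-run \code{r2_randomized}, \code{mean_rr2},
#'   \code{crp2} and \code{variant}.
#' @export
y_randomization <- function(X, y = NULL, features, n_runs = 100,
                            rng_seed = 1, variant = c("as_printed", "sqrt")) {
  variant <- match.arg(variant)
  stopifnot(n_runs >= 1)
  if (inherits(X, "wm_matrix")) {
    y <- X$y
    X <- X$X
  }
  Xs <- as.matrix(X)[, features, drop = FALSE]
  r2 <- r2_of_fit(y, ols_fit(Xs, y)$fitted)
  rr2 <- with_seed(rng_seed, vapply(seq_len(n_runs), function(i) {
    ys <- sample(y)
    r2_of_fit(ys, ols_fit(Xs, ys)$fitted)
  }, numeric(1)))
  m <- mean(rr2)
  crp2 <- switch(variant,
    as_printed = sqrt(r2) * (r2 - m),
    sqrt = sqrt(r2) * sqrt(max(r2 - m, 0)))
  structure(list(n_runs = n_runs, r2_original = r2, r2_randomized = rr2,
                 mean_rr2 = m, crp2 = crp2, variant = variant),
            class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf(
    "Y-randomization (%d runs): R2 = %.4f, mean Rr2 = %.4f, cRp2 = %.4f (%s)\n",
    x$n_runs, x$r2_original, x$mean_rr2, x$crp2, x$variant))
  invisible(x)
}

#' Assemble the full validation report for a fitted model
#'
#' Convenience wrapper running \code{\link{loo_cv}}, \code{\link{lco_cv}},
#' \code{\link{external_metrics}} and \code{\link{rm2_metrics}} for a
#' model on its training rows and (optionally) a test set.
#'
#' @param model a \code{mix_mlr}.
#' @param train_m \code{wm_matrix} of the training rows the model was fit
#'   on.
#' @param test_m optional \code{wm_matrix} of test rows.
#' @param skip_unevaluable passed to \code{\link{lco_cv}}.
#' @param rm2_scaled passed to \code{\link{rm2_metrics}}.
#' @return Object of class \code{validation_report}: a list of the metric
#'   battery (\code{q2_loo}, \code{mae_loo}, \code{q2_lco},
#'   \code{mae_lco}, \code{r2_pred}, \code{mae_test},
#'   \code{aard_train_pct}, \code{aard_test_pct}, \code{rm2_loo},
#'   \code{delta_rm2_loo}, \code{rm2_test}, \code{delta_rm2_test}) plus
#'   per-record predictions.
#' @export
validate_model <- function(model, train_m, test_m = NULL,
                           skip_unevaluable = FALSE, rm2_scaled = FALSE) {
  stopifnot(inherits(model, "mix_mlr"), inherits(train_m, "wm_matrix"))
  feats <- model$features
  loo <- loo_cv(train_m, features = feats)
  lco <- lco_cv(train_m, feats, skip_unevaluable = skip_unevaluable)
  fitted_train <- predict(model, train_m)
  rm2_loo <- rm2_metrics(train_m$y, loo$predictions, scaled = rm2_scaled)
  rep <- list(
    q2_loo = loo$q2_loo, mae_loo = loo$mae_loo,
    q2_lco = lco$q2_lco, mae_lco = lco$mae_lco,
    aard_train_pct = 100 * mean(abs(train_m$y - fitted_train) / train_m$y),
    rm2_loo = rm2_loo$rm2, delta_rm2_loo = rm2_loo$delta_rm2,
    loo_predictions = loo$predictions,
    lco_detail = lco$detail)
  if (!is.null(test_m)) {
    pred <- predict(model, test_m)
    ext <- external_metrics(train_m$y, test_m$y, pred)
    rm2_test <- rm2_metrics(test_m$y, pred, scaled = rm2_scaled)
    rep <- c(rep, list(
      r2_pred = ext$r2_pred, mae_test = ext$mae_test,
      aard_test_pct = ext$aard_pct,
      rm2_test = rm2_test$rm2, delta_rm2_test = rm2_test$delta_rm2,
      test_predictions = pred))
  }
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("internal: Q2_LOO = %.4f, MAE_LOO = %.4g, Q2_LCO = %.4f, MAE_LCO = %.4g\n",
              x$q2_loo, x$mae_loo, x$q2_lco, x$mae_lco))
  cat(sprintf("          rm2_LOO = %.4f, delta rm2_LOO = %.4f, %%AARD_train = %.3f\n",
              x$rm2_loo, x$delta_rm2_loo, x$aard_train_pct))
  if (!is.null(x$r2_pred)) {
    cat(sprintf("external: R2_pred = %.4f, MAE_test = %.4g, rm2_test = %.4f, delta rm2_test = %.4f, %%AARD_test = %.3f\n",
                x$r2_pred, x$mae_test, x$rm2_test, x$delta_rm2_test,
                x$aard_test_pct))
  }
  invisible(x)
}
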