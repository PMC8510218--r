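# Correlation prefilter, scoring functions, sequential forward selection
# MLR with the %MAE_LOO-reduction stopping rule, and final OLS fitting.

#' Configuration for sequential forward selection
#'
#' @param scoring candidate-ranking criterion: determination coefficient
#'   \code{"R2"}, negative mean absolute error \code{"NMAE"}, or negative
#'   mean Poisson deviance \code{"NMPD"} (higher is always better).
#' @param cv_folds 0 for no cross-validation (candidates scored in-sample
#'   on the training rows) or a fold count (5 and 10 are the conventional
#'   choices); folds are contiguous blocks of a seeded permutation.
#' @param max_steps maximum number of descriptors (default 10).
#' @param pct_mae_reduction a candidate is accepted only if it lowers
#'   MAE_LOO by at least this percentage relative to the current model
#'   (default 5); on the first rejection selection stops.
#' @param corr_cutoff absolute Pearson correlation above which one of a
#'   descriptor pair is removed before selection (default 0.95).
#' @param cv_seed seed for the fold-assignment permutation.
#' @return An object of class \code{sfs_config}.
#' @export
sfs_config <- function(scoring = c("R2", "NMAE", "NMPD"), cv_folds = 0,
                       max_steps = 10, pct_mae_reduction = 5,
                       corr_cutoff = 0.95, cv_seed = 1) {
  scoring <- match.arg(toupper(scoring[1]), c("R2", "NMAE", "NMPD"))
  stopifnot(cv_folds == 0 || cv_folds >= 2,
            max_steps >= 1,
            pct_mae_reduction >= 0,
            corr_cutoff > 0, corr_cutoff <= 1)
  structure(list(scoring = scoring, cv_folds = as.integer(cv_folds),
                 max_steps = as.integer(max_steps),
                 pct_mae_reduction = pct_mae_reduction,
                 corr_cutoff = corr_cutoff,
                 cv_seed = as.integer(cv_seed)),
            class = "sfs_config")
}

#' Remove highly intercorrelated descriptors
#'
#' Greedy scan in column order: a column is dropped as soon as its absolute
#' Pearson correlation with any earlier retained column exceeds
#' \code{corr_cutoff} (i.e. the later member of an offending pair loses).
#' After filtering no remaining pair exceeds the cutoff, and the result is
#' deterministic for a given column order.
#'
#' @param X numeric feature matrix (training rows).
#' @param corr_cutoff absolute correlation threshold (default 0.95).
#' @return list with the reduced matrix \code{X} and a \code{removed}
#'   data.frame (column, the retained column it correlated with, r).
#' @export
prefilter_correlated <- function(X, corr_cutoff = 0.95) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(list(X = X, removed = NULL))
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop("constant column(s) have undefined correlation: ",
         paste(colnames(X)[sds == 0], collapse = ", "),
         "; apply drop_degenerate_columns() first", call. = FALSE)
  }
  C <- abs(cor(X))
  keep <- 1L
  removed <- list()
  for (j in 2:ncol(X)) {
    hits <- keep[C[j, keep] > corr_cutoff]
    if (length(hits)) {
      removed[[length(removed) + 1L]] <-
        data.frame(removed = colnames(X)[j],
                   correlated_with = colnames(X)[hits[1]],
                   r = C[j, hits[1]])
    } else {
      keep <- c(keep, j)
    }
  }
  list(X = X[, keep, drop = FALSE],
       removed = if (length(removed)) do.call(rbind, removed) else NULL)
}

#' Scoring functions for candidate ranking
#'
#' All scores are oriented so that higher is better: \code{R2}
#' \eqn{= 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}; \code{NMAE}
#' \eqn{= -\frac{1}{n}\sum|y-\hat y|}; \code{NMPD}
#' \eqn{= -\frac{1}{n}\sum 2[y \ln(y/\hat y) - y + \hat y]} (both vectors
#' must be strictly positive).
#'
#' @param y_true,y_pred numeric vectors of equal length (at least 2).
#' @param scoring one of \code{"R2"}, \code{"NMAE"}, \code{"NMPD"}.
#' @return A scalar score.
#' @export
score_predictions <- function(y_true, y_pred,
                              scoring = c("R2", "NMAE", "NMPD")) {
  scoring <- match.arg(toupper(scoring[1]), c("R2", "NMAE", "NMPD"))
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  switch(scoring,
    R2 = 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2),
    NMAE = -mean(abs(y_true - y_pred)),
    NMPD = {
      if (any(y_true <= 0) || any(y_pred <= 0)) {
        stop("NMPD requires strictly positive observed and predicted values",
             call. = FALSE)
      }
      -mean(2 * (y_true * log(y_true / y_pred) - y_true + y_pred))
    })
}

# Contiguous-block fold ids on a seeded permutation.
make_folds <- function(n, k, seed) {
  perm <- with_seed(seed, sample.int(n))
  bounds <- round(seq(0, n, length.out = k + 1))
  id <- integer(n)
  for (b in seq_len(k)) {
    id[perm[(bounds[b] + 1):bounds[b + 1]]] <- b
  }
  id
}

# Score a candidate feature set under the configured CV scheme.
cv_score <- function(X, y, cols, config, fold_id) {
  Xs <- X[, cols, drop = FALSE]
  if (config$cv_folds == 0) {
    f <- ols_fit(Xs, y)
    return(score_predictions(y, f$fitted, config$scoring))
  }
  scores <- vapply(seq_len(config$cv_folds), function(b) {
    inn <- fold_id != b
    f <- ols_fit(Xs[inn, , drop = FALSE], y[inn])
    pred <- drop(cbind(1, Xs[!inn, , drop = FALSE]) %*% f$beta)
    score_predictions(y[!inn], pred, config$scoring)
  }, numeric(1))
  mean(scores)
}

loo_mae_of <- function(X, y, cols) {
  mean(abs(ols_loo(X[, cols, drop = FALSE], y)$errors))
}

#' Sequential forward selection MLR
#'
#' Greedy forward selection: at each step the candidate descriptor that
#' maximizes the configured score (in-sample, or mean out-of-fold score
#' under k-fold CV) is proposed; the proposal is accepted only if the
#' leave-one-out MAE of the grown model is at most
#' \code{(1 - pct_mae_reduction/100)} times that of the current model.
#' The reference for the first step is the intercept-only model, whose LOO
#' prediction for each left-out point is the mean of the remaining
#' responses.  The first rejection terminates selection; at most
#' \code{max_steps} descriptors are accepted.  Ties between equally scoring
#' candidates go to the lower column index.  Setting
#' \code{pct_mae_reduction = 0} disables the stopping rule entirely, so
#' selection reduces to plain greedy forward selection truncated only by
#' \code{max_steps}.
#'
#' @param X numeric feature matrix of the training rows, already passed
#'   through \code{\link{drop_degenerate_columns}} and
#'   \code{\link{prefilter_correlated}}.
#' @param y training response.
#' @param config an \code{\link{sfs_config}}.
#' @return A list with the final \code{model} (\code{\link{fit_mlr}} on the
#'   accepted descriptors; intercept-only with a warning if nothing is
#'   accepted), the accepted \code{features} in selection order, and a
#'   per-step \code{trace} data.frame (candidate, score, MAE_LOO before and
#'   after, accepted flag).
#' @export
sfs_mlr <- function(X, y, config = sfs_config()) {
  stopifnot(inherits(config, "sfs_config"))
  X <- as.matrix(X)
  if (length(y) <= config$max_steps + 1) {
    stop("need more training rows than max_steps + 1", call. = FALSE)
  }
  fold_id <- if (config$cv_folds > 0) {
    make_folds(length(y), config$cv_folds, config$cv_seed)
  }
  selected <- character(0)
  mae_cur <- loo_mae_of(X, y, character(0))  # intercept-only baseline
  trace <- list()
  while (length(selected) < config$max_steps) {
    candidates <- setdiff(colnames(X), selected)
    if (!length(candidates)) break
    scores <- vapply(candidates, function(f) {
      tryCatch(cv_score(X, y, c(selected, f), config, fold_id),
               error = function(e) -Inf)
    }, numeric(1))
    best <- candidates[which.max(scores)]  # first max = lowest column index
    mae_new <- tryCatch(loo_mae_of(X, y, c(selected, best)),
                        error = function(e) Inf)
    accepted <- (config$pct_mae_reduction == 0 && is.finite(mae_new)) ||
      mae_new <= (1 - config$pct_mae_reduction / 100) * mae_cur
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L, candidate = best,
      score = scores[[best]], mae_loo_before = mae_cur,
      mae_loo_after = mae_new, accepted = accepted)
    if (!accepted) break
    selected <- c(selected, best)
    mae_cur <- mae_new
  }
  if (!length(selected)) {
    warning("no descriptor met the %MAE_LOO reduction criterion; ",
            "returning the intercept-only model", call. = FALSE)
  }
  list(model = fit_mlr(X, y, selected),
       features = selected,
       trace = do.call(rbind, trace),
       config = config)
}

#' Fit a multiple linear regression on a fixed descriptor set
#'
#' Ordinary least squares via \code{\link[stats]{lm}}.  Reports
#' coefficients with standard errors, \eqn{R^2}, adjusted \eqn{R^2}, the
#' overall F statistic, the residual standard error, and the maximum
#' absolute pairwise correlation among the selected descriptors ("Max
#' Inc"), which flags collinear models.
#'
#' @param X numeric feature matrix (training rows).
#' @param y training response.
#' @param features character vector of column names to use (may be empty
#'   for an intercept-only model).
#' @return Object of class \code{mix_mlr}.
#' @export
fit_mlr <- function(X, y, features) {
  X <- as.matrix(X)
  missing_cols <- setdiff(features, colnames(X))
  if (length(missing_cols)) {
    stop("feature column(s) absent from the matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- length(y)
  p <- length(features)
  if (n <= p + 1) stop("need n > p + 1 training rows", call. = FALSE)
  df <- data.frame(y = y, X[, features, drop = FALSE], check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  max_ic <- if (p >= 2) {
    C <- abs(cor(X[, features, drop = FALSE]))
    max(C[upper.tri(C)])
  } else 0
  structure(list(
    features = features,
    coefficients = coef(fit),
    se = sm$coefficients[, "Std. Error"],
    n_train = n,
    r2 = sm$r.squared,
    r2_adj = sm$adj.r.squared,
    f_statistic = if (!is.null(sm$fstatistic)) sm$fstatistic else
      c(value = NA_real_, numdf = 0, dendf = n - 1),
    sigma = sm$sigma,
    max_intercorrelation = max_ic,
    fitted = unname(fitted(fit)),
    residuals = unname(residuals(fit)),
    y = y
  ), class = "mix_mlr")
}

#' Predict from a fitted mixture MLR model
#'
#' @param object a \code{mix_mlr}.
#' @param newdata a \code{wm_matrix} or numeric matrix containing all model
#'   feature columns.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mix_mlr <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "wm_matrix")) newdata$X else as.matrix(newdata)
  missing_cols <- setdiff(object$features, colnames(X))
  if (length(missing_cols)) {
    stop("prediction matrix is missing feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  b <- object$coefficients
  drop(X[, object$features, drop = FALSE] %*% b[object$features]) + b[1]
}

#' @export
print.mix_mlr <- function(x, digits = 4, ...) {
  cat("mixture MLR:", length(x$features), "descriptors, n =", x$n_train, "\n")
  terms <- sprintf("%+.*f(±%.*f) %s", digits, x$coefficients,
                   digits, x$se, c("", x$features))
  cat("  y =", paste(terms, collapse = " "), "\n")
  cat(sprintf("  R2 = %.4f, adj R2 = %.4f, max intercorrelation = %.3f\n",
              x$r2, x$r2_adj, x$max_intercorrelation))
  invisible(x)
}
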