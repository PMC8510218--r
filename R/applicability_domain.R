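# Leverage / standardized-residual (Williams plot) applicability domain
# and Euclidean similarity thresholds.

#' Leverage warning threshold
#'
#' \eqn{h^* = 3(p + 1)/n}, the conventional cut-off above which a record is
#' considered a structural outlier (outside the model's applicability
#' domain).
#'
#' @param n_train number of training records.
#' @param p number of model descriptors.
#' @return The scalar threshold.
#' @export
leverage_threshold <- function(n_train, p) {
  stopifnot(n_train > p + 1)
  3 * (p + 1) / n_train
}

#' Leverages with respect to a training design
#'
#' \eqn{h(x) = x (X^T X)^{-1} x^T} with \eqn{x} intercept-augmented and
#' \eqn{X} the intercept-augmented training design.  For the training rows
#' themselves these are the hat-matrix diagonals, which sum to \eqn{p + 1}.
#'
#' @param train numeric matrix of training feature values (no intercept
#'   column).
#' @param query optional matrix of query rows in the same feature space;
#'   if omitted, training leverages are returned.
#' @return Numeric vector of leverages.
#' @export
leverages <- function(train, query = NULL) {
  X1 <- cbind(1, as.matrix(train))
  XtX <- crossprod(X1)
  XtXinv <- tryCatch(solve(XtX), error = function(e) {
    stop("singular training design; cannot compute leverages", call. = FALSE)
  })
  Q1 <- if (is.null(query)) X1 else cbind(1, as.matrix(query))
  unname(rowSums((Q1 %*% XtXinv) * Q1))
}

#' Standardized residuals
#'
#' \eqn{SDR_i = (y_i - \hat y_i)/s} with
#' \eqn{s = \sqrt{\sum (y - \hat y)^2 / (n - p - 1)}} the residual standard
#' error.  Records with \eqn{|SDR| > 3} are response outliers.  A perfect
#' fit yields all-zero residuals (s would be 0; SDR is defined as 0 then).
#'
#' @param y,yhat observed and fitted values.
#' @param p number of model descriptors (degrees-of-freedom correction).
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(y, yhat, p) {
  n <- length(y)
  stopifnot(n > p + 1, length(yhat) == n)
  e <- y - yhat
  s <- sqrt(sum(e^2) / (n - p - 1))
  if (s == 0) return(rep(0, n))
  e / s
}

#' Williams-plot data for a fitted model
#'
#' Combines leverages (against the model's training design) and
#' standardized residuals per fold into a tidy, plot-ready table, and
#' counts structural (\eqn{h > h^*}) and response (\eqn{|SDR| > 3})
#' outliers per fold.  Residuals of test/external records are standardized
#' with the training residual standard error, so all folds share one
#' scale.
#'
#' @param model a \code{mix_mlr}.
#' @param train_m \code{wm_matrix} of the training rows the model was fit
#'   on.
#' @param test_m optional \code{wm_matrix} of test or external rows.
#' @return Object of class \code{ad_report}: list with the tidy
#'   \code{table} (record_id, fold, h, sdr, outlier flags), \code{h_star},
#'   the residual scale \code{s}, and per-fold outlier \code{counts}.
#' @export
williams_data <- function(model, train_m, test_m = NULL) {
  stopifnot(inherits(model, "mix_mlr"), inherits(train_m, "wm_matrix"))
  feats <- model$features
  Xtr <- train_m$X[, feats, drop = FALSE]
  n <- nrow(Xtr)
  p <- length(feats)
  h_star <- leverage_threshold(n, p)
  e_tr <- train_m$y - predict(model, train_m)
  s <- sqrt(sum(e_tr^2) / (n - p - 1))
  sdr_of <- function(e) if (s == 0) rep(0, length(e)) else e / s

  tab <- data.frame(record_id = train_m$meta$record_id, fold = "train",
                    h = leverages(Xtr), sdr = sdr_of(e_tr),
                    stringsAsFactors = FALSE)
  if (!is.null(test_m)) {
    e_te <- test_m$y - predict(model, test_m)
    tab <- rbind(tab, data.frame(
      record_id = test_m$meta$record_id, fold = "test",
      h = leverages(Xtr, test_m$X[, feats, drop = FALSE]),
      sdr = sdr_of(e_te), stringsAsFactors = FALSE))
  }
  tab$is_structural_outlier <- tab$h > h_star
  tab$is_response_outlier <- abs(tab$sdr) > 3
  counts <- aggregate(cbind(n_structural = is_structural_outlier,
                            n_response = is_response_outlier) ~ fold,
                      data = tab, FUN = sum)
  structure(list(table = tab, h_star = h_star, s = s, p = p, n_train = n,
                 counts = counts), class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("applicability domain: h* = %.4f (n = %d, p = %d)\n",
              x$h_star, x$n_train, x$p))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Euclidean similarity threshold over a training set
#'
#' Pairwise Euclidean distances are computed on the z-scored (training
#' mean/sd per column, sample sd) feature space; columns with zero variance
#' are excluded with a note.  The threshold for "structurally similar" is
#' mean + 3 * SD of the pairwise distances (sample standard deviation).
#'
#' @param train numeric matrix of training feature values.
#' @return list with \code{mean_distance}, \code{sd_distance},
#'   \code{threshold}, and the scaling statistics (\code{center},
#'   \code{scale}, \code{kept} columns) needed to place query points in the
#'   same space.
#' @export
similarity_threshold <- function(train) {
  X <- as.matrix(train)
  if (nrow(X) < 2) stop("need at least 2 training rows", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  kept <- sdv > 0
  if (any(!kept)) {
    message("excluding zero-variance column(s) from similarity space: ",
            paste(colnames(X)[!kept], collapse = ", "))
  }
  d <- if (any(kept)) {
    Z <- scale(X[, kept, drop = FALSE], center = mu[kept], scale = sdv[kept])
    as.numeric(dist(Z))
  } else {
    rep(0, choose(nrow(X), 2))
  }
  m <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  list(mean_distance = m, sd_distance = s, threshold = m + 3 * s,
       center = mu, scale = sdv, kept = kept)
}
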