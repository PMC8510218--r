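# Intelligent consensus prediction over an ensemble of fitted models
# (CM0-CM3).

#' Bundle a fitted model with its training rows for consensus prediction
#'
#' Consensus methods need, per member, the model itself plus its own
#' training rows: leave-one-out prediction errors (for the local-quality
#' estimate), the leverage threshold, and the similarity threshold are all
#' member-specific.
#'
#' @param model a \code{mix_mlr}.
#' @param train_m \code{wm_matrix} of the rows the model was trained on.
#' @return Object of class \code{consensus_member}.
#' @export
consensus_member <- function(model, train_m) {
  stopifnot(inherits(model, "mix_mlr"), inherits(train_m, "wm_matrix"))
  structure(list(model = model, train = train_m), class = "consensus_member")
}

#' Predictions of every member model on a feature matrix
#'
#' @param models list of \code{mix_mlr} (or \code{consensus_member})
#'   objects.
#' @param m a \code{wm_matrix} or numeric matrix containing all members'
#'   feature columns.
#' @return Numeric matrix, rows = records, columns = models.
#' @export
predict_members <- function(models, m) {
  stopifnot(length(models) >= 1)
  preds <- vapply(seq_along(models), function(j) {
    mod <- models[[j]]
    if (inherits(mod, "consensus_member")) mod <- mod$model
    tryCatch(predict(mod, m), error = function(e) {
      stop("model ", j, ": ", conditionMessage(e), call. = FALSE)
    })
  }, numeric(if (inherits(m, "wm_matrix")) nrow(m$X) else nrow(m)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  colnames(preds) <- paste0("model", seq_along(models))
  preds
}

# z-score rows into a member's similarity space (its own training
# statistics over the given feature union; zero-variance columns excluded).
member_space <- function(member, space_features) {
  Xtr <- member$train$X[, space_features, drop = FALSE]
  st <- similarity_threshold(Xtr)
  kept <- names(st$center)[st$kept]
  list(Z_train = scale(Xtr[, kept, drop = FALSE],
                       center = st$center[kept], scale = st$scale[kept]),
       center = st$center[kept], scale = st$scale[kept], kept = kept,
       threshold = st$threshold)
}

#' Local cross-validated quality of one model around one test record
#'
#' Finds the \code{n_similar} training records nearest to the test record
#' (Euclidean distance in the z-scored \code{space_features} space, scaled
#' by the member's training statistics) and returns the mean absolute
#' leave-one-out error of the member's model over those records.
#'
#' @param member a \code{\link{consensus_member}}.
#' @param test_row single-row numeric matrix (or vector named by feature)
#'   of the test record.
#' @param n_similar neighborhood size (default 10); if the member has
#'   fewer training records, all are used with a warning.
#' @param space_features feature space for the distance (default: the
#'   member's own model features).
#' @return The scalar mean absolute LOO error over the neighborhood.
#' @export
per_record_model_quality <- function(member, test_row, n_similar = 10,
                                     space_features = NULL) {
  stopifnot(inherits(member, "consensus_member"))
  space_features <- space_features %||% member$model$features
  sp <- member_space(member, space_features)
  loo <- loo_cv(member$train, features = member$model$features)
  abs_err <- abs(member$train$y - loo$predictions)
  x <- matrix(as.numeric(test_row[space_features]), nrow = 1)
  colnames(x) <- space_features
  z <- (x[, sp$kept, drop = FALSE] -
          matrix(sp$center, 1)) / matrix(sp$scale, 1)
  d <- sqrt(rowSums((sp$Z_train - matrix(z, nrow(sp$Z_train),
                                         length(z), byrow = TRUE))^2))
  if (n_similar > length(d)) {
    warning("fewer training records than n_similar; using all",
            call. = FALSE)
    n_similar <- length(d)
  }
  nn <- order(d)[seq_len(n_similar)]
  mean(abs_err[nn])
}

#' Consensus prediction configuration
#'
#' @param members list of \code{\link{consensus_member}} objects (at least
#'   2 for CM0--CM2, at least 1 for CM3).
#' @param method \code{"CM0"} (plain average over all members),
#'   \code{"CM1"} (average over qualified members), \code{"CM2"} (weighted
#'   average over qualified members, weights proportional to the inverse of
#'   the local cross-validated MAE), or \code{"CM3"} (per-record best
#'   member by local cross-validated MAE).
#' @param n_similar neighborhood size for the local quality estimate
#'   (default 10).
#' @return Object of class \code{consensus_config}.
#' @details A member is \emph{qualified} for a test record when the record
#'   lies inside the member's leverage applicability domain
#'   (\eqn{h \le h^*}) \emph{and} its distance to the member's nearest
#'   training record does not exceed the member's mean + 3 SD similarity
#'   threshold.  If no member qualifies for a record, all members are used
#'   as a fallback (flagged in the result).
#' @export
consensus_config <- function(members, method = c("CM0", "CM1", "CM2", "CM3"),
                             n_similar = 10) {
  method <- match.arg(toupper(method[1]), c("CM0", "CM1", "CM2", "CM3"))
  stopifnot(length(members) >= if (method == "CM3") 1 else 2,
            all(vapply(members, inherits, TRUE, "consensus_member")),
            n_similar >= 1)
  structure(list(members = members, method = method,
                 n_similar = as.integer(n_similar)),
            class = "consensus_config")
}

#' Intelligent consensus prediction
#'
#' Combines the member models' predictions on a test set according to the
#' configured method (see \code{\link{consensus_config}}).  All consensus
#' predictions are convex combinations of the contributing members'
#' predictions.  External metrics of the consensus predictions are
#' computed against \code{y_train_ref} (defaults to the first member's
#' training response).
#'
#' @param config a \code{\link{consensus_config}}.
#' @param test_m \code{wm_matrix} of test records.
#' @param y_train_ref reference training response for
#'   \code{\link{external_metrics}}.
#' @return Object of class \code{consensus_result}: per-record table
#'   (consensus prediction, number of qualified members, CM3 choice),
#'   member \code{predictions}, \code{qualified} and \code{weights}
#'   matrices, \code{cv_mae_similar} matrix, and the external
#'   \code{metrics}.
#' @export
consensus_predict <- function(config, test_m, y_train_ref = NULL) {
  stopifnot(inherits(config, "consensus_config"),
            inherits(test_m, "wm_matrix"))
  members <- config$members
  n_members <- length(members)
  n_test <- nrow(test_m$X)
  space_features <- sort(unique(unlist(
    lapply(members, function(mb) mb$model$features))))

  P <- predict_members(members, test_m)
  Q <- matrix(FALSE, n_test, n_members)
  CMAE <- matrix(NA_real_, n_test, n_members)

  for (j in seq_len(n_members)) {
    mb <- members[[j]]
    feats <- mb$model$features
    Xtr <- mb$train$X[, feats, drop = FALSE]
    h_star <- leverage_threshold(nrow(Xtr), length(feats))
    h <- leverages(Xtr, test_m$X[, feats, drop = FALSE])

    sp <- member_space(mb, space_features)
    Zq <- scale(test_m$X[, sp$kept, drop = FALSE],
                center = sp$center, scale = sp$scale)
    # test x train distance matrix in the member's z-scored space
    D2 <- outer(rowSums(Zq^2), rowSums(sp$Z_train^2), "+") -
      2 * Zq %*% t(sp$Z_train)
    D <- sqrt(pmax(D2, 0))
    Q[, j] <- (h <= h_star) & (apply(D, 1, min) <= sp$threshold)

    loo <- loo_cv(mb$train, features = feats)
    abs_err <- abs(mb$train$y - loo$predictions)
    k <- min(config$n_similar, ncol(D))
    if (k < config$n_similar) {
      warning("member ", j, ": fewer training records than n_similar; ",
              "using all", call. = FALSE)
    }
    CMAE[, j] <- apply(D, 1, function(d) {
      mean(abs_err[order(d)[seq_len(k)]])
    })
  }

  fallback <- rowSums(Q) == 0
  Quse <- Q
  Quse[fallback, ] <- TRUE

  W <- matrix(0, n_test, n_members)
  chosen <- rep(NA_integer_, n_test)
  pred <- numeric(n_test)
  for (i in seq_len(n_test)) {
    q <- which(Quse[i, ])
    pred[i] <- switch(config$method,
      CM0 = mean(P[i, ]),
      CM1 = mean(P[i, q]),
      CM2 = {
        cm <- CMAE[i, q]
        # ties at (numerically) zero local error share the weight evenly
        zero <- cm < 1e-12
        w <- if (any(zero)) as.numeric(zero) else 1 / cm
        w <- w / sum(w)
        W[i, q] <- w
        sum(w * P[i, q])
      },
      CM3 = {
        chosen[i] <- q[which.min(CMAE[i, q])]
        P[i, chosen[i]]
      })
  }

  y_train_ref <- y_train_ref %||% members[[1]]$train$y
  metrics <- tryCatch({
    ext <- external_metrics(y_train_ref, test_m$y, pred)
    rm2 <- rm2_metrics(test_m$y, pred)
    c(ext, list(rm2_test = rm2$rm2, delta_rm2_test = rm2$delta_rm2))
  }, error = function(e) NULL)

  structure(list(
    method = config$method,
    table = data.frame(record_id = test_m$meta$record_id,
                       prediction = pred,
                       n_qualified = rowSums(Q),
                       used_fallback = fallback,
                       chosen_member = chosen,
                       stringsAsFactors = FALSE),
    predictions = P, qualified = Q, weights = W,
    cv_mae_similar = CMAE, metrics = metrics
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus %s over %d members, %d test records\n",
              x$method, ncol(x$predictions), nrow(x$table)))
  if (!is.null(x$metrics)) {
    cat(sprintf("  R2_pred = %.4f, MAE_test = %.4g, %%AARD = %.3f, rm2 = %.4f (delta %.4f)\n",
                x$metrics$r2_pred, x$metrics$mae_test, x$metrics$aard_pct,
                x$metrics$rm2_test, x$metrics$delta_rm2_test))
  }
  invisible(x)
}
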