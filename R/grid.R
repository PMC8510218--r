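# End-to-end driver: featurize -> enumerate splits -> train per
# (scoring, CV, seed, interval) -> validate -> rank.

#' Train and validate models over a split/configuration grid
#'
#' Runs the full workflow: build weighted-mixture features, enumerate
#' mixtures-out and/or compounds-out splits over the (seed, interval) grid,
#' and for every retained split and every (scoring, cv) combination run the
#' correlation prefilter (on the training rows), sequential forward
#' selection, and the validation battery.  Individual model failures are
#' logged and skipped, not fatal.  Model ids are \code{<STRATEGY><seq>} in
#' deterministic grid order (they are this package's own numbering, not
#' comparable across tools).
#'
#' @param dataset a \code{\link{mixture_dataset}}.
#' @param strategies subset of \code{c("MO", "CO")}.
#' @param max_seed,max_interval,min_test_fraction split-grid parameters
#'   (see \code{\link{mo_splits}}).
#' @param scorings,cv_folds vectors of scoring methods and CV fold counts
#'   to cross.
#' @param mode weighted-descriptor mode for \code{\link{wm_features}}.
#' @param max_steps,pct_mae_reduction,corr_cutoff,cv_seed passed to
#'   \code{\link{sfs_config}}.
#' @return Object of class \code{grid_run}: \code{summary} data.frame (one
#'   row per trained model, sorted by ascending MAE_LOO) and \code{models}
#'   (per id: the fitted model, its split, config, and selection trace).
#' @export
run_grid <- function(dataset, strategies = c("MO", "CO"),
                     max_seed = 7, max_interval = 7,
                     min_test_fraction = 0.20,
                     scorings = "R2", cv_folds = 0, mode = "both",
                     max_steps = 10, pct_mae_reduction = 5,
                     corr_cutoff = 0.95, cv_seed = 1) {
  stopifnot(inherits(dataset, "mixture_dataset"),
            all(strategies %in% c("MO", "CO")))
  m <- drop_degenerate_columns(wm_features(dataset, mode = mode))

  rows <- list()
  models <- list()
  for (strategy in strategies) {
    splits <- if (strategy == "MO") {
      mo_splits(dataset, max_seed, max_interval, min_test_fraction)
    } else {
      co_splits(dataset, max_seed, max_interval, min_test_fraction)
    }
    seq_no <- 0L
    for (split in splits) {
      for (sc in scorings) {
        for (cv in cv_folds) {
          seq_no <- seq_no + 1L
          id <- sprintf("%s%d", strategy, seq_no)
          res <- tryCatch({
            tr <- wm_subset(m, split$train_idx)
            te <- wm_subset(m, split$test_idx)
            pf <- prefilter_correlated(tr$X, corr_cutoff)
            cfg <- sfs_config(scoring = sc, cv_folds = cv,
                              max_steps = max_steps,
                              pct_mae_reduction = pct_mae_reduction,
                              corr_cutoff = corr_cutoff, cv_seed = cv_seed)
            sel <- suppressWarnings(sfs_mlr(pf$X, tr$y, cfg))
            model <- sel$model
            rep <- validate_model(model, tr, te, skip_unevaluable = TRUE)
            list(model = model, split = split, config = cfg,
                 trace = sel$trace, report = rep,
                 row = data.frame(
                   model_id = id, strategy = strategy,
                   seed = split$seed, interval = split$interval,
                   scoring = sc, cv = cv,
                   n_train = length(split$train_idx),
                   n_test = length(split$test_idx),
                   n_features = length(model$features),
                   q2_loo = rep$q2_loo, q2_lco = rep$q2_lco,
                   mae_loo = rep$mae_loo, mae_lco = rep$mae_lco,
                   r2_pred = rep$r2_pred, mae_test = rep$mae_test,
                   max_intercorrelation = model$max_intercorrelation,
                   stringsAsFactors = FALSE))
          }, error = function(e) {
            message("model ", id, " failed: ", conditionMessage(e))
            NULL
          })
          if (is.null(res)) next
          rows[[id]] <- res$row
          models[[id]] <- res[c("model", "split", "config", "trace",
                                "report")]
        }
      }
    }
  }
  if (!length(rows)) stop("no model could be trained", call. = FALSE)
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$mae_loo), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(summary = summary, models = models), class = "grid_run")
}

#' @export
print.grid_run <- function(x, n = 10, ...) {
  cat("grid_run:", nrow(x$summary), "models\n")
  print(head(x$summary[, c("model_id", "strategy", "seed", "interval",
                           "scoring", "cv", "n_features", "q2_loo",
                           "q2_lco", "mae_loo", "r2_pred", "mae_test")], n),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Shortlist models for consensus prediction
#'
#' Drops models whose maximum descriptor intercorrelation exceeds the
#' cutoff (collinear models are unstable), ranks the remainder by the
#' ascending mean of MAE_LOO and MAE_test, and returns the top \code{k}.
#'
#' @param x a \code{grid_run} or its summary data.frame.
#' @param k shortlist size (default 6).
#' @param max_intercorrelation_cutoff exclusion threshold on the maximum
#'   absolute pairwise descriptor correlation (default 0.80).
#' @return The shortlisted summary rows with a \code{mae_mean} column, best
#'   first; empty (with a warning) if every model is filtered out.
#' @export
rank_and_select <- function(x, k = 6, max_intercorrelation_cutoff = 0.80) {
  s <- if (inherits(x, "grid_run")) x$summary else x
  stopifnot(nrow(s) >= 1)
  keep <- s$max_intercorrelation <= max_intercorrelation_cutoff &
    !is.na(s$mae_test)
  s <- s[keep, , drop = FALSE]
  if (!nrow(s)) {
    warning("all models exceeded the intercorrelation cutoff", call. = FALSE)
    return(s)
  }
  s$mae_mean <- (s$mae_loo + s$mae_test) / 2
  s <- s[order(s$mae_mean), , drop = FALSE]
  rownames(s) <- NULL
  head(s, k)
}
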