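# Weighted-mixture feature construction.

#' Build the weighted-mixture feature matrix
#'
#' For every base descriptor \eqn{d} with per-component values \eqn{D_1}
#' (component 1, HBA/cation) and \eqn{D_2} (component 2, HBD), two mixture
#' descriptors are formed from the mole fractions \eqn{x_1, x_2}:
#' \deqn{d_{pmix} = x_1 D_1 + x_2 D_2}
#' \deqn{d_{nmix} = |x_1 D_1 - x_2 D_2|}
#' Columns are named \code{<descriptor>_pmix} / \code{<descriptor>_nmix}.
#' Three passthrough columns are appended verbatim: the measuring
#' temperature \code{T_K} and the two binary halide indicators
#' \code{has_Cl}, \code{has_Br}.
#'
#' @param dataset a \code{\link{mixture_dataset}}.
#' @param mode which weighted forms to generate: \code{"both"} (default),
#'   \code{"pmix"} or \code{"nmix"}.
#' @return An object of class \code{wm_matrix}: a list with the numeric
#'   feature matrix \code{X} (rows aligned one-to-one with dataset records),
#'   the response vector \code{y}, and \code{meta} (record and component
#'   ids, kept for leave-chemical-out validation).
#' @export
wm_features <- function(dataset, mode = c("both", "pmix", "nmix")) {
  stopifnot(inherits(dataset, "mixture_dataset"))
  mode <- match.arg(mode)
  r <- dataset$records
  X <- wm_feature_block(r, dataset$components, mode)
  structure(list(
    X = X,
    y = r$y,
    meta = r[c("record_id", "comp1_id", "comp2_id")]
  ), class = "wm_matrix")
}

# Core arithmetic, shared with the synthetic generator (which needs features
# before a response exists).
wm_feature_block <- function(records, components, mode = "both") {
  D1 <- components[records$comp1_id, , drop = FALSE]
  D2 <- components[records$comp2_id, , drop = FALSE]
  # column-wise recycling of the mole-fraction vectors over the descriptor
  # matrices
  P <- D1 * records$x1 + D2 * records$x2
  N <- abs(D1 * records$x1 - D2 * records$x2)
  colnames(P) <- paste0(colnames(components), "_pmix")
  colnames(N) <- paste0(colnames(components), "_nmix")
  blocks <- switch(mode,
    pmix = P,
    nmix = N,
    both = cbind(P, N))
  X <- cbind(blocks,
             T_K = records$T_K,
             has_Cl = records$has_Cl,
             has_Br = records$has_Br)
  rownames(X) <- NULL
  X
}

#' @export
print.wm_matrix <- function(x, ...) {
  cat("wm_matrix:", nrow(x$X), "records x", ncol(x$X), "features\n")
  invisible(x)
}

#' Subset a feature matrix by record index
#'
#' @param m a \code{wm_matrix}.
#' @param idx integer record indices.
#' @return A \code{wm_matrix} restricted to the given records.
#' @export
wm_subset <- function(m, idx) {
  stopifnot(inherits(m, "wm_matrix"))
  structure(list(
    X = m$X[idx, , drop = FALSE],
    y = m$y[idx],
    meta = m$meta[idx, , drop = FALSE]
  ), class = "wm_matrix")
}

#' Drop (near-)constant feature columns
#'
#' Columns whose variance does not exceed \code{variance_floor} carry no
#' information and break downstream correlation filtering and regression,
#' so they are removed up front.  Removal is reported via \code{message}.
#'
#' @param m a \code{wm_matrix} or numeric matrix.
#' @param variance_floor columns with variance \code{<=} this value are
#'   dropped.  Default 0 removes exactly-constant columns only.
#' @return The input with offending columns removed; errors if nothing
#'   would remain.
#' @export
drop_degenerate_columns <- function(m, variance_floor = 0) {
  X <- if (inherits(m, "wm_matrix")) m$X else as.matrix(m)
  v <- apply(X, 2, var)
  drop <- v <= variance_floor
  if (all(drop)) {
    stop("all feature columns are degenerate at variance_floor = ",
         variance_floor, call. = FALSE)
  }
  if (any(drop)) {
    message("dropping degenerate column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
  }
  X <- X[, !drop, drop = FALSE]
  if (inherits(m, "wm_matrix")) {
    m$X <- X
    m
  } else {
    X
  }
}

#' Export a feature matrix as a data.frame / CSV
#'
#' @param m a \code{wm_matrix}.
#' @param path optional CSV output path.
#' @return data.frame with \code{record_id}, the feature columns and
#'   \code{y}.
#' @export
wm_as_data_frame <- function(m, path = NULL) {
  stopifnot(inherits(m, "wm_matrix"))
  out <- data.frame(record_id = m$meta$record_id, m$X, y = m$y,
                    check.names = FALSE)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
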