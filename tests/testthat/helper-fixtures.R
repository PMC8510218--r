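# Fixtures and independent oracles used across the suite.
# All fixtures are built in code; the oracles are deliberately naive
# (explicit refit loops, normal equations) so they stay independent of the
# package's computational shortcuts.

# A small component table: 3 HBAs, 2 HBDs, 2 descriptors.
tiny_components <- function() {
  m <- matrix(c(
    # dX,   dY
    5.0,  1.0,   # A1
    3.0, -2.0,   # A2
    1.0,  4.0,   # A3
    7.0,  0.5,   # B1
    6.0,  2.5),  # B2
    ncol = 2, byrow = TRUE,
    dimnames = list(c("A1", "A2", "A3", "B1", "B2"), c("dX", "dY")))
  m
}

# Build a record data.frame from parallel vectors; temperatures/y filled
# with plausible defaults.
make_records <- function(comp1, comp2, x1 = 0.5, T_K = 300, y = 1.1,
                         has_Cl = 0, has_Br = 0) {
  n <- max(lengths(list(comp1, comp2, x1, T_K, y)))
  data.frame(record_id = sprintf("r%03d", seq_len(n)),
             comp1_id = rep_len(comp1, n), comp2_id = rep_len(comp2, n),
             x1 = rep_len(x1, n), x2 = 1 - rep_len(x1, n),
             T_K = rep_len(T_K, n),
             has_Cl = rep_len(has_Cl, n), has_Br = rep_len(has_Br, n),
             y = rep_len(y, n), stringsAsFactors = FALSE)
}

# Dataset whose unique-mixture instance counts are A:5 B:4 C:3 D:2 E:1
# (in that sorted order, first-occurrence ties).
counted_mixture_dataset <- function() {
  recs <- rbind(
    make_records("A1", "B1", T_K = 300 + 10 * (0:4)),          # mixture A x5
    make_records("A1", "B2", T_K = 300 + 10 * (0:3)),          # mixture B x4
    make_records("A2", "B1", T_K = 300 + 10 * (0:2)),          # mixture C x3
    make_records("A2", "B2", T_K = 300 + 10 * (0:1)),          # mixture D x2
    make_records("A3", "B1", T_K = 300))                       # mixture E x1
  recs$record_id <- sprintf("r%03d", seq_len(nrow(recs)))
  mixture_dataset(recs, tiny_components())
}

# Dataset with component-record counts comp1 {A1:8, A2:4} and
# comp2 {B1:6, B2:4, B3:2}.
co_example_dataset <- function() {
  comps <- rbind(tiny_components(),
                 B3 = c(2.0, 3.0))
  recs <- rbind(
    make_records("A1", "B1", T_K = 300 + 10 * (0:3)),
    make_records("A1", "B2", T_K = 300 + 10 * (0:3)),
    make_records("A2", "B1", T_K = 300 + 10 * (0:1)),
    make_records("A2", "B3", T_K = 300 + 10 * (0:1)))
  recs$record_id <- sprintf("r%03d", seq_len(nrow(recs)))
  mixture_dataset(recs, comps)
}

# Small random regression fixture (plain matrix + response).
random_regression <- function(n = 20, p = 4, seed = 42, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  beta <- seq_len(p) / p
  y <- 1 + drop(X %*% beta) + rnorm(n, sd = noise)
  list(X = X, y = y)
}

# A wm_matrix-shaped object for direct metric calls.
as_wm <- function(X, y, comp1 = NULL, comp2 = NULL) {
  n <- length(y)
  structure(list(
    X = X, y = y,
    meta = data.frame(record_id = sprintf("q%03d", seq_len(n)),
                      comp1_id = comp1 %||% rep("c1", n),
                      comp2_id = comp2 %||% rep("c2", n),
                      stringsAsFactors = FALSE)),
    class = "wm_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles ---------------------------------------------------

# Naive leave-one-out: refit with lm for every left-out point.
naive_loo_oracle <- function(X, y, features) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    df <- data.frame(y = y[-i], X[-i, features, drop = FALSE],
                     check.names = FALSE)
    fit <- lm(y ~ ., data = df)
    nd <- as.data.frame(X[i, features, drop = FALSE])
    unname(predict(fit, newdata = nd))
  }, numeric(1))
}

# Naive leave-chemical-out: refit per chemical, predict its records.
naive_lco_oracle <- function(X, y, ids, features) {
  pred <- rep(NA_real_, length(y))
  for (ch in unique(ids)) {
    out <- ids == ch
    df <- data.frame(y = y[!out], X[!out, features, drop = FALSE],
                     check.names = FALSE)
    fit <- lm(y ~ ., data = df)
    nd <- as.data.frame(X[out, features, drop = FALSE])
    pred[out] <- unname(predict(fit, newdata = nd))
  }
  pred
}

# Brute-force greedy forward selection by in-sample R2 (no stopping rule).
greedy_sfs_oracle <- function(X, y, max_steps) {
  selected <- character(0)
  for (step in seq_len(max_steps)) {
    cands <- setdiff(colnames(X), selected)
    if (!length(cands)) break
    r2 <- vapply(cands, function(f) {
      summary(lm(y ~ ., data = data.frame(
        y = y, X[, c(selected, f), drop = FALSE],
        check.names = FALSE)))$r.squared
    }, numeric(1))
    selected <- c(selected, cands[which.max(r2)])
  }
  selected
}

# Consensus fixture: a response driven by two "family" descriptors, each
# active in one half of the chemical space, and two member models that each
# know only one of them.  Member A is the local expert where dA is active,
# member B where dB is active.
region_fixture <- function(seed, n_train = 60, n_test = 30) {
  set.seed(seed)
  half <- n_train / 2
  mk <- function(n, active) {
    dA <- if (active == "A") runif(n, 1, 2) else rnorm(n, 0, 0.02)
    dB <- if (active == "B") runif(n, 1, 2) else rnorm(n, 0, 0.02)
    cbind(dA = dA, dB = dB, T_K = runif(n, 283, 373))
  }
  Xtr <- rbind(mk(half, "A"), mk(half, "B"))
  Xte <- rbind(mk(n_test / 2, "A"), mk(n_test / 2, "B"))
  law <- function(X) 1.2 + 0.3 * X[, "dA"] + 0.3 * X[, "dB"] -
    4e-4 * X[, "T_K"]
  ytr <- law(Xtr) + rnorm(n_train, sd = 0.003)
  yte <- law(Xte) + rnorm(n_test, sd = 0.003)
  train <- as_wm(Xtr, ytr)
  test <- as_wm(Xte, yte)
  members <- list(
    consensus_member(fit_mlr(Xtr, ytr, c("dA", "T_K")), train),
    consensus_member(fit_mlr(Xtr, ytr, c("dB", "T_K")), train))
  list(train = train, test = test, members = members)
}

# Recovery-experiment spec: enough chemicals that descriptor-level sample
# correlations are small and greedy selection is reliable.
recovery_spec <- function(seed) {
  synthetic_spec(n_comp1 = 12, n_comp2 = 14, n_descriptors = 10,
                 n_mixtures = 70,
                 ratios = list(c(0.5, 0.5), c(0.75, 0.25)),
                 n_temps_per_mixture = 4,
                 cl_coefficient = 0, br_coefficient = 0,
                 rng_seed = seed)
}
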