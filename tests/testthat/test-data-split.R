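test_that("MO selection follows the sorted-count seed/interval rule", {
  ds <- counted_mixture_dataset()  # counts A:5 B:4 C:3 D:2 E:1
  splits <- mo_splits(ds, max_seed = 0, max_interval = 2)
  ivals <- vapply(splits, `[[`, 0L, "interval")

  # seed 0, interval 2 selects sorted positions 1, 3 (0-based): B and D
  s <- splits[[which(ivals == 2)]]
  keys <- mixqspr:::record_mixture_keys(ds)
  test_mix <- sort(unique(keys[s$test_idx]))
  expect_equal(test_mix, sort(c("A1|B2|0.5000:0.5000", "A2|B2|0.5000:0.5000")))
  expect_equal(s$test_fraction, 6 / 15)

  # the max-instance mixture (A) always trains, for every emitted split
  for (sp in mo_splits(ds, 3, 3)) {
    expect_false("A1|B1|0.5000:0.5000" %in% keys[sp$test_idx])
    expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(15))
    expect_length(intersect(keys[sp$train_idx], keys[sp$test_idx]), 0)
  }

  # a seed beyond the list length yields no test mixtures -> discarded
  far <- suppressWarnings(mo_splits(ds, max_seed = 10, max_interval = 1))
  expect_true(all(vapply(far, function(x) length(x$test_idx) > 0, TRUE)))
  expect_true(all(vapply(far, function(x) max(x$provenance$seed) <= 3, TRUE)))
})

test_that("CO selection removes chosen chemicals wholesale in both slots", {
  ds <- co_example_dataset()  # comp1 {A1:8, A2:4}; comp2 {B1:6, B2:4, B3:2}
  splits <- co_splits(ds, max_seed = 0, max_interval = 1)
  s <- splits[[1]]
  expect_equal(s$selected_comp1, "A2")
  expect_equal(sort(s$selected_comp2), c("B2", "B3"))

  r <- ds$records
  expect_setequal(s$test_idx,
                  which(r$comp1_id == "A2" | r$comp2_id %in% c("B2", "B3")))
  # no training record contains a selected chemical
  expect_false(any(r$comp1_id[s$train_idx] %in% s$selected_comp1))
  expect_false(any(r$comp2_id[s$train_idx] %in% s$selected_comp2))

  d <- describe_split(s, ds)
  expect_true(all(c("A2", "B2", "B3") %in% d$chemicals_only_in_test))
  expect_equal(d$train$n_records + d$test$n_records, nrow(r))
})

test_that("describe_split counts records, mixtures and chemicals per side", {
  ds <- counted_mixture_dataset()
  splits <- mo_splits(ds, max_seed = 0, max_interval = 2)
  s <- splits[[which(vapply(splits, `[[`, 0L, "interval") == 2)]]
  d <- describe_split(s, ds)
  expect_equal(d$train$n_records, 9)
  expect_equal(d$train$n_mixtures, 3)
  expect_equal(d$test$n_records, 6)
  expect_equal(d$test$n_mixtures, 2)

  # degenerate all-train "split": test counts all zero
  full <- mixqspr:::new_data_split("MO", 0, 1, seq_len(15), integer(0), 15)
  d0 <- describe_split(full, ds)
  expect_equal(unlist(d0$test), c(n_records = 0, n_mixtures = 0,
                                  n_comp1 = 0, n_comp2 = 0))
})

test_that("split enumeration over synthetic data honors all contracts", {
  g <- generate_mixture_data(synthetic_spec(
    n_comp1 = 6, n_comp2 = 5, n_descriptors = 4, n_mixtures = 40,
    ratios = list(c(0.5, 0.5), c(2/3, 1/3)), n_temps_per_mixture = 4,
    rng_seed = 11))
  ds <- g$dataset
  n <- nrow(ds$records)
  keys <- mixqspr:::record_mixture_keys(ds)
  top_mix <- unique_mixtures(ds)$key[1]

  mo <- mo_splits(ds, 5, 5)
  expect_gt(length(mo), 0)
  for (sp in mo) {
    expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(n))
    expect_length(intersect(sp$train_idx, sp$test_idx), 0)
    expect_length(intersect(keys[sp$train_idx], keys[sp$test_idx]), 0)
    expect_false(top_mix %in% keys[sp$test_idx])
    expect_gte(sp$test_fraction, 0.20)
  }
  # deduplication: no two emitted splits share a partition
  sigs <- vapply(mo, function(sp) paste(sp$test_idx, collapse = ","), "")
  expect_false(anyDuplicated(sigs) > 0)

  co <- co_splits(ds, 5, 5)
  r <- ds$records
  for (sp in co) {
    expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(n))
    expect_false(any(r$comp1_id[sp$train_idx] %in% sp$selected_comp1))
    expect_false(any(r$comp2_id[sp$train_idx] %in% sp$selected_comp2))
    expect_gte(sp$test_fraction, 0.20)
    expect_gt(length(sp$train_idx), 0)
  }

  # determinism: identical inputs give identical split lists
  expect_identical(mo, mo_splits(ds, 5, 5))
  expect_identical(co, co_splits(ds, 5, 5))
})
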