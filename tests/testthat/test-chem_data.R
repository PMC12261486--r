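test_that("canonicalization merges equivalent writings and is idempotent", {
  keys <- canonicalize_smiles(c("OCC", "CCO", "C(C)O"))
  expect_length(unique(keys), 1L)
  expect_identical(canonicalize_smiles(keys), keys)
  # aromatic ring written kekulized and aromatic
  k2 <- canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(k2[1], k2[2])
})

test_that("canonicalization rejects unparsable input, naming the row", {
  expect_error(canonicalize_smiles(c("CCO", "not_a_smiles")), "row 2")
  expect_error(canonicalize_smiles(""), "empty")
  # opaque mode treats anything non-empty as its own key
  expect_identical(canonicalize_smiles("whatever_key", opaque = TRUE),
                   "whatever_key")
})

test_that("aggregation merges tables on the canonical key with masks", {
  specs <- endpoint_specs(c("e1", "e2"), c("A", "D"),
                          c("classification", "regression"))
  tables <- list(
    e1 = data.frame(smiles = c("CCO", "CCN"), label = c(1, 0)),
    e2 = data.frame(smiles = "CCO", label = 2.5))
  ds <- aggregate_endpoints(tables, specs)
  expect_s3_class(ds, "adme_dataset")
  expect_length(ds$keys, 2L)
  cco <- which(ds$keys == canonicalize_smiles("CCO"))
  ccn <- setdiff(1:2, cco)
  expect_true(all(ds$mask[cco, ]))
  expect_identical(unname(ds$mask[ccn, ]), c(TRUE, FALSE))
  expect_equal(unname(ds$labels[cco, ]), c(1, 2.5))
  expect_true(is.na(ds$labels[ccn, "e2"]))
})

test_that("disjoint molecule sets concatenate; same-structure rows merge", {
  specs <- endpoint_specs(c("e1", "e2"), c("A", "A"),
                          c("regression", "regression"))
  ds <- aggregate_endpoints(list(
    e1 = data.frame(smiles = c("CCO", "CCN"), label = c(1, 2)),
    e2 = data.frame(smiles = c("CCC", "CCCC"), label = c(3, 4))), specs)
  expect_length(ds$keys, 4L)
  # "CCO" and "OCC" are one molecule: consistent duplicate collapses
  ds2 <- aggregate_endpoints(list(
    e1 = data.frame(smiles = c("CCO", "OCC"), label = c(1, 1))),
    specs[1, ])
  expect_length(ds2$keys, 1L)
  expect_equal(unname(ds2$labels[1, "e1"]), 1)
})

test_that("duplicate consolidation: majority vote, mean, tie handling", {
  specs <- endpoint_specs(c("clf", "reg"), c("A", "A"),
                          c("classification", "regression"))
  tables <- list(
    clf = data.frame(smiles = c("CCO", "OCC", "CCO", "CCN", "NCC"),
                     label = c(1, 1, 0, 1, 0)),
    reg = data.frame(smiles = c("CCO", "OCC"), label = c(1, 3)))
  ds <- aggregate_endpoints(tables, specs)
  cco <- which(ds$keys == canonicalize_smiles("CCO"))
  ccn <- which(ds$keys == canonicalize_smiles("CCN"))
  expect_equal(unname(ds$labels[cco, "clf"]), 1)   # 2-vs-1 majority
  expect_false(ds$mask[ccn, "clf"])                # 1-vs-1 tie dropped
  expect_equal(unname(ds$labels[cco, "reg"]), 2)   # arithmetic mean
  expect_error(aggregate_endpoints(tables, specs, on_conflict = "error"),
               "strict")
})

test_that("aggregation conserves observations and masks imply values", {
  syn <- local_syn()
  ds <- syn$dataset
  # every TRUE mask bit has a stored value
  expect_false(anyNA(ds$labels[ds$mask]))
  # observed entries equal input rows (generator keys are already unique)
  gen <- generate_labels(syn$molecules, syn$cfg)
  expect_identical(sum(ds$mask),
                   sum(vapply(gen$tables, nrow, integer(1))))
  expect_error(aggregate_endpoints(list(), ds$specs), "non-empty")
})

test_that("z-score normalization matches the hand-computed 3-point case", {
  specs <- endpoint_specs("r", "A", "regression")
  ds <- aggregate_endpoints(
    list(r = data.frame(smiles = c("CCO", "CCN", "CCC"), label = c(1, 2, 3))),
    specs)
  keys <- ds$keys[order(match(ds$labels[, "r"], 1:3))]
  dsn <- fit_normalization(ds, ds$keys)
  expect_equal(sort(unname(dsn$labels[, "r"])),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(unname(dsn$specs$norm_sd[1]), sqrt(2 / 3), tolerance = 1e-12)
  # transformed training values: mean 0, population sd 1
  v <- dsn$labels[, "r"]
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
})

test_that("normalization is a fixed point on standardized data and centers held-out values", {
  specs <- endpoint_specs("r", "A", "regression")
  n <- 9
  raw <- seq(-2, 2, length.out = n)
  std <- (raw - mean(raw)) / sqrt(mean((raw - mean(raw))^2))
  smis <- paste0("C", strrep("C", seq_len(n)))  # distinct alkanes
  ds <- aggregate_endpoints(list(r = data.frame(smiles = smis, label = std)),
                            specs)
  dsn <- fit_normalization(ds, ds$keys)
  expect_equal(sort(unname(dsn$labels[, "r"])), sort(std), tolerance = 1e-9)

  # held-out value equal to the train mean maps to 0
  smis2 <- c(smis, "CCO")
  ds2 <- aggregate_endpoints(
    list(r = data.frame(smiles = smis2, label = c(raw, mean(raw)))), specs)
  train <- canonicalize_smiles(smis)
  ds2n <- fit_normalization(ds2, train)
  held <- ds2$keys == canonicalize_smiles("CCO")
  expect_equal(unname(ds2n$labels[held, "r"]), 0, tolerance = 1e-12)
})

test_that("normalization never reads held-out values (poisoning check)", {
  specs <- endpoint_specs("r", "A", "regression")
  smis <- c("CCO", "CCN", "CCC", "CCCC", "CCCCC")
  base <- data.frame(smiles = smis, label = c(1, 2, 3, 4, 5))
  pois <- base; pois$label[4:5] <- c(1e6, -1e6)
  train <- canonicalize_smiles(smis[1:3])
  a <- fit_normalization(aggregate_endpoints(list(r = base), specs), train)
  b <- fit_normalization(aggregate_endpoints(list(r = pois), specs), train)
  expect_identical(a$specs$norm_mean, b$specs$norm_mean)
  expect_identical(a$specs$norm_sd, b$specs$norm_sd)
  # zero spread errors, naming the endpoint
  flat <- data.frame(smiles = smis, label = rep(7, 5))
  expect_error(fit_normalization(aggregate_endpoints(list(r = flat), specs),
                                 canonicalize_smiles(smis)), "r")
})

test_that("stratified folds balance positives and are deterministic", {
  y <- c(rep(1, 2), rep(0, 8))
  f <- stratified_kfold(y, 5, seed = 3)
  expect_identical(sort(unique(f)), 0:4)
  expect_true(all(table(f) == 2))                     # equal fold sizes
  pos_per_fold <- tapply(y, f, sum)
  expect_true(all(pos_per_fold <= 1))                 # no fold hoards positives
  expect_identical(f, stratified_kfold(y, 5, seed = 3))
  expect_false(identical(f, stratified_kfold(y, 5, seed = 4)))
  expect_error(stratified_kfold(y, 11, seed = 1), "records")
  # single-class labels degrade to a plain balanced k-fold
  f1 <- stratified_kfold(rep(1, 10), 5, seed = 1)
  expect_true(all(table(f1) == 2))
  # proportional share within 1 for larger imbalanced sets
  y2 <- rep(c(1, 0), c(17, 83))
  f2 <- stratified_kfold(y2, 5, seed = 9)
  expect_true(all(abs(tapply(y2, f2, sum) - 17 / 5) < 1))
})

test_that("dataset round-trips through the on-disk layout byte-stably", {
  syn <- local_syn()
  ds <- fit_normalization(syn$dataset, syn$dataset$keys[1:100])
  ds <- assign_folds(ds, hash_kfold(ds$keys, 5, seed = 2))
  pre <- file.path(withr::local_tempdir(), "agg")
  write_adme_dataset(ds, pre)
  ds2 <- read_adme_dataset(pre)
  expect_identical(ds2$keys, ds$keys)
  expect_equal(ds2$labels, ds$labels)
  expect_identical(ds2$mask, ds$mask)
  expect_identical(ds2$folds, ds$folds)
  expect_equal(ds2$specs$norm_sd, ds$specs$norm_sd)
  pre2 <- file.path(withr::local_tempdir(), "agg2")
  write_adme_dataset(ds2, pre2)
  expect_identical(readLines(paste0(pre2, ".csv")),
                   readLines(paste0(pre, ".csv")))
  expect_identical(readLines(paste0(pre2, ".json")),
                   readLines(paste0(pre, ".json")))
})

test_that("manifest-driven loading reproduces the in-memory aggregate", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_molecules = 40, seed = 5)
  write_synthetic_dataset(cfg, dir)
  ds <- load_adme_dataset(file.path(dir, "manifest.csv"))
  expect_length(ds$keys, 40L)
  expect_identical(nrow(ds$specs), 8L)
  expect_error(read_endpoint_table(file.path(dir, "latents.csv")), "label")
})
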