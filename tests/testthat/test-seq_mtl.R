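test_that("masked losses average observed entries only", {
  specs <- endpoint_specs(c("c", "r"), c("A", "A"),
                          c("classification", "regression"))
  labels <- cbind(c = c(1, 0, 1, 999), r = c(0.5, 999, -0.5, 1))
  mask <- cbind(c = c(TRUE, TRUE, TRUE, FALSE),
                r = c(TRUE, FALSE, TRUE, TRUE))
  # perfect classification; regression off by 0.5 on both observed rows
  preds <- list(c = c(1, 0, 1, 0.123), r = c(1, 77, 0, 1))
  ml <- masked_losses(preds, labels, mask, specs)
  expect_equal(unname(ml$per_endpoint["c"]), 0)
  expect_equal(unname(ml$per_endpoint["r"]), mean(c(0.25, 0.25, 0)))
  expect_equal(ml$total, mean(ml$per_endpoint))
  expect_false(ml$skip)
  expect_identical(unname(ml$n_obs), c(3L, 3L))

  # two observed squared errors of 0.25 -> endpoint loss 0.25
  ml2 <- masked_losses(list(r = c(1, 77, 0, 1)), labels,
                       cbind(c = mask[, "c"],
                             r = c(TRUE, FALSE, TRUE, FALSE)), specs)
  expect_equal(unname(ml2$per_endpoint["r"]), 0.25)

  # flipping a masked-out label changes nothing, to the last bit
  labels2 <- labels; labels2[4, "c"] <- -123456
  ml3 <- masked_losses(preds, labels2, mask, specs)
  expect_identical(ml3$per_endpoint, ml$per_endpoint)

  # all-masked batch flags a no-op instead of erroring
  ml4 <- masked_losses(preds, labels, mask & FALSE, specs)
  expect_true(ml4$skip)
  expect_true(is.na(ml4$total))
})

test_that("training is bitwise reproducible under a fixed seed", {
  ds <- make_toy_dataset(n = 60)
  X <- toy_features(60, d = 16)
  f1 <- adme_mtl(ds, fast_control(seed = 5), features = X)
  f2 <- adme_mtl(ds, fast_control(seed = 5), features = X)
  expect_identical(f1$model$params, f2$model$params)
  expect_true(ledger_equal(f1$ledger, f2$ledger))
  f3 <- adme_mtl(ds, fast_control(seed = 6), features = X)
  expect_false(identical(f3$model$params, f1$model$params))
})

test_that("sequential training with one category reduces to naive training", {
  specs <- toy_specs(categories = "A", per = 3L)
  ds <- make_toy_dataset(n = 50, specs = specs, seed = 7)
  X <- toy_features(50, d = 16, seed = 7)
  sq <- adme_mtl(ds, fast_control(mode = "sequential", order = "A",
                                  pcgrad = FALSE, seed = 9), features = X)
  nv <- adme_mtl(ds, fast_control(mode = "naive", seed = 9), features = X)
  expect_true(ledger_equal(sq$ledger, nv$ledger))
  expect_identical(sq$model$params, nv$model$params)
})

test_that("masked label values influence neither losses nor parameters", {
  specs <- toy_specs()
  ds <- make_toy_dataset(n = 60, specs = specs, seed = 11, poison = 0)
  ds2 <- ds
  ds2$labels[!ds2$mask] <- 31337  # different placeholder under the mask
  X <- toy_features(60, d = 16, seed = 11)
  f1 <- adme_mtl(ds, fast_control(seed = 12), features = X)
  f2 <- adme_mtl(ds2, fast_control(seed = 12), features = X)
  expect_identical(f1$model$params, f2$model$params)
  expect_true(ledger_equal(f1$ledger, f2$ledger))
})

test_that("the ledger's total equals the mean of its per-endpoint components", {
  ds <- make_toy_dataset(n = 60, seed = 3)
  X <- toy_features(60, d = 16, seed = 3)
  fit <- adme_mtl(ds, fast_control(seed = 8), features = X)
  for (ep in unique(fit$ledger$total$epoch)) {
    comp <- fit$ledger$val$loss[fit$ledger$val$epoch == ep]
    expect_lt(abs(fit$ledger$total$loss[ep] - mean(comp)), 1e-9)
  }
  # one train row per (epoch, endpoint) seen; categories visited in order
  cats <- unique(fit$ledger$train$category)
  expect_identical(cats, c("A", "D", "M", "E"))
})

test_that("visit order and subsets are validated before training", {
  ds <- make_toy_dataset(n = 40)
  X <- toy_features(40, d = 16)
  # reversed order runs and logs a different visit sequence
  rev <- adme_mtl(ds, fast_control(order = c("E", "M", "D", "A"), seed = 2),
                  features = X)
  expect_identical(unique(rev$ledger$train$category), c("E", "M", "D", "A"))
  expect_error(adme_mtl(ds, fast_control(order = c("A", "D")), features = X),
               "order")
  expect_error(train_config(mode = "subset"), "subset_categories")
  # a category with zero observed data fails fast
  ds0 <- ds
  ds0$mask[, ds0$specs$category == "E"] <- FALSE
  expect_error(adme_mtl(ds0, fast_control(seed = 1), features = X),
               "no observed data")
})

test_that("subset mode trains only the requested categories", {
  ds <- make_toy_dataset(n = 50, seed = 13)
  X <- toy_features(50, d = 16, seed = 13)
  fit <- train_naive(ds, features = X, subset_categories = c("A", "D"),
                     epochs_max = 3, batch_size = 32, hidden = 16, d_z = 8,
                     seed = 4)
  expect_setequal(unique(fit$ledger$val$endpoint),
                  ds$specs$name[ds$specs$category %in% c("A", "D")])
  expect_error(train_naive(ds, features = X, subset_categories = "Z",
                           seed = 1),
               "absent")
})

test_that("pcgrad on/off changes trunk updates only when conflicts arise", {
  ds <- make_toy_dataset(n = 50, seed = 17)
  X <- toy_features(50, d = 16, seed = 17)
  on <- adme_mtl(ds, fast_control(pcgrad = TRUE, seed = 3), features = X)
  off <- adme_mtl(ds, fast_control(pcgrad = FALSE, seed = 3), features = X)
  # with real conflicting tasks the trajectories genuinely differ
  expect_false(identical(on$model$params, off$model$params))
})
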