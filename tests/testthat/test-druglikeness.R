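# Direct-formula oracles, independent of the package implementation.
oracle_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}
oracle_f1 <- function(tp, tn, fp, fn) {
  prec <- if (tp + fp == 0) NA else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA else tp / (tp + fn)
  if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
  else 2 * prec * rec / (prec + rec)
}
# Brute-force average precision: walk distinct thresholds explicitly.
oracle_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  ap <- 0; last_rec <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / npos
    ap <- ap + (rec - last_rec) * prec
    last_rec <- rec
  }
  ap
}

test_that("MCC and F1 match direct formulas on enumerated confusion matrices", {
  for (tp in 0:5) for (tn in 0:5) for (fp in 0:5) for (fn in 0:5) {
    expect_equal(mcc_counts(tp, tn, fp, fn), oracle_mcc(tp, tn, fp, fn),
                 tolerance = 1e-12)
    expect_equal(f1_counts(tp, tn, fp, fn), oracle_f1(tp, tn, fp, fn),
                 tolerance = 1e-12)
  }
  # anchor cases
  expect_identical(mcc_counts(1, 1, 1, 1), 0)
  expect_identical(f1_counts(2, 0, 1, 1), 2 / 3)
  expect_equal(mcc_counts(5, 5, 0, 0), 1, tolerance = 1e-12)
})

test_that("AUPRC matches a brute-force average-precision oracle", {
  set.seed(41)
  for (rep in 1:300) {
    n <- sample(2:50, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force ties sometimes
    expect_equal(auprc(scores, labels), oracle_ap(scores, labels),
                 tolerance = 1e-12)
  }
  expect_identical(auprc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  # AUPRC depends only on the ranking: monotone transforms are invisible
  s <- runif(30); y <- rbinom(30, 1, 0.4); y[1] <- 1
  expect_equal(auprc(plogis(5 * s - 2), y), auprc(s, y), tolerance = 1e-12)
})

test_that("a random scorer's AUPRC concentrates near the prevalence", {
  set.seed(43)
  n <- 10000
  labels <- rep(c(1, 0), c(1000, 9000))  # prevalence 0.1
  scores <- runif(n)
  expect_lt(abs(auprc(scores, labels) - 0.1), 0.03)
})

test_that("evaluate_binary applies the 0.5 tie rule and label checks", {
  ev <- evaluate_binary(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(ev$mcc, ev$f1, ev$auprc), c(1, 1, 1), tolerance = 1e-12)
  # a score of exactly 0.5 counts as a predicted drug
  ev2 <- evaluate_binary(c(0.5, 0.4), c(1, 0))
  expect_identical(ev2$tp, 1L)
  expect_identical(ev2$tn, 1L)
  expect_error(evaluate_binary(c(0.2, 0.8), c(1, 1)), "single class")
  # MCC negates under prediction inversion
  set.seed(7)
  y <- sample(rep(c(1, 0), c(6, 14)))
  s <- ifelse(y == 1, runif(20, 0.3, 1), runif(20, 0, 0.7))
  ev_pos <- evaluate_binary(s, y)
  ev_neg <- evaluate_binary(1 - s + 1e-9, y)
  expect_equal(ev_neg$mcc, -ev_pos$mcc, tolerance = 1e-9)
})

test_that("scoring validates dimensions and stays in [0, 1]", {
  set.seed(5)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- as.numeric(X[, 1] > 0)
  cv <- druglikeness_cv(X, y, k = 4, seed = 2, epochs_max = 30)
  sc <- predict_score(cv$classifiers[[1]], matrix(rnorm(80), 10, 8))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predict_score(cv$classifiers[[1]], matrix(0, 2, 7)), "width")
})

test_that("cross-validated training separates separable embeddings", {
  set.seed(19)
  n <- 160
  y <- rep(c(1, 0), each = n / 2)
  X <- matrix(rnorm(n * 8, mean = rep(ifelse(y == 1, 1.5, -1.5), 8)), n, 8)
  cv <- druglikeness_cv(X, y, k = 5, seed = 3, epochs_max = 60)
  expect_gte(cv$report$mean["mcc"], 0.9)
  expect_identical(nrow(cv$report$folds), 5L)
  # mean/sd recomputable from the per-fold values
  expect_equal(unname(cv$report$mean["f1"]), mean(cv$report$folds$f1))
  expect_equal(unname(cv$report$sd["auprc"]), sd(cv$report$folds$auprc))
  # determinism under the seed
  cv2 <- druglikeness_cv(X, y, k = 5, seed = 3, epochs_max = 60)
  expect_identical(cv$report, cv2$report)
  # single-class training folds are rejected
  expect_error(druglikeness_cv(X[y == 1, ], y[y == 1], k = 2, seed = 1),
               "one class")
})

test_that("metric reports write the per-fold rows plus mean and sd", {
  set.seed(23)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- as.numeric(X[, 1] + 0.3 * rnorm(60) > 0)
  cv <- druglikeness_cv(X, y, k = 3, seed = 4, epochs_max = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(cv$report, path)
  got <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(got$fold, c("0", "1", "2", "mean", "sd"))
  expect_equal(got$mcc[4], mean(got$mcc[1:3]), tolerance = 1e-12)
})
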