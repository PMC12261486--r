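# Step 2: drug-likeness classification on frozen ADME-informed embeddings,
# evaluated with balanced metrics (MCC, F1, AUPRC) under stratified
# cross-validation.

#' Matthews correlation coefficient from a thresholded confusion matrix
#'
#' @param tp,tn,fp,fn Confusion-matrix counts.
#' @return MCC in `[-1, 1]`; defined as 0 when the denominator is 0.
#' @export
mcc_counts <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' F1 score (positive class) from a confusion matrix
#'
#' @inheritParams mcc_counts
#' @return Harmonic mean of precision and recall; 0 when undefined.
#' @export
f1_counts <- function(tp, tn, fp, fn) {
  den <- 2 * tp + fp + fn
  if (den == 0) return(0)
  2 * tp / den
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function average precision over the score ranking:
#' `AP = sum_k (R_k - R_{k-1}) P_k` over the distinct score thresholds in
#' decreasing order.  Tied scores are processed as one block, so the
#' result does not depend on the ordering within ties.  No trapezoidal
#' interpolation is applied.
#'
#' @param scores Numeric scores (higher = more drug-like).
#' @param labels Binary labels (1 = positive).
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1)
  if (npos == 0) stop_named("auprc: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # block boundaries = last index of each distinct score
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  ctp <- cumsum(y)[ends]
  prec <- ctp / ends
  rec <- ctp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate binary scores with the balanced-metric battery
#'
#' Hard labels come from thresholding the scores at 0.5 (a score of
#' exactly 0.5 counts as a drug); MCC and F1 are computed from the
#' resulting confusion matrix, AUPRC from the full ranking.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary labels containing both classes.
#' @return Named list: mcc, f1, auprc, and the confusion counts.
#' @export
evaluate_binary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop_named("evaluate_binary: labels contain a single class (MCC undefined)")
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  list(mcc = mcc_counts(tp, tn, fp, fn), f1 = f1_counts(tp, tn, fp, fn),
       auprc = auprc(scores, labels), tp = tp, tn = tn, fp = fp, fn = fn)
}

# ---- binary MLP on embeddings -------------------------------------------

mlp_binary_init <- function(d_in, hidden, seed) {
  set.seed(as.integer(seed))
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(W1 = he(d_in, hidden[1]), b1 = numeric(hidden[1]),
       W2 = he(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
       w3 = matrix(stats::rnorm(hidden[2], 0, sqrt(1 / hidden[2])), hidden[2], 1),
       b3 = 0)
}

mlp_binary_forward <- function(p, X) {
  H1 <- relu(sweep(X %*% p$W1, 2, p$b1, `+`))
  H2 <- relu(sweep(H1 %*% p$W2, 2, p$b2, `+`))
  s <- drop(H2 %*% p$w3) + p$b3
  list(H1 = H1, H2 = H2, logit = s)
}

mlp_binary_fit <- function(X, y, hidden = c(128L, 128L), epochs_max = 200L,
                           batch_size = 64L, learning_rate = 1e-3,
                           patience = 10L, tol = 1e-4, seed = 1L,
                           val_fraction = 0.1) {
  n <- nrow(X)
  p <- mlp_binary_init(ncol(X), hidden, substream_seed(seed, "dl.init"))
  opt <- adam_init(p)
  set.seed(substream_seed(seed, "dl.shuffle"))
  vidx <- sample.int(n, max(1L, round(val_fraction * n)))
  tidx <- setdiff(seq_len(n), vidx)
  best <- Inf; best_p <- p; stall <- 0L
  for (epoch in seq_len(epochs_max)) {
    perm <- tidx[sample.int(length(tidx))]
    nb <- ceiling(length(perm) / batch_size)
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1) * batch_size + 1):min(b * batch_size, length(perm))]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      fw <- mlp_binary_forward(p, Xb)
      ds <- (sigmoid(fw$logit) - yb) / length(idx)
      dH2 <- (ds %*% t(p$w3)) * (fw$H2 > 0)
      dH1 <- (dH2 %*% t(p$W2)) * (fw$H1 > 0)
      grads <- list(W1 = crossprod(Xb, dH1), b1 = colSums(dH1),
                    W2 = crossprod(fw$H1, dH2), b2 = colSums(dH2),
                    w3 = crossprod(fw$H2, matrix(ds)), b3 = sum(ds))
      st <- adam_step(opt, p, grads, learning_rate)
      opt <- st$state; p <- st$params
    }
    sv <- mlp_binary_forward(p, X[vidx, , drop = FALSE])$logit
    vloss <- mean(log1pexp(sv) - y[vidx] * sv)
    if (!is.finite(best) || best - vloss > tol * abs(best)) {
      best <- vloss; best_p <- p; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(params = best_p, d_in = ncol(X), hidden = hidden),
            class = "dl_classifier")
}

#' Score molecules with a drug-likeness classifier
#'
#' @param classifier A `dl_classifier` (one fold of [druglikeness_cv()]).
#' @param embeddings Embedding matrix with the classifier's input width.
#' @return Numeric scores in `[0, 1]`; the hard label is drug when the
#'   score is `>= 0.5`.
#' @export
predict_score <- function(classifier, embeddings) {
  stopifnot(inherits(classifier, "dl_classifier"))
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1)
  if (ncol(embeddings) != classifier$d_in)
    stop_named("predict_score: embedding width %d does not match classifier input %d",
               ncol(embeddings), classifier$d_in)
  sigmoid(mlp_binary_forward(classifier$params, embeddings)$logit)
}

#' Cross-validated drug-likeness classification on frozen embeddings
#'
#' Trains one MLP classifier per cross-validation round on the embeddings
#' of the training folds (binary cross-entropy, early stopping on an inner
#' validation split) and evaluates it on the held-out fold with MCC, F1
#' and AUPRC.  The encoder that produced the embeddings is never touched:
#' only the embedding matrix enters this step.
#'
#' @param embeddings Numeric matrix (molecules x d_z) from [encode()].
#' @param labels Binary drug labels (1 = approved drug).
#' @param k Number of stratified folds.
#' @param seed Integer seed (fold assignment and per-fold training).
#' @param folds Optional precomputed 0-based fold vector.
#' @param hidden Hidden-layer widths of the classifier.
#' @param ... Further arguments to the internal trainer (epochs_max,
#'   batch_size, learning_rate, patience).
#' @return Object of class `druglikeness_cv`: per-fold classifiers,
#'   per-fold scores and a `metric_report`.
#' @export
druglikeness_cv <- function(embeddings, labels, k = 5L, seed = 1L,
                            folds = NULL, hidden = c(128L, 128L), ...) {
  stopifnot(nrow(embeddings) == length(labels), all(labels %in% c(0, 1)))
  if (is.null(folds))
    folds <- stratified_kfold(labels, k, substream_seed(seed, "dl.folds"))
  k <- length(unique(folds))
  fold_rows <- list(); classifiers <- list(); scores <- rep(NA_real_, length(labels))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2)
      stop_named("druglikeness_cv: training folds for round %d contain one class", f)
    clf <- mlp_binary_fit(embeddings[tr, , drop = FALSE], labels[tr],
                          hidden = hidden,
                          seed = substream_seed(seed, paste0("dl.fold", f)), ...)
    sc <- predict_score(clf, embeddings[!tr, , drop = FALSE])
    ev <- evaluate_binary(sc, labels[!tr])
    fold_rows[[length(fold_rows) + 1L]] <-
      data.frame(fold = f, mcc = ev$mcc, f1 = ev$f1, auprc = ev$auprc)
    classifiers[[as.character(f)]] <- clf
    scores[!tr] <- sc
  }
  perfold <- do.call(rbind, fold_rows)
  report <- structure(list(
    folds = perfold,
    mean = colMeans(perfold[, c("mcc", "f1", "auprc")]),
    sd = apply(perfold[, c("mcc", "f1", "auprc")], 2, stats::sd)),
    class = "metric_report")
  structure(list(classifiers = classifiers, folds = folds, scores = scores,
                 report = report, seed = seed),
            class = "druglikeness_cv")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("cross-validated drug-likeness metrics (mean (sd) over folds):\n")
  for (m in c("mcc", "f1", "auprc"))
    cat(sprintf("  %-6s %.3f (%.4f)\n", toupper(m), x$mean[m], x$sd[m]))
  invisible(x)
}

#' @export
print.druglikeness_cv <- function(x, ...) {
  cat(sprintf("druglikeness_cv: %d folds, %d molecules\n",
              length(x$classifiers), length(x$folds)))
  print(x$report)
  invisible(x)
}

#' Write a metric report as a delimited table
#'
#' Per-fold rows plus mean and sd rows, mirroring the usual benchmark
#' layout (MCC, F1, AUPRC).
#'
#' @param report A `metric_report`.
#' @param path Output CSV path.
#' @export
write_metric_report <- function(report, path) {
  df <- report$folds
  df$fold <- as.character(df$fold)
  df <- rbind(df,
              data.frame(fold = "mean", mcc = report$mean["mcc"],
                         f1 = report$mean["f1"], auprc = report$mean["auprc"]),
              data.frame(fold = "sd", mcc = report$sd["mcc"],
                         f1 = report$sd["f1"], auprc = report$sd["auprc"]))
  df$mcc <- fmt_num(df$mcc); df$f1 <- fmt_num(df$f1); df$auprc <- fmt_num(df$auprc)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Digest of an encoder's parameters
#'
#' Deterministic fingerprint of all trunk and head parameters, used to
#' verify that the encoder stayed frozen while the drug-likeness
#' classifier trained.
#'
#' @param fit An `adme_mtl` fit (or an `encoder_model`).
#' @return A 32-character hexadecimal string.
#' @export
encoder_digest <- function(fit) {
  params <- if (inherits(fit, "adme_mtl")) fit$model$params else fit$params
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(params, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}
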