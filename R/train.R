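#' Training configuration
#'
#' @param order Category visit order per epoch, a permutation of the
#'   categories present (default the pharmacokinetic order A, D, M, E).
#' @param mode `"sequential"` (one visit group per category, in `order`),
#'   `"naive"` (all endpoints in one group, the classic multi-task
#'   baseline) or `"subset"` (naive training restricted to
#'   `subset_categories`; with one category this is the single-task-group
#'   baseline used by the dependency analysis).
#' @param subset_categories Character vector over `{A,D,M,E}` (subset mode).
#' @param pcgrad Apply gradient surgery to the trunk gradients within a
#'   visit group (default: only in sequential mode, where conflict
#'   resolution operates inside each category).
#' @param epochs_max Hard cap on epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param convergence_tol Relative improvement in total validation loss
#'   below which an epoch counts as non-improving.
#' @param patience Consecutive non-improving epochs before stopping.
#' @param seed Master seed; initialization, batch shuffling, the
#'   validation split and the gradient-surgery order all derive from it
#'   through named substreams.
#' @param hidden,d_z Trunk layer widths (see [new_encoder()]).
#' @param val_fraction Fraction of molecules held out (by seeded hash of
#'   the canonical key) for the convergence criterion and the ledger's
#'   validation losses.
#' @return A list of class `train_config`.
#' @export
train_config <- function(order = c("A", "D", "M", "E"),
                         mode = c("sequential", "naive", "subset"),
                         subset_categories = NULL,
                         pcgrad = NULL,
                         epochs_max = 200L, batch_size = 128L,
                         learning_rate = 3e-3, convergence_tol = 1e-4,
                         patience = 5L, seed = 1L,
                         hidden = 256L, d_z = 128L, val_fraction = 0.1) {
  mode <- match.arg(mode)
  stopifnot(epochs_max >= 1, batch_size >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 1)
  if (mode == "subset" && length(subset_categories) == 0L)
    stop_named("train_config: subset mode requires non-empty subset_categories")
  if (is.null(pcgrad)) pcgrad <- (mode == "sequential")
  structure(list(order = order, mode = mode,
                 subset_categories = subset_categories,
                 pcgrad = isTRUE(pcgrad),
                 epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 convergence_tol = convergence_tol,
                 patience = as.integer(patience), seed = as.integer(seed),
                 hidden = as.integer(hidden), d_z = as.integer(d_z),
                 val_fraction = val_fraction),
            class = "train_config")
}

#' Deterministic held-out split keyed on molecule identity
#'
#' The validation molecules a trainer with this seed will hold out: a
#' seeded hash of each canonical key selects approximately
#' `fraction` of the records.  Exposed so that preprocessing
#' (e.g. fitting the regression-target normalization on training
#' molecules only) can agree exactly with the trainer's split.
#'
#' @param keys Character vector of canonical keys.
#' @param seed The training seed ([train_config()]'s `seed`).
#' @param fraction Held-out fraction in (0, 1).
#' @return Logical vector, `TRUE` = held out.
#' @export
validation_split <- function(keys, seed, fraction = 0.1) {
  stopifnot(fraction > 0, fraction < 1)
  (hash_strings(keys, substream_seed(seed, "val")) %% 1000) < fraction * 1000
}

# Visit groups per epoch: a named list category-label -> endpoint names.
visit_groups <- function(specs, cfg) {
  present <- unique(specs$category)
  if (cfg$mode == "sequential") {
    ord <- cfg$order[cfg$order %in% present]
    if (!setequal(ord, present))
      stop_named("train: order (%s) must cover the categories present (%s)",
                 paste(cfg$order, collapse = ""), paste(present, collapse = ""))
    stats::setNames(lapply(ord, function(ct) specs$name[specs$category == ct]), ord)
  } else {
    cats <- if (cfg$mode == "subset") cfg$subset_categories else present
    bad <- setdiff(cats, present)
    if (length(bad))
      stop_named("train: subset categories absent from the dataset: %s",
                 paste(bad, collapse = ", "))
    eps <- specs$name[specs$category %in% cats]
    stats::setNames(list(eps), paste(sort(unique(specs$category[specs$name %in% eps])),
                                     collapse = ""))
  }
}

#' Fit a molecular encoder by (sequential) multi-task training
#'
#' The main fitting function.  Each epoch visits the configured endpoint
#' groups: all of them at once in naive/subset mode, or one
#' pharmacokinetic category after another in sequential mode so that
#' representations learned for upstream stages (absorption) are in place
#' when downstream stages (distribution, metabolism, excretion) train.
#' Within a visit group, per-endpoint losses are computed over observed
#' labels only; the shared trunk receives either the plain sum of the
#' per-endpoint gradients or their gradient-surgery combination
#' ([pcgrad_project()]), while each head receives only its own task's
#' gradient.  One Adam optimizer instance persists across groups and
#' epochs.  Training stops when the total validation loss fails to improve
#' by more than `convergence_tol` (relative) for `patience` consecutive
#' epochs, or at `epochs_max`; the returned parameters are those of the
#' best validation epoch.
#'
#' @param dataset An `adme_dataset` (see [aggregate_endpoints()]).
#' @param control A [train_config()].
#' @param features Optional precomputed feature matrix (rows aligned with
#'   `dataset$keys`); computed from `fp` when missing.
#' @param fp An [fp_config()] used when `features` is missing, and stored
#'   for later featurization of new molecules.
#' @return Object of class `adme_mtl` with elements `model`
#'   (`encoder_model` at the best epoch), `ledger` (a `loss_ledger`),
#'   `control`, `fp`, `val_keys`, `best_epoch`, `epochs_run`, `converged`.
#' @export
adme_mtl <- function(dataset, control = train_config(), features = NULL,
                     fp = fp_config()) {
  stopifnot(inherits(dataset, "adme_dataset"), inherits(control, "train_config"))
  specs <- dataset$specs
  if (is.null(features)) features <- featurize_fingerprint(dataset$keys, fp)
  stopifnot(nrow(features) == length(dataset$keys))
  groups <- visit_groups(specs, control)
  for (g in names(groups)) {
    if (sum(dataset$mask[, groups[[g]], drop = FALSE]) == 0L)
      stop_named("adme_mtl: category group '%s' has no observed data", g)
  }

  n <- length(dataset$keys)
  is_val <- validation_split(dataset$keys, control$seed, control$val_fraction)
  if (!any(is_val) || all(is_val))
    stop_named("adme_mtl: degenerate validation split")
  model <- new_encoder(specs, n_in = ncol(features), hidden = control$hidden,
                       d_z = control$d_z,
                       seed = substream_seed(control$seed, "init"))
  params <- model$params
  opt <- adam_init(params)

  train_rows <- list(); val_rows <- list(); total_rows <- list()
  best <- Inf; best_params <- params; best_epoch <- 0L; stall <- 0L
  converged <- FALSE
  ep_cat <- stats::setNames(specs$category, specs$name)

  set.seed(substream_seed(control$seed, "shuffle"))
  for (epoch in seq_len(control$epochs_max)) {
    for (g in names(groups)) {
      eps <- groups[[g]]
      mols <- which(!is_val &
                    rowSums(dataset$mask[, eps, drop = FALSE]) > 0)
      perm <- mols[sample.int(length(mols))]
      nb <- ceiling(length(perm) / control$batch_size)
      loss_sum <- stats::setNames(numeric(length(eps)), eps)
      loss_n <- stats::setNames(numeric(length(eps)), eps)
      for (b in seq_len(nb)) {
        idx <- perm[((b - 1) * control$batch_size + 1):min(b * control$batch_size, length(perm))]
        Xb <- features[idx, , drop = FALSE]
        Lb <- dataset$labels[idx, , drop = FALSE]
        Mb <- dataset$mask[idx, , drop = FALSE]
        if (control$pcgrad && length(eps) > 1) {
          gr <- endpoint_batch_grads(params, Xb, Lb, Mb, specs, eps)
          if (length(gr) == 0L) next  # no observation in this batch
          combined <- if (length(gr) > 1)
            pcgrad_project(lapply(unname(gr), `[[`, "trunk"))
          else gr[[1]]$trunk
          grads <- unflatten_trunk(combined, params)
          for (e in names(gr)) {
            grads[[paste0("head.", e, ".w")]] <- gr[[e]]$head_w
            grads[[paste0("head.", e, ".b")]] <- gr[[e]]$head_b
            loss_sum[e] <- loss_sum[e] + gr[[e]]$loss * gr[[e]]$n_obs
            loss_n[e] <- loss_n[e] + gr[[e]]$n_obs
          }
        } else {
          gr <- batch_grads_summed(params, Xb, Lb, Mb, specs, eps)
          if (is.null(gr)) next  # no observation in this batch
          grads <- gr$trunk
          for (e in names(gr$heads)) {
            grads[[paste0("head.", e, ".w")]] <- gr$heads[[e]]$w
            grads[[paste0("head.", e, ".b")]] <- gr$heads[[e]]$b
            loss_sum[e] <- loss_sum[e] + gr$losses[[e]]$loss * gr$losses[[e]]$n_obs
            loss_n[e] <- loss_n[e] + gr$losses[[e]]$n_obs
          }
        }
        st <- adam_step(opt, params, grads, control$learning_rate)
        opt <- st$state; params <- st$params
      }
      seen <- loss_n > 0
      if (any(seen))
        train_rows[[length(train_rows) + 1L]] <-
          data.frame(epoch = epoch, category = g, endpoint = eps[seen],
                     loss = unname(loss_sum[seen] / loss_n[seen]),
                     n = unname(loss_n[seen]))
    }
    # held-out losses
    model$params <- params
    vidx <- which(is_val)
    in_scope <- unique(unlist(groups, use.names = FALSE))
    preds <- predict_endpoints(model, features[vidx, , drop = FALSE], in_scope)
    ml <- masked_losses(preds, dataset$labels[vidx, , drop = FALSE],
                        dataset$mask[vidx, , drop = FALSE], specs)
    seen <- !is.na(ml$per_endpoint)
    val_rows[[length(val_rows) + 1L]] <-
      data.frame(epoch = epoch, endpoint = names(ml$per_endpoint)[seen],
                 loss = unname(ml$per_endpoint[seen]),
                 n = unname(ml$n_obs[seen]))
    total_rows[[length(total_rows) + 1L]] <-
      data.frame(epoch = epoch, loss = ml$total)
    if (is.finite(ml$total) &&
        (!is.finite(best) || best - ml$total > control$convergence_tol * abs(best))) {
      best <- ml$total; best_params <- params; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) { converged <- TRUE; break }
    }
  }

  ledger <- structure(list(train = do.call(rbind, train_rows),
                           val = do.call(rbind, val_rows),
                           total = do.call(rbind, total_rows)),
                      class = "loss_ledger")
  model$params <- best_params
  structure(list(model = model, ledger = ledger, control = control, fp = fp,
                 specs = specs, val_keys = dataset$keys[is_val],
                 best_epoch = best_epoch, epochs_run = epoch,
                 converged = converged, ep_cat = ep_cat),
            class = "adme_mtl")
}

#' Sequential multi-task training (category-ordered)
#'
#' Convenience wrapper around [adme_mtl()] with `mode = "sequential"`.
#'
#' @inheritParams adme_mtl
#' @param ... Arguments forwarded to [train_config()].
#' @export
train_sequential <- function(dataset, features = NULL, fp = fp_config(), ...) {
  adme_mtl(dataset, train_config(mode = "sequential", ...),
           features = features, fp = fp)
}

#' Naive multi-task training (all endpoints in one group)
#'
#' Convenience wrapper around [adme_mtl()] with `mode = "naive"` (or
#' `"subset"` when `subset_categories` is given).
#'
#' @inheritParams adme_mtl
#' @param subset_categories Restrict training to these categories.
#' @param ... Arguments forwarded to [train_config()].
#' @export
train_naive <- function(dataset, features = NULL, fp = fp_config(),
                        subset_categories = NULL, ...) {
  mode <- if (is.null(subset_categories)) "naive" else "subset"
  adme_mtl(dataset, train_config(mode = mode,
                                 subset_categories = subset_categories, ...),
           features = features, fp = fp)
}

#' @export
print.adme_mtl <- function(x, ...) {
  cat(sprintf("adme_mtl fit: %s mode%s, %d endpoints, d_z = %d\n",
              x$control$mode,
              if (x$control$mode == "sequential")
                paste0(" (order ", paste(x$control$order, collapse = ""),
                       if (x$control$pcgrad) ", PCGrad" else "", ")") else "",
              nrow(x$specs), x$model$d_z))
  cat(sprintf("  epochs run: %d (best validation epoch %d, total val loss %.5f)%s\n",
              x$epochs_run, x$best_epoch,
              x$ledger$total$loss[x$best_epoch],
              if (x$converged) "" else " [epoch cap reached]"))
  invisible(x)
}

#' @export
summary.adme_mtl <- function(object, ...) {
  v <- object$ledger$val
  vb <- v[v$epoch == object$best_epoch, ]
  vb$category <- object$ep_cat[vb$endpoint]
  print(object)
  cat("held-out loss at best epoch, by endpoint:\n")
  print(vb[, c("category", "endpoint", "loss", "n")], row.names = FALSE)
  invisible(vb)
}

#' @export
plot.adme_mtl <- function(x, ...) {
  tot <- x$ledger$total
  graphics::plot(tot$epoch, tot$loss, type = "b", pch = 16, cex = 0.6,
                 xlab = "epoch", ylab = "total validation loss", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}

#' Predict endpoints from a fitted model
#'
#' @param object An `adme_mtl` fit.
#' @param newdata Character vector of SMILES (featurized with the fit's
#'   fingerprint configuration) or a feature matrix.
#' @param endpoints Endpoint names (default all).
#' @param ... Unused.
#' @return Named list of prediction vectors (probabilities for
#'   classification endpoints; normalized-scale reals for regression).
#' @export
predict.adme_mtl <- function(object, newdata, endpoints = object$specs$name, ...) {
  X <- if (is.character(newdata))
    featurize_fingerprint(canonicalize_smiles(newdata, opaque = object$fp$opaque),
                          object$fp) else newdata
  predict_endpoints(object$model, X, endpoints)
}

#' @export
encode.adme_mtl <- function(object, features, ...) {
  if (is.character(features))
    features <- featurize_fingerprint(
      canonicalize_smiles(features, opaque = object$fp$opaque), object$fp)
  encode(object$model, features)
}

#' Category-level held-out losses of a fit
#'
#' Unweighted mean of each category's endpoint validation losses at the
#' best epoch — the quantity the task improvement rate is computed from.
#'
#' @param fit An `adme_mtl` object.
#' @return Named numeric vector (one entry per category present).
#' @export
category_val_losses <- function(fit) {
  v <- fit$ledger$val
  vb <- v[v$epoch == fit$best_epoch, ]
  cat_of <- fit$ep_cat[vb$endpoint]
  tapply(vb$loss, cat_of, mean)
}

# ---- checkpoints ---------------------------------------------------------

specs_digest <- function(specs) {
  hash_ints(hash_strings(paste(specs$name, specs$category, specs$task_type,
                               sep = "|")))
}

#' Save a fitted model checkpoint
#'
#' Single serialized file holding the configuration, trunk and head
#' parameters and a digest of the endpoint manifest; [load_checkpoint()]
#' refuses to load against a mismatched manifest.
#'
#' @param fit An `adme_mtl` object.
#' @param path Output file.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "adme_mtl"))
  saveRDS(list(format = "seqadme-checkpoint-1",
               specs_digest = specs_digest(fit$specs), fit = fit), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @param specs Endpoint specification table the checkpoint must match
#'   (`NULL` skips the check).
#' @return The `adme_mtl` object.
#' @export
load_checkpoint <- function(path, specs = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "seqadme-checkpoint-1"))
    stop_named("load_checkpoint: %s is not a seqadme checkpoint", path)
  if (!is.null(specs) && specs_digest(specs) != obj$specs_digest)
    stop_named("load_checkpoint: endpoint manifest does not match the checkpoint")
  obj$fit
}

#' @export
print.loss_ledger <- function(x, ...) {
  cat(sprintf("loss_ledger: %d epochs, %d endpoints\n",
              max(x$total$epoch), length(unique(x$val$endpoint))))
  cat(sprintf("  final total validation loss: %.5f\n",
              x$total$loss[nrow(x$total)]))
  invisible(x)
}

#' Write a loss ledger as delimited text
#'
#' Three CSV files (`<prefix>_train.csv`, `<prefix>_val.csv`,
#' `<prefix>_total.csv`).
#'
#' @param ledger A `loss_ledger`.
#' @param prefix Output path prefix.
#' @export
write_ledger <- function(ledger, prefix) {
  utils::write.csv(ledger$train, paste0(prefix, "_train.csv"), row.names = FALSE)
  utils::write.csv(ledger$val, paste0(prefix, "_val.csv"), row.names = FALSE)
  utils::write.csv(ledger$total, paste0(prefix, "_total.csv"), row.names = FALSE)
  invisible(prefix)
}
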