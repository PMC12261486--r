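# Fixture builders.  Trainer-mechanics tests use opaque keys and random
# feature matrices so they exercise the engine without touching the
# chemistry toolkit; chemistry-dependent tests build small real-molecule
# sets.

toy_specs <- function(categories = c("A", "D", "M", "E"), per = 2L) {
  nm <- unlist(lapply(categories, function(ct) paste0(ct, seq_len(per))))
  endpoint_specs(nm, rep(categories, each = per),
                 rep(rep(c("classification", "regression"), length.out = per),
                     length(categories)))
}

# A hand-built adme_dataset with opaque keys, random labels and ~85%
# observation; labels under FALSE mask bits carry a poison value so that
# any code path reading them is caught immediately.
make_toy_dataset <- function(n = 60L, specs = toy_specs(), seed = 1L,
                             missing_rate = 0.15, poison = 999) {
  set.seed(seed)
  keys <- sprintf("K%04d", seq_len(n))
  p <- nrow(specs)
  labels <- matrix(NA_real_, n, p, dimnames = list(NULL, specs$name))
  mask <- matrix(runif(n * p) >= missing_rate, n, p,
                 dimnames = list(NULL, specs$name))
  for (j in seq_len(p)) {
    labels[, j] <- if (specs$task_type[j] == "classification")
      rbinom(n, 1, 0.5) else rnorm(n)
  }
  labels[!mask] <- poison
  structure(list(keys = keys, labels = labels, mask = mask,
                 specs = specs, folds = NULL),
            class = "adme_dataset")
}

toy_features <- function(n, d = 32L, seed = 2L) {
  set.seed(seed)
  matrix(as.numeric(runif(n * d) < 0.3), n, d)
}

fast_control <- function(...) {
  train_config(epochs_max = 3L, batch_size = 32L, hidden = 16L, d_z = 8L,
               patience = 2L, ...)
}

# Small real-molecule synthetic study, memoised across tests within a run.
local_syn <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_molecules = 150L, seed = 90L)
      cache <<- c(synthetic_adme_dataset(cfg), list(cfg = cfg))
    }
    cache
  }
})

ledger_equal <- function(a, b) {
  isTRUE(all.equal(a$train, b$train, tolerance = 0)) &&
    isTRUE(all.equal(a$val, b$val, tolerance = 0)) &&
    isTRUE(all.equal(a$total, b$total, tolerance = 0))
}
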