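#' Declare ADME endpoint specifications
#'
#' One row per endpoint: its short name, its pharmacokinetic category
#' (A = absorption, D = distribution, M = metabolism, E = excretion) and its
#' task type.  Normalization statistics (`norm_mean`, `norm_sd`) start unset
#' and are filled by [fit_normalization()] for regression endpoints.
#'
#' @param name Character vector of endpoint names (unique).
#' @param category Character vector over `{"A","D","M","E"}`.
#' @param task_type Character vector over `{"classification","regression"}`.
#' @return A `data.frame` with columns name, category, task_type,
#'   norm_mean, norm_sd.
#' @export
endpoint_specs <- function(name, category, task_type) {
  stopifnot(length(name) == length(category),
            length(name) == length(task_type))
  if (anyDuplicated(name)) stop_named("endpoint_specs: duplicate endpoint names")
  if (!all(category %in% c("A", "D", "M", "E")))
    stop_named("endpoint_specs: category must be one of A, D, M, E")
  if (!all(task_type %in% c("classification", "regression")))
    stop_named("endpoint_specs: task_type must be classification or regression")
  data.frame(name = as.character(name), category = as.character(category),
             task_type = as.character(task_type),
             norm_mean = NA_real_, norm_sd = NA_real_,
             stringsAsFactors = FALSE)
}

#' Aggregate per-endpoint tables into one masked multi-task dataset
#'
#' Merges per-endpoint `(smiles, label)` tables on the canonical molecule
#' key: one record per unique canonical SMILES, with a label and an observed
#' mask per endpoint.  A molecule missing from an endpoint's table is masked
#' out for that endpoint and excluded from its training and evaluation.
#'
#' Duplicate `(key, endpoint)` entries are consolidated: classification
#' labels by majority vote (ties drop the pair, i.e. mask it out),
#' regression labels by arithmetic mean.  With `on_conflict = "error"`,
#' classification ties raise an error listing the offending keys instead.
#'
#' @param tables Named list (endpoint name -> `data.frame`) with columns
#'   `smiles` and `label` (an `id` column is accepted and ignored for
#'   merging).
#' @param specs Endpoint specification table from [endpoint_specs()]
#'   covering every name in `tables`.
#' @param opaque_keys Logical; skip chemical canonicalization and use raw
#'   strings as keys (fixture mode).
#' @param on_conflict `"resolve"` (default) or `"error"`.
#' @return An object of class `adme_dataset`: list with `keys` (character),
#'   `labels` (numeric matrix, `NA` where unobserved), `mask` (logical
#'   matrix), `specs`, and `folds` (`NULL` until assigned).
#' @export
aggregate_endpoints <- function(tables, specs, opaque_keys = FALSE,
                                on_conflict = c("resolve", "error")) {
  on_conflict <- match.arg(on_conflict)
  if (!is.list(tables) || length(tables) == 0L || is.null(names(tables)))
    stop_named("aggregate_endpoints: 'tables' must be a non-empty named list")
  missing_spec <- setdiff(names(tables), specs$name)
  if (length(missing_spec))
    stop_named("aggregate_endpoints: no spec for endpoint(s): %s",
               paste(missing_spec, collapse = ", "))
  specs <- specs[specs$name %in% names(tables), , drop = FALSE]
  rownames(specs) <- NULL

  canon <- lapply(names(tables), function(e) {
    tb <- tables[[e]]
    stopifnot(all(c("smiles", "label") %in% names(tb)))
    canonicalize_smiles(as.character(tb$smiles), opaque = opaque_keys)
  })
  names(canon) <- names(tables)
  keys <- sort(unique(unlist(canon, use.names = FALSE)))
  p <- nrow(specs)
  labels <- matrix(NA_real_, length(keys), p,
                   dimnames = list(NULL, specs$name))
  mask <- matrix(FALSE, length(keys), p, dimnames = list(NULL, specs$name))

  conflicts <- character(0)
  for (e in specs$name) {
    tb <- tables[[e]]
    ck <- canon[[e]]
    val <- as.numeric(tb$label)
    ttype <- specs$task_type[specs$name == e]
    if (ttype == "classification" && !all(val[!is.na(val)] %in% c(0, 1)))
      stop_named("aggregate_endpoints: endpoint '%s' has non-binary classification labels", e)
    agg <- tapply(val, ck, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      if (ttype == "regression") return(mean(v))
      n1 <- sum(v == 1); n0 <- sum(v == 0)
      if (n1 == n0) return(NA_real_)  # tie -> drop the pair
      as.numeric(n1 > n0)
    })
    if (ttype == "classification" && on_conflict == "error") {
      tied <- tapply(val, ck, function(v) {
        v <- v[!is.na(v)]
        length(v) && sum(v == 1) == sum(v == 0)
      })
      if (any(tied))
        conflicts <- c(conflicts,
                       paste0(e, ": ", paste(names(tied)[tied], collapse = ", ")))
    }
    idx <- match(names(agg), keys)
    labels[idx, e] <- as.numeric(agg)
    mask[idx, e] <- !is.na(agg)
  }
  if (length(conflicts))
    stop_named("aggregate_endpoints: unresolvable duplicate labels under strict mode:\n%s",
               paste(conflicts, collapse = "\n"))

  structure(list(keys = keys, labels = labels, mask = mask,
                 specs = specs, folds = NULL),
            class = "adme_dataset")
}

#' @export
print.adme_dataset <- function(x, ...) {
  cat(sprintf("adme_dataset: %d molecules x %d endpoints\n",
              length(x$keys), nrow(x$specs)))
  obs <- colSums(x$mask)
  for (i in seq_len(nrow(x$specs)))
    cat(sprintf("  %-14s [%s, %s] %d observed%s\n", x$specs$name[i],
                x$specs$category[i], substr(x$specs$task_type[i], 1, 5),
                obs[i],
                if (!is.na(x$specs$norm_mean[i])) " (normalized)" else ""))
  if (!is.null(x$folds))
    cat(sprintf("  folds: %s\n", paste(table(x$folds), collapse = "/")))
  invisible(x)
}

#' Fit train-set normalization and apply it to all observed values
#'
#' For each regression endpoint, the z-score transform is fitted on the
#' observed values of the training molecules only (mean and population
#' standard deviation, i.e. dividing by `n`) and applied to every observed
#' value, train and held-out alike.  This puts all regression targets on a
#' comparable scale so that squared-error and cross-entropy losses
#' contribute comparably to the multi-task objective.  Classification
#' labels are untouched.
#'
#' @param dataset An `adme_dataset`.
#' @param train_keys Character vector of keys whose values may inform the
#'   fitted statistics.
#' @return The dataset with transformed regression labels and
#'   `norm_mean`/`norm_sd` filled in `specs`.
#' @export
fit_normalization <- function(dataset, train_keys) {
  stopifnot(inherits(dataset, "adme_dataset"))
  intr <- dataset$keys %in% train_keys
  for (i in seq_len(nrow(dataset$specs))) {
    if (dataset$specs$task_type[i] != "regression") next
    e <- dataset$specs$name[i]
    obs_tr <- intr & dataset$mask[, e]
    v <- dataset$labels[obs_tr, e]
    if (length(v) < 2)
      stop_named("fit_normalization: endpoint '%s' has < 2 observed training values", e)
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    if (sd_pop == 0)
      stop_named("fit_normalization: endpoint '%s' has zero spread on the training set", e)
    obs <- dataset$mask[, e]
    dataset$labels[obs, e] <- (dataset$labels[obs, e] - mu) / sd_pop
    dataset$specs$norm_mean[i] <- mu
    dataset$specs$norm_sd[i] <- sd_pop
  }
  dataset
}

#' Stratified k-fold assignment for a binary label
#'
#' Shuffles each class with a seeded RNG and deals it round-robin across
#' folds, so every fold's positive count is within one of the proportional
#' share.  Fold indices are 0-based; fold `f` serves as the test fold in
#' cross-validation round `f`.
#'
#' @param labels Binary vector (0/1), one per record.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Integer vector of fold indices in `0..k-1`.
#' @export
stratified_kfold <- function(labels, k, seed) {
  stopifnot(k >= 2, all(labels %in% c(0, 1)))
  if (k > length(labels))
    stop_named("stratified_kfold: k = %d exceeds the number of records (%d)",
               k, length(labels))
  folds <- integer(length(labels))
  set.seed(as.integer(seed))
  counter <- 0L
  for (cls in sort(unique(labels), decreasing = TRUE)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    # a running counter across classes keeps total fold sizes balanced too
    folds[idx] <- (counter + seq_along(idx) - 1L) %% as.integer(k)
    counter <- counter + length(idx)
  }
  folds
}

#' Hash-based k-fold assignment keyed on molecule identity
#'
#' Deterministic pseudo-random fold assignment from a seeded hash of each
#' canonical key.  Used for the multi-endpoint ADME dataset, which has no
#' single label to stratify on; the drug-likeness dataset uses
#' [stratified_kfold()] instead.
#'
#' @param keys Character vector of canonical keys.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `0..k-1`.
#' @export
hash_kfold <- function(keys, k, seed) {
  stopifnot(k >= 2)
  as.integer(hash_strings(keys, seed = as.integer(seed)) %% k)
}

#' Attach a fold assignment to a dataset
#'
#' @param dataset An `adme_dataset`.
#' @param folds Integer vector of 0-based fold indices, one per record.
#' @return The dataset with `folds` set.
#' @export
assign_folds <- function(dataset, folds) {
  stopifnot(inherits(dataset, "adme_dataset"),
            length(folds) == length(dataset$keys))
  dataset$folds <- as.integer(folds)
  dataset
}

# ---- on-disk layout ------------------------------------------------------

#' Read one endpoint table in the TDC single-instance layout
#'
#' Delimited text with header columns `id`, `smiles`, `label` (extra
#' columns ignored).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A `data.frame` with columns id, smiles, label.
#' @export
read_endpoint_table <- function(path, sep = ",") {
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("smiles", "label")
  if (!all(need %in% names(tb)))
    stop_named("read_endpoint_table: %s lacks columns %s", path,
               paste(setdiff(need, names(tb)), collapse = ", "))
  if (!"id" %in% names(tb)) tb$id <- seq_len(nrow(tb))
  tb[, c("id", "smiles", "label")]
}

#' Read an endpoint manifest
#'
#' CSV mapping endpoint files to names: columns `file`, `name`, `category`,
#' `task_type`.  Paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest file path.
#' @return List with `specs` (an [endpoint_specs()] table) and `files`
#'   (named character vector of resolved paths).
#' @export
read_endpoint_manifest <- function(path) {
  mf <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("file", "name", "category", "task_type") %in% names(mf)))
  specs <- endpoint_specs(mf$name, mf$category, mf$task_type)
  files <- file.path(dirname(path), mf$file)
  names(files) <- mf$name
  list(specs = specs, files = files)
}

#' Load and aggregate the endpoint tables named by a manifest
#'
#' @param manifest_path Path to the manifest CSV (see
#'   [read_endpoint_manifest()]).
#' @inheritParams aggregate_endpoints
#' @return An `adme_dataset`.
#' @export
load_adme_dataset <- function(manifest_path, opaque_keys = FALSE,
                              on_conflict = "resolve") {
  mf <- read_endpoint_manifest(manifest_path)
  tables <- lapply(mf$files, read_endpoint_table)
  aggregate_endpoints(tables, mf$specs, opaque_keys = opaque_keys,
                      on_conflict = on_conflict)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write an aggregated dataset to its on-disk layout
#'
#' One wide CSV (`<prefix>.csv`: key plus one value and one mask column per
#' endpoint) and a JSON sidecar (`<prefix>.json`) holding the endpoint
#' specs with any fitted normalization statistics and the fold assignment.
#' Numbers are written with full precision so a write/read/write cycle is
#' byte-stable.
#'
#' @param dataset An `adme_dataset`.
#' @param prefix Output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_adme_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "adme_dataset"))
  eps <- dataset$specs$name
  cols <- c(list(key = dataset$keys),
            stats::setNames(lapply(eps, function(e) fmt_num(dataset$labels[, e])),
                            paste0(eps, "_value")),
            stats::setNames(lapply(eps, function(e) as.integer(dataset$mask[, e])),
                            paste0(eps, "_mask")))
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE, quote = FALSE)
  side <- list(endpoints = dataset$specs,
               folds = if (is.null(dataset$folds)) NULL else dataset$folds)
  jsonlite::write_json(side, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null",
                       pretty = TRUE)
  invisible(prefix)
}

#' Read an aggregated dataset written by [write_adme_dataset()]
#'
#' @param prefix Path prefix used when writing.
#' @return An `adme_dataset` identical to the one written.
#' @export
read_adme_dataset <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  specs <- as.data.frame(side$endpoints, stringsAsFactors = FALSE)
  specs$norm_mean <- as.numeric(specs$norm_mean)
  specs$norm_sd <- as.numeric(specs$norm_sd)
  eps <- specs$name
  labels <- sapply(eps, function(e) {
    v <- df[[paste0(e, "_value")]]
    as.numeric(ifelse(v == "", NA, v))
  })
  mask <- sapply(eps, function(e) df[[paste0(e, "_mask")]] == "1")
  if (length(df$key) == 1L) {  # sapply drops to vector for one row
    labels <- matrix(labels, 1, dimnames = list(NULL, eps))
    mask <- matrix(mask, 1, dimnames = list(NULL, eps))
  }
  folds <- side$folds
  structure(list(keys = df$key, labels = labels, mask = mask,
                 specs = specs,
                 folds = if (is.null(folds)) NULL else as.integer(folds)),
            class = "adme_dataset")
}
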