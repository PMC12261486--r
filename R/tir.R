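# Task-dependency analysis: brute-force combination sweep over category
# subsets, task improvement rate (TIR), and the signed dependency graph.
#
# TIR(target | partner) = (L_STL(target) - L_MTL(target|partner)) / L_STL(target)
#
# where L_STL is the target category's held-out loss when trained alone and
# L_MTL(target|partner) averages the target's held-out loss over every
# trained subset that contains both categories.  A positive rate means
# co-training with the partner lowered the target's loss; a negative rate
# means interference.

all_category_subsets <- function(categories = c("A", "D", "M", "E")) {
  n <- length(categories)
  subs <- list()
  for (m in 1:(2^n - 1)) {
    subs[[length(subs) + 1L]] <- categories[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]
  }
  subs
}

subset_key <- function(s) paste(sort(s), collapse = "")

#' Brute-force combination sweep over category subsets
#'
#' Trains one naive (unordered, jointly batched) multi-task model per
#' requested category subset and records each member category's held-out
#' loss (the unweighted mean of its endpoints' validation losses at the
#' best epoch).  The default sweeps all 15 non-empty subsets of
#' `{A, D, M, E}`.
#'
#' All subsets train under one common seed derived from the base seed
#' (common random numbers): every configuration shares the same parameter
#' initialization, validation molecules and shuffling stream, so
#' loss differences between subsets — the quantity TIR is built from —
#' are not confounded by split or initialization noise.  Two sweeps with
#' the same configuration are identical.
#'
#' @param dataset An `adme_dataset` covering the swept categories.
#' @param control A [train_config()]; its mode is overridden per subset.
#' @param subsets Optional list of character vectors (category subsets).
#' @param features Optional precomputed feature matrix.
#' @param fp An [fp_config()] used when `features` is missing.
#' @return A `task_loss_table`: named list subset-key -> named numeric
#'   vector of member-category losses.
#' @export
run_combination_sweep <- function(dataset, control = train_config(mode = "subset",
                                                                  subset_categories = "A"),
                                  subsets = NULL, features = NULL,
                                  fp = fp_config()) {
  stopifnot(inherits(dataset, "adme_dataset"))
  if (is.null(subsets))
    subsets <- all_category_subsets(intersect(c("A", "D", "M", "E"),
                                              unique(dataset$specs$category)))
  keys <- vapply(subsets, subset_key, character(1))
  if (anyDuplicated(keys))
    stop_named("run_combination_sweep: duplicate subsets requested: %s",
               paste(unique(keys[duplicated(keys)]), collapse = ", "))
  if (is.null(features)) features <- featurize_fingerprint(dataset$keys, fp)
  table <- stats::setNames(vector("list", length(subsets)), keys)
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    cfg <- control
    cfg$mode <- "subset"
    cfg$subset_categories <- s
    cfg$pcgrad <- FALSE  # the sweep characterizes naive co-training
    cfg$seed <- substream_seed(control$seed, "sweep")
    fit <- adme_mtl(dataset, cfg, features = features, fp = fp)
    losses <- category_val_losses(fit)
    ss <- sort(s)
    table[[keys[i]]] <- stats::setNames(as.numeric(losses[ss]), ss)
  }
  structure(table, class = "task_loss_table")
}

#' @export
print.task_loss_table <- function(x, ...) {
  cat("task_loss_table:\n")
  for (k in names(x))
    cat(sprintf("  %-5s %s\n", k,
                paste(sprintf("%s=%.4f", names(x[[k]]), x[[k]]), collapse = "  ")))
  invisible(x)
}

#' Task improvement rate of one category given a partner
#'
#' `TIR(target|partner) = (L_STL - L_MTL) / L_STL`, where `L_MTL` is the
#' arithmetic mean of the target's loss over all swept subsets containing
#' both the target and the partner.
#'
#' @param table A `task_loss_table` from [run_combination_sweep()] (or
#'   hand-built: a named list, names like `"AD"`, values named numeric
#'   vectors of member-category losses).
#' @param target,partner Category letters.
#' @return The improvement rate (positive = co-training helps the target).
#' @export
compute_tir <- function(table, target, partner) {
  stopifnot(target != partner)
  if (!(target %in% names(table)))
    stop_named("compute_tir: singleton subset '%s' missing from the table", target)
  l_stl <- unname(table[[target]][target])
  if (is.na(l_stl)) stop_named("compute_tir: no loss recorded for singleton '%s'", target)
  if (l_stl == 0) stop_named("compute_tir: L_STL(%s) = 0, ratio undefined", target)
  qual <- names(table)[vapply(names(table), function(k) {
    cats <- strsplit(k, "")[[1]]
    target %in% cats && partner %in% cats
  }, logical(1))]
  if (!length(qual))
    stop_named("compute_tir: no swept subset contains both %s and %s",
               target, partner)
  l_mtl <- mean(vapply(qual, function(k) unname(table[[k]][target]), numeric(1)))
  (l_stl - l_mtl) / l_stl
}

#' Full 4x4 task-improvement-rate matrix
#'
#' @param table A `task_loss_table`.
#' @param categories Categories to include (default: those with singleton
#'   entries in the table).
#' @return Numeric matrix, rows = target, columns = partner, `NA` on the
#'   diagonal.
#' @export
tir_matrix <- function(table, categories = NULL) {
  if (is.null(categories))
    categories <- sort(names(table)[nchar(names(table)) == 1])
  m <- matrix(NA_real_, length(categories), length(categories),
              dimnames = list(target = categories, partner = categories))
  for (tg in categories) for (pt in categories) {
    if (tg != pt) m[tg, pt] <- compute_tir(table, tg, pt)
  }
  m
}

#' Signed task-dependency graph from a TIR matrix
#'
#' Emits one directed edge partner -> target for every off-diagonal cell
#' with `|TIR| >= threshold`, signed by the direction of the effect and
#' weighted by its magnitude.
#'
#' @param tir A matrix from [tir_matrix()].
#' @param threshold Non-negative magnitude cutoff.
#' @return A `data.frame` edge list: source, target, tir, sign, weight.
#' @export
build_dependency_graph <- function(tir, threshold = 0) {
  if (threshold < 0) stop_named("build_dependency_graph: threshold must be >= 0")
  rows <- list()
  for (tg in rownames(tir)) for (pt in colnames(tir)) {
    v <- tir[tg, pt]
    if (tg == pt || is.na(v) || abs(v) < threshold) next
    rows[[length(rows) + 1L]] <-
      data.frame(source = pt, target = tg, tir = v,
                 sign = if (v >= 0) "+" else "-", weight = abs(v))
  }
  if (!length(rows))
    return(data.frame(source = character(0), target = character(0),
                      tir = numeric(0), sign = character(0),
                      weight = numeric(0)))
  do.call(rbind, rows)
}

#' Write a task-loss table as delimited text
#'
#' @param table A `task_loss_table`.
#' @param path Output CSV path (columns subset, category, loss).
#' @export
write_task_loss_table <- function(table, path) {
  rows <- do.call(rbind, lapply(names(table), function(k)
    data.frame(subset = k, category = names(table[[k]]),
               loss = fmt_num(unname(table[[k]])))))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a task-loss table written by [write_task_loss_table()]
#'
#' @param path CSV path.
#' @return A `task_loss_table`.
#' @export
read_task_loss_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  out <- lapply(split(df, df$subset), function(d)
    stats::setNames(as.numeric(d$loss), d$category))
  structure(out[unique(df$subset)], class = "task_loss_table")
}
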