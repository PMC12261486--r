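# Pipeline wiring: run the stages (generate -> aggregate -> train-adme ->
# sweep-tir -> embed -> train-dl -> evaluate) from one structured-text
# config, with a run manifest recording the resolved config, seed, input
# digests and outcome.  All stage randomness derives from the single run
# seed through named substreams.

pipeline_defaults <- function() list(
  seed = 1L,
  out = "seqadme_run",
  stages = c("generate", "aggregate", "train_adme", "sweep_tir",
             "embed", "train_dl", "evaluate"),
  fingerprint = list(radius = 2L, n_bits = 256L),
  generate = list(n_molecules = 2000L, endpoints_per_category = 2L,
                  chain_strength = 0.8, noise_sd = 0.3, missing_rate = 0.2),
  aggregate = list(manifest = NULL, val_fraction = 0.1),
  train_adme = list(order = "ADME", mode = "sequential", pcgrad = TRUE,
                    epochs_max = 30L, batch_size = 128L,
                    learning_rate = 1e-3, hidden = 64L, d_z = 32L,
                    patience = 5L, convergence_tol = 1e-4),
  sweep_tir = list(epochs_max = 20L, threshold = 0),
  train_dl = list(k = 5L, hidden = c(128L, 128L), epochs_max = 100L),
  evaluate = list(scores = NULL, labels = NULL)
)

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

parse_order <- function(s) {
  ord <- strsplit(toupper(s), "")[[1]]
  if (!setequal(ord, c("A", "D", "M", "E")) || length(ord) != 4)
    stop_named("order '%s' must be a permutation of ADME", s)
  ord
}

pkg_version <- function() {
  as.character(utils::packageVersion("seqadme"))
}

write_run_manifest <- function(out, command, config, inputs, status) {
  digests <- if (length(inputs))
    stats::setNames(as.character(tools::md5sum(inputs)), basename(inputs))
  else NULL
  jsonlite::write_json(
    list(command = command, config = config, seed = config$seed,
         input_digests = digests, tool_version = pkg_version(),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         status = status),
    file.path(out, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}

require_input <- function(path, what) {
  if (!file.exists(path))
    stop_named("missing upstream artifact: %s (%s)", what, path)
  path
}

#' Run the full pipeline from a structured-text config
#'
#' Executes the requested stages in dependency order under one run seed.
#' Stage outputs land under `config$out`; every run writes a
#' `run_manifest.json` with the resolved config, input file digests and
#' the outcome (`ok` / `failed`).  A re-run with an identical config and
#' seed reproduces identical metric files.
#'
#' @param config_file Path to a YAML config; any omitted field falls back
#'   to the package defaults (see the pipeline vignette).  Alternatively a
#'   named list with the same structure.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config_file) {
  user <- if (is.character(config_file)) {
    if (!file.exists(config_file))
      stop_named("config file not found: %s", config_file)
    yaml::read_yaml(config_file)
  } else config_file
  config <- merge_config(pipeline_defaults(), user)
  known <- pipeline_defaults()$stages
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop_named("unknown stage(s): %s", paste(bad, collapse = ", "))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  status <- "failed"
  on.exit(write_run_manifest(out, "run", config, inputs, status))

  seed <- as.integer(config$seed)
  fp <- fp_config(radius = config$fingerprint$radius,
                  n_bits = config$fingerprint$n_bits)
  log_file <- file.path(out, "run.log")
  logmsg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }

  for (stage in known[known %in% config$stages]) {
    logmsg("stage %s", stage)
    switch(stage,
      generate = {
        g <- config$generate
        cfg <- synthetic_config(n_molecules = g$n_molecules,
                                endpoints_per_category = g$endpoints_per_category,
                                chain_strength = g$chain_strength,
                                noise_sd = g$noise_sd,
                                missing_rate = g$missing_rate,
                                seed = substream_seed(seed, "data"), fp = fp)
        write_synthetic_dataset(cfg, file.path(out, "data"))
      },
      aggregate = {
        mf <- config$aggregate$manifest %||% file.path(out, "data", "manifest.csv")
        inputs <- c(inputs, require_input(mf, "endpoint manifest"))
        ds <- load_adme_dataset(mf)
        is_val <- validation_split(ds$keys, seed, config$aggregate$val_fraction)
        ds <- fit_normalization(ds, ds$keys[!is_val])
        ds <- assign_folds(ds, hash_kfold(ds$keys, 5L,
                                          substream_seed(seed, "folds")))
        write_adme_dataset(ds, file.path(out, "adme_dataset"))
      },
      train_adme = {
        t <- config$train_adme
        ds_path <- require_input(file.path(out, "adme_dataset.csv"),
                                 "aggregated dataset")
        ds <- read_adme_dataset(sub("[.]csv$", "", ds_path))
        ds$labels[!ds$mask] <- NA  # placeholder hygiene
        ctl <- train_config(order = parse_order(t$order), mode = t$mode,
                            pcgrad = t$pcgrad, epochs_max = t$epochs_max,
                            batch_size = t$batch_size,
                            learning_rate = t$learning_rate,
                            convergence_tol = t$convergence_tol,
                            patience = t$patience, hidden = t$hidden,
                            d_z = t$d_z, seed = seed,
                            val_fraction = config$aggregate$val_fraction)
        fit <- adme_mtl(ds, ctl, fp = fp)
        save_checkpoint(fit, file.path(out, "encoder.rds"))
        write_ledger(fit$ledger, file.path(out, "ledger"))
        jsonlite::write_json(list(order = t$order, mode = t$mode,
                                  pcgrad = t$pcgrad, seed = seed,
                                  best_epoch = fit$best_epoch,
                                  epochs_run = fit$epochs_run),
                             file.path(out, "train_config_echo.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        logmsg("trained: best epoch %d of %d", fit$best_epoch, fit$epochs_run)
      },
      sweep_tir = {
        ds_path <- require_input(file.path(out, "adme_dataset.csv"),
                                 "aggregated dataset")
        ds <- read_adme_dataset(sub("[.]csv$", "", ds_path))
        ctl <- train_config(mode = "subset", subset_categories = "A",
                            epochs_max = config$sweep_tir$epochs_max,
                            hidden = config$train_adme$hidden,
                            d_z = config$train_adme$d_z,
                            seed = substream_seed(seed, "sweep"))
        table <- run_combination_sweep(ds, ctl, fp = fp)
        write_task_loss_table(table, file.path(out, "task_loss_table.csv"))
        tm <- tir_matrix(table)
        utils::write.csv(cbind(data.frame(target = rownames(tm)), as.data.frame(tm)),
                         file.path(out, "tir_matrix.csv"), row.names = FALSE)
        utils::write.csv(build_dependency_graph(tm, config$sweep_tir$threshold),
                         file.path(out, "dependency_edges.csv"), row.names = FALSE)
      },
      embed = {
        fit <- load_checkpoint(require_input(file.path(out, "encoder.rds"),
                                             "trained encoder"))
        dlf <- require_input(file.path(out, "data", "druglikeness.csv"),
                             "drug-likeness table")
        inputs <- c(inputs, dlf)
        dl <- utils::read.csv(dlf, stringsAsFactors = FALSE)
        Z <- encode(fit, as.character(dl$smiles))
        emb <- data.frame(id = dl$id, label = dl$label)
        for (j in seq_len(ncol(Z))) emb[[paste0("z", j)]] <- fmt_num(Z[, j])
        utils::write.csv(emb, file.path(out, "embeddings.csv"),
                         row.names = FALSE, quote = FALSE)
      },
      train_dl = {
        emb <- utils::read.csv(require_input(file.path(out, "embeddings.csv"),
                                             "embeddings"),
                               stringsAsFactors = FALSE)
        Z <- as.matrix(emb[, grep("^z", names(emb)), drop = FALSE])
        cvfit <- druglikeness_cv(Z, emb$label, k = config$train_dl$k,
                                 seed = substream_seed(seed, "dl"),
                                 hidden = config$train_dl$hidden,
                                 epochs_max = config$train_dl$epochs_max)
        write_metric_report(cvfit$report, file.path(out, "dl_metrics.csv"))
        utils::write.csv(data.frame(id = emb$id, label = emb$label,
                                    score = fmt_num(cvfit$scores)),
                         file.path(out, "dl_scores.csv"), row.names = FALSE,
                         quote = FALSE)
        logmsg("drug-likeness CV MCC %.3f", cvfit$report$mean["mcc"])
      },
      evaluate = {
        sf <- config$evaluate$scores %||% file.path(out, "dl_scores.csv")
        inputs <- c(inputs, require_input(sf, "score file"))
        sc <- utils::read.csv(sf, stringsAsFactors = FALSE)
        labels <- if (!is.null(config$evaluate$labels)) {
          lf <- require_input(config$evaluate$labels, "label file")
          utils::read.csv(lf, stringsAsFactors = FALSE)$label
        } else sc$label
        ev <- evaluate_binary(as.numeric(sc$score), as.numeric(labels))
        jsonlite::write_json(ev[c("mcc", "f1", "auprc")],
                             file.path(out, "evaluation.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      })
  }
  status <- "ok"
  invisible(out)
}
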