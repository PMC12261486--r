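# Synthetic fixture generator: small drug-like molecules from a fragment
# vocabulary, multi-endpoint ADME labels driven by a planted A -> D -> M -> E
# latent dependency chain, per-endpoint missingness, and a drug-likeness
# label derived from the latents.  Everything is a pure function of the
# configuration, so two runs with the same config are byte-identical.

# Scaffold templates, each with two substitution slots, decorated
# combinatorially with terminal substituents.  All products are valid
# SMILES by construction (slots sit on ring or chain atoms).
synthetic_scaffolds <- function() c(
  "c1cc(%s)ccc1%s",            # benzene, para-ish
  "c1c(%s)cccc1%s",            # benzene, ortho-ish
  "c1cc(%s)cc(%s)c1",          # benzene, meta
  "c1ccc2c(c1)cc(%s)n2%s",     # indole, 3- and N-substituted
  "c1cnc(%s)cc1%s",            # pyridine
  "c1cnc(%s)nc1%s",            # pyrimidine
  "c1cc(%s)c(%s)cn1",          # pyridine, disubstituted
  "c1csc(%s)c1%s",             # thiophene
  "c1coc(%s)c1%s",             # furan
  "c1cn(%s)cc1%s",             # N-substituted pyrrole
  "C1CCC(%s)(%s)CC1",          # cyclohexane gem
  "C1CCC(%s)CC1%s",            # cyclohexane 1,?-
  "C1CCN(%s)CC1%s",            # piperidine N-sub
  "C1CCOC1C(%s)%s",            # tetrahydrofuran side chain
  "C1CC1C(%s)%s",              # cyclopropane side chain
  "CC(%s)CC(%s)C",             # branched chain
  "CCC(%s)C(%s)CC",            # hexane backbone
  "C(%s)C(%s)O",               # glycol-like
  "CC(=O)N(%s)C(%s)C",         # amide core
  "CC(=O)OC(%s)C%s",           # ester core
  "N(%s)C(=O)C(%s)C",          # reversed amide
  "CS(=O)(=O)N(%s)C%s",        # sulfonamide
  "CC(%s)NC(=O)N(%s)C",        # urea
  "c1cc(%s)ccc1OC%s",          # aryl ether
  "c1cc(%s)ccc1N(C)C%s",       # aryl amine
  "c1cc(%s)ccc1C(=O)N(%s)C",   # benzamide
  "c1cc(%s)ccc1S(=O)(=O)N(%s)C", # aryl sulfonamide
  "C1=CC(%s)CC(%s)C1",         # cyclohexene
  "c1cc2ccccc2c(%s)c1%s",      # naphthalene
  "c1cnn(%s)c1%s"              # N-substituted pyrazole
)

synthetic_substituents <- function() c(
  "C", "CC", "CCC", "CCO", "CO", "CN", "CCN", "O", "N", "F", "Cl", "Br",
  "C(=O)O", "C(=O)N", "C#N", "C(C)C", "OC", "CCF"
)

#' Configuration of the synthetic ADME study
#'
#' Defines the planted study conditions: how many molecules, how many
#' endpoints per pharmacokinetic category, the strength of the latent
#' A -> D -> M -> E dependency chain (the fraction of a downstream latent's
#' variance inherited from its upstream neighbor), the observation noise,
#' and the per-endpoint missingness.
#'
#' @param n_molecules Number of molecules.
#' @param endpoints_per_category Endpoints per category (>= 2; types
#'   alternate classification/regression within each category).
#' @param chain_strength In `[0, 1]`; 0 severs the chain (independent
#'   categories), values near 1 make downstream latents copies of
#'   upstream ones.
#' @param noise_sd Standard deviation of the Gaussian noise added to each
#'   latent and each endpoint readout (latents have unit variance).
#' @param missing_rate Independent probability that a molecule's label for
#'   an endpoint is unobserved.
#' @param seed Integer seed; the generated set is a pure function of this
#'   configuration.
#' @param fp Fingerprint configuration used to build the
#'   fingerprint-computable part of the latent signal (so that a
#'   fingerprint encoder can in principle learn the labels).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_molecules = 2000L, endpoints_per_category = 2L,
                             chain_strength = 0.8, noise_sd = 0.3,
                             missing_rate = 0.2, seed = 1L,
                             fp = fp_config(radius = 2L, n_bits = 256L)) {
  stopifnot(n_molecules >= 1, endpoints_per_category >= 2,
            chain_strength >= 0, chain_strength <= 1, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (noise_sd == 0 && chain_strength == 1)
    warning("synthetic_config: noise_sd = 0 with chain_strength = 1 is degenerate")
  structure(list(n_molecules = as.integer(n_molecules),
                 endpoints_per_category = as.integer(endpoints_per_category),
                 chain_strength = chain_strength, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 fp = fp),
            class = "synthetic_config")
}

#' Generate a reproducible set of unique small molecules
#'
#' Molecules are assembled by decorating ~30 scaffold templates with two
#' terminal substituents each; the combinatorial space is sampled without
#' replacement in a seeded order and deduplicated on the canonical SMILES
#' key, so the output is deterministic, chemically valid and unique.
#'
#' @param cfg A [synthetic_config()].
#' @return Character vector of `cfg$n_molecules` canonical SMILES.
#' @export
generate_molecules <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sc <- synthetic_scaffolds(); su <- synthetic_substituents()
  space <- length(sc) * length(su) * length(su)
  set.seed(substream_seed(cfg$seed, "molecules"))
  ord <- sample.int(space)
  out <- character(0)
  pos <- 0L
  chunk <- max(256L, cfg$n_molecules)
  while (length(out) < cfg$n_molecules && pos < space) {
    take <- ord[(pos + 1):min(pos + chunk, space)]
    pos <- pos + length(take)
    i_sc <- (take - 1L) %% length(sc) + 1L
    rest <- (take - 1L) %/% length(sc)
    i_s1 <- rest %% length(su) + 1L
    i_s2 <- rest %/% length(su) + 1L
    smi <- sprintf(sc[i_sc], su[i_s1], su[i_s2])
    can <- canonicalize_smiles(smi)
    new <- !(can %in% out) & !duplicated(can)
    out <- c(out, can[new])
  }
  if (length(out) < cfg$n_molecules)
    stop_named("generate_molecules: requested %d but only %d unique molecules are enumerable",
               cfg$n_molecules, length(out))
  out[seq_len(cfg$n_molecules)]
}

#' Generate ADME endpoint labels with a planted dependency chain
#'
#' Latent construction: `u_A` is a standardized linear readout of the
#' molecule fingerprint plus Gaussian noise; each downstream latent mixes
#' `sqrt(chain_strength)` of its upstream neighbor with
#' `sqrt(1 - chain_strength)` of an independent fingerprint signal, plus
#' noise, and is re-standardized.  Each category's endpoints are noisy
#' affine readouts of its latent: classification endpoints threshold the
#' readout at its median (balanced classes by construction), regression
#' endpoints keep a per-endpoint affine rescaling of it.  Labels are
#' masked independently at `missing_rate`; masked rows are absent from the
#' emitted per-endpoint tables.  The drug-likeness label is the indicator
#' of a logistic score over all four latents exceeding its median.
#'
#' @param molecules Canonical SMILES from [generate_molecules()].
#' @param cfg A [synthetic_config()].
#' @param features Optional precomputed fingerprint matrix for
#'   `molecules` under `cfg$fp` (labels are a pure function of molecules
#'   and config either way; passing it only skips refeaturization).
#' @return List: `tables` (named list of endpoint `data.frame`s with
#'   columns id, smiles, label), `specs` ([endpoint_specs()] table),
#'   `druglikeness` (`data.frame` id, smiles, label), `latents`
#'   (n x 4 matrix, columns A, D, M, E; the ground truth for oracle
#'   tests), and `features` (the fingerprint matrix used).
#' @export
generate_labels <- function(molecules, cfg, features = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- length(molecules)
  X <- features %||% featurize_fingerprint(molecules, cfg$fp)
  stopifnot(nrow(X) == n, ncol(X) == cfg$fp$n_bits)
  cats <- c("A", "D", "M", "E")
  std <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))

  set.seed(substream_seed(cfg$seed, "latents"))
  fsig <- sapply(cats, function(ct) {
    w <- stats::rnorm(ncol(X))
    s <- drop(X %*% w)
    if (stats::sd(s) == 0) s else std(s)
  })
  U <- matrix(NA_real_, n, 4, dimnames = list(NULL, cats))
  U[, "A"] <- std(fsig[, "A"] + cfg$noise_sd * stats::rnorm(n))
  for (i in 2:4) {
    mix <- sqrt(cfg$chain_strength) * U[, cats[i - 1]] +
      sqrt(1 - cfg$chain_strength) * fsig[, cats[i]]
    U[, cats[i]] <- std(mix + cfg$noise_sd * stats::rnorm(n))
  }

  m <- cfg$endpoints_per_category
  nm <- unlist(lapply(cats, function(ct) paste0(ct, seq_len(m))))
  type <- rep(rep(c("classification", "regression"), length.out = m), 4)
  specs <- endpoint_specs(nm, rep(cats, each = m), type)

  labels <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  mask <- matrix(FALSE, n, length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    ct <- specs$category[j]
    r <- U[, ct] + cfg$noise_sd * stats::rnorm(n)
    if (specs$task_type[j] == "classification") {
      labels[, j] <- as.numeric(r > stats::median(r))
    } else {
      a <- stats::runif(1, 0.5, 3); b <- stats::runif(1, -2, 2)
      labels[, j] <- a * r + b
    }
    mask[, j] <- stats::runif(n) >= cfg$missing_rate
  }

  dl_lin <- rowSums(U) / 2 + cfg$noise_sd * stats::rnorm(n)
  dl <- as.numeric(dl_lin > stats::median(dl_lin))

  ids <- sprintf("SYN%05d", seq_len(n))
  tables <- stats::setNames(lapply(seq_along(nm), function(j) {
    keep <- mask[, j]
    data.frame(id = ids[keep], smiles = molecules[keep],
               label = labels[keep, j], stringsAsFactors = FALSE)
  }), nm)
  list(tables = tables, specs = specs,
       druglikeness = data.frame(id = ids, smiles = molecules, label = dl,
                                 stringsAsFactors = FALSE),
       latents = U, features = X)
}

#' Generate and write a complete synthetic study to disk
#'
#' Emits one CSV per endpoint, the drug-likeness table, an endpoint
#' manifest consumable by [load_adme_dataset()], and the ground-truth
#' latents for oracle tests.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the `generate_labels()` result (plus `molecules`).
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mols <- generate_molecules(cfg)
  gen <- generate_labels(mols, cfg)
  for (e in names(gen$tables)) {
    tb <- gen$tables[[e]]
    tb$label <- fmt_num(tb$label)
    utils::write.csv(tb, file.path(dir, paste0(e, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(data.frame(file = paste0(gen$specs$name, ".csv"),
                              name = gen$specs$name,
                              category = gen$specs$category,
                              task_type = gen$specs$task_type),
                   file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  dl <- gen$druglikeness
  dl$label <- fmt_num(dl$label)
  utils::write.csv(dl, file.path(dir, "druglikeness.csv"),
                   row.names = FALSE, quote = FALSE)
  lat <- as.data.frame(gen$latents)
  lat <- as.data.frame(lapply(lat, fmt_num))
  lat <- cbind(data.frame(id = gen$druglikeness$id, smiles = mols), lat)
  utils::write.csv(lat, file.path(dir, "latents.csv"), row.names = FALSE,
                   quote = FALSE)
  gen$molecules <- mols
  invisible(gen)
}

#' Build an in-memory `adme_dataset` from a synthetic study
#'
#' Convenience wrapper: generate molecules and labels, aggregate the
#' endpoint tables, and return the dataset together with the generation
#' ground truth.
#'
#' @param cfg A [synthetic_config()].
#' @param molecules,features Optional pre-generated molecule library and
#'   its fingerprint matrix (e.g. when drawing several label realizations
#'   over one fixed library).
#' @return List: `dataset` (an `adme_dataset`), `features`, `druglikeness`,
#'   `latents`, `molecules`.
#' @export
synthetic_adme_dataset <- function(cfg, molecules = NULL, features = NULL) {
  mols <- molecules %||% generate_molecules(cfg)
  gen <- generate_labels(mols, cfg, features = features)
  # generator keys are canonical and unique already, so aggregation can
  # merge on the raw strings without re-canonicalizing
  dataset <- aggregate_endpoints(gen$tables, gen$specs, opaque_keys = TRUE)
  # records are keyed and sorted on canonical SMILES; realign ground truth
  idx <- match(dataset$keys, mols)
  stopifnot(!anyNA(idx))
  list(dataset = dataset, features = gen$features[idx, , drop = FALSE],
       druglikeness = gen$druglikeness[idx, , drop = FALSE],
       latents = gen$latents[idx, , drop = FALSE],
       molecules = mols[idx])
}
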