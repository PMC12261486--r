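# Multi-head MLP encoder in plain matrix code.
#
# Architecture: a shared trunk of two dense layers with ReLU activations
# mapping the binary fingerprint to the embedding z (the representation
# later reused for drug-likeness prediction), plus one linear prediction
# head per endpoint reading z.  Classification heads emit a logit that is
# squashed to a probability; regression heads emit an unbounded real on the
# normalized target scale.  Parameters live in a flat named list so that
# the optimizer and the gradient-surgery step can treat the trunk as one
# vector.

#' Create an untrained multi-head encoder
#'
#' @param specs Endpoint specification table ([endpoint_specs()]); one
#'   prediction head is created per row.
#' @param n_in Input feature width (fingerprint length).
#' @param hidden Width of the first trunk layer.
#' @param d_z Embedding dimension (second trunk layer output).
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `encoder_model`.
#' @export
new_encoder <- function(specs, n_in, hidden = 256L, d_z = 128L, seed = 1L) {
  stopifnot(n_in > 0, hidden > 0, d_z > 0, nrow(specs) >= 1)
  set.seed(as.integer(seed))
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  params <- list(W1 = he(n_in, hidden), b1 = numeric(hidden),
                 W2 = he(hidden, d_z), b2 = numeric(d_z))
  for (e in specs$name) {
    params[[paste0("head.", e, ".w")]] <- matrix(stats::rnorm(d_z, 0, sqrt(1 / d_z)), d_z, 1)
    params[[paste0("head.", e, ".b")]] <- 0
  }
  structure(list(params = params, specs = specs, n_in = as.integer(n_in),
                 hidden = as.integer(hidden), d_z = as.integer(d_z)),
            class = "encoder_model")
}

trunk_forward <- function(params, X) {
  H <- relu(sweep(X %*% params$W1, 2, params$b1, `+`))
  Z <- relu(sweep(H %*% params$W2, 2, params$b2, `+`))
  list(H = H, Z = Z)
}

head_logit <- function(params, Z, e) {
  drop(Z %*% params[[paste0("head.", e, ".w")]]) + params[[paste0("head.", e, ".b")]]
}

#' Extract embeddings from an encoder
#'
#' Reads the trunk output z before any prediction head; the embedding is
#' therefore unchanged by the presence, absence or parameters of the heads.
#'
#' @param object An `encoder_model` (or a fitted [adme_mtl()] object).
#' @param features Feature matrix with `n_in` columns.
#' @param ... Unused.
#' @return Numeric matrix, rows = molecules, `d_z` columns.
#' @export
encode <- function(object, features, ...) UseMethod("encode")

#' @export
encode.encoder_model <- function(object, features, ...) {
  if (ncol(features) != object$n_in)
    stop_named("encode: feature width %d does not match trunk input width %d",
               ncol(features), object$n_in)
  trunk_forward(object$params, features)$Z
}

#' Predict endpoint values from features
#'
#' @param model An `encoder_model`.
#' @param features Feature matrix.
#' @param endpoints Endpoint names to predict (default: all heads).
#' @return Named list of numeric vectors; probabilities in (0,1) for
#'   classification endpoints, reals on the normalized scale for regression
#'   endpoints.
#' @export
predict_endpoints <- function(model, features, endpoints = model$specs$name) {
  stopifnot(inherits(model, "encoder_model"))
  unknown <- setdiff(endpoints, model$specs$name)
  if (length(unknown))
    stop_named("predict_endpoints: unknown endpoint(s): %s",
               paste(unknown, collapse = ", "))
  if (length(endpoints) == 0L) return(stats::setNames(list(), character(0)))
  Z <- encode(model, features)
  out <- lapply(endpoints, function(e) {
    s <- head_logit(model$params, Z, e)
    if (model$specs$task_type[model$specs$name == e] == "classification")
      sigmoid(s) else s
  })
  stats::setNames(out, endpoints)
}

#' Per-endpoint masked losses
#'
#' Each endpoint's loss is the mean over its observed entries only: binary
#' cross-entropy for classification (predictions are probabilities),
#' squared error on the normalized scale for regression.  Endpoints with no
#' observed entry in the batch contribute nothing; the total is the
#' unweighted mean over contributing endpoints.  Masked-out label values
#' are never read, so any placeholder stored under a `FALSE` mask bit
#' cannot influence a loss.
#'
#' @param predictions Named list endpoint -> numeric predictions (one per
#'   row of the batch).
#' @param labels Numeric matrix of labels (columns named by endpoint).
#' @param mask Logical matrix, `TRUE` = observed.
#' @param specs Endpoint specification table.
#' @return List with `per_endpoint` (named numeric, `NA` when nothing
#'   observed), `n_obs`, `total` (NA when no endpoint contributes) and
#'   `skip` (TRUE when the whole batch carries no observation).
#' @export
masked_losses <- function(predictions, labels, mask, specs) {
  eps <- names(predictions)
  stopifnot(all(eps %in% specs$name))
  per <- stats::setNames(rep(NA_real_, length(eps)), eps)
  nob <- stats::setNames(integer(length(eps)), eps)
  for (e in eps) {
    obs <- mask[, e]
    nob[e] <- sum(obs)
    if (!any(obs)) next
    y <- labels[obs, e]
    p <- predictions[[e]][obs]
    if (specs$task_type[specs$name == e] == "classification") {
      per[e] <- mean(ifelse(y == 1, -log(p), -log(1 - p)))
    } else {
      per[e] <- mean((p - y)^2)
    }
  }
  contributing <- !is.na(per)
  list(per_endpoint = per, n_obs = nob,
       total = if (any(contributing)) mean(per[contributing]) else NA_real_,
       skip = !any(contributing))
}

# ---- gradients -----------------------------------------------------------

trunk_param_names <- c("W1", "b1", "W2", "b2")

flatten_trunk <- function(grads) {
  c(as.numeric(grads$W1), as.numeric(grads$b1),
    as.numeric(grads$W2), as.numeric(grads$b2))
}

unflatten_trunk <- function(vec, params) {
  out <- list()
  pos <- 0L
  for (nm in trunk_param_names) {
    len <- length(params[[nm]])
    g <- vec[pos + seq_len(len)]
    dim(g) <- dim(params[[nm]])
    out[[nm]] <- g
    pos <- pos + len
  }
  out
}

# Forward pass plus per-endpoint gradients for one batch.  Loss gradients
# are normalized by each endpoint's observed count (mean loss), and the
# loss values logged here use the numerically stable logit form of the
# cross-entropy.  Returns NULL components for endpoints with no
# observation in the batch.
endpoint_batch_grads <- function(params, X, labels, mask, specs, endpoints) {
  fw <- trunk_forward(params, X)
  H <- fw$H; Z <- fw$Z
  res <- list()
  for (e in endpoints) {
    obs <- mask[, e]
    m <- sum(obs)
    if (m == 0L) next
    w <- params[[paste0("head.", e, ".w")]]
    s <- drop(Z %*% w) + params[[paste0("head.", e, ".b")]]
    y <- labels[, e]
    ds <- numeric(nrow(X))
    if (specs$task_type[specs$name == e] == "classification") {
      p <- sigmoid(s)
      loss <- mean(log1pexp(s[obs]) - y[obs] * s[obs])
      ds[obs] <- (p[obs] - y[obs]) / m
    } else {
      loss <- mean((s[obs] - y[obs])^2)
      ds[obs] <- 2 * (s[obs] - y[obs]) / m
    }
    dZ <- (ds %*% t(w)) * (Z > 0)
    dW2 <- crossprod(H, dZ)
    db2 <- colSums(dZ)
    dH <- (dZ %*% t(params$W2)) * (H > 0)
    dW1 <- crossprod(X, dH)
    db1 <- colSums(dH)
    res[[e]] <- list(
      trunk = flatten_trunk(list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)),
      head_w = crossprod(Z, matrix(ds)), head_b = sum(ds),
      loss = loss, n_obs = m)
  }
  res
}

# Summed-gradient fast path: when no gradient surgery is requested the
# trunk update is the gradient of the summed per-endpoint losses, which
# equals the sum of per-endpoint trunk gradients by linearity and needs
# only one backward pass.  Per-endpoint losses and head gradients are
# still computed individually.
batch_grads_summed <- function(params, X, labels, mask, specs, endpoints) {
  fw <- trunk_forward(params, X)
  H <- fw$H; Z <- fw$Z
  dZ_acc <- NULL
  heads <- list()
  losses <- list()
  for (e in endpoints) {
    obs <- mask[, e]
    m <- sum(obs)
    if (m == 0L) next
    w <- params[[paste0("head.", e, ".w")]]
    s <- drop(Z %*% w) + params[[paste0("head.", e, ".b")]]
    y <- labels[, e]
    ds <- numeric(nrow(X))
    if (specs$task_type[specs$name == e] == "classification") {
      loss <- mean(log1pexp(s[obs]) - y[obs] * s[obs])
      ds[obs] <- (sigmoid(s[obs]) - y[obs]) / m
    } else {
      loss <- mean((s[obs] - y[obs])^2)
      ds[obs] <- 2 * (s[obs] - y[obs]) / m
    }
    dZe <- ds %*% t(w)
    dZ_acc <- if (is.null(dZ_acc)) dZe else dZ_acc + dZe
    heads[[e]] <- list(w = crossprod(Z, matrix(ds)), b = sum(ds))
    losses[[e]] <- list(loss = loss, n_obs = m)
  }
  if (is.null(dZ_acc)) return(NULL)
  dZ <- dZ_acc * (Z > 0)
  dH <- (dZ %*% t(params$W2)) * (H > 0)
  list(trunk = list(W1 = crossprod(X, dH), b1 = colSums(dH),
                    W2 = crossprod(H, dZ), b2 = colSums(dZ)),
       heads = heads, losses = losses)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  state <- list(t = 0)
  for (nm in names(params)) {
    state[[paste0("m.", nm)]] <- params[[nm]] * 0
    state[[paste0("v.", nm)]] <- params[[nm]] * 0
  }
  state
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state[[paste0("m.", nm)]] <- beta1 * state[[paste0("m.", nm)]] + (1 - beta1) * g
    v <- state[[paste0("v.", nm)]] <- beta2 * state[[paste0("v.", nm)]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(state = state, params = params)
}
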