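#' Gradient surgery for conflicting task gradients (PCGrad)
#'
#' Resolves destructive interference between tasks that share parameters.
#' For each task gradient `g_i`, the other tasks' raw gradients are visited
#' in a random order; whenever `g_i . g_j < 0` (a conflict), `g_i` is
#' replaced by its projection onto the normal plane of `g_j`:
#' `g_i <- g_i - (g_i . g_j / ||g_j||^2) g_j`.  The projection always uses
#' the partner's raw (unprojected) gradient.  The combined update is the
#' sum of the projected gradients; when no pair conflicts this is exactly
#' the sum of the inputs.
#'
#' A zero-norm partner in a conflicting pair cannot define a projection
#' plane; that projection is skipped with a one-time warning.
#'
#' @param grads List of numeric vectors (one gradient per task over the
#'   shared parameters), all the same length.
#' @param seed Optional integer seed for the visiting order; when `NULL`
#'   the current RNG stream is used (the trainer passes its own seeded
#'   stream through).
#' @param combine When `FALSE`, return the list of projected per-task
#'   gradients instead of their sum (useful for inspecting the surgery).
#' @return Numeric vector: the combined gradient (or a list of projected
#'   gradients when `combine = FALSE`).
#' @examples
#' pcgrad_project(list(c(1, 0), c(-1, 1)), seed = 1)
#' @export
pcgrad_project <- function(grads, seed = NULL, combine = TRUE) {
  stopifnot(is.list(grads), length(grads) >= 1)
  len <- unique(vapply(grads, length, integer(1)))
  if (length(len) != 1L)
    stop_named("pcgrad_project: gradients must all have the same length")
  k <- length(grads)
  if (k == 1L) return(if (combine) grads[[1]] else grads)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sq_norms <- vapply(grads, function(g) sum(g * g), numeric(1))
  warned <- FALSE
  proj <- vector("list", k)
  for (i in seq_len(k)) {
    gi <- grads[[i]]
    others <- setdiff(seq_len(k), i)
    for (j in others[sample.int(k - 1L)]) {
      d <- sum(gi * grads[[j]])
      if (d < 0) {
        if (sq_norms[j] == 0) {
          if (!warned) {
            warning("pcgrad_project: zero-norm conflicting gradient; projection skipped")
            warned <- TRUE
          }
          next
        }
        gi <- gi - (d / sq_norms[j]) * grads[[j]]
      }
    }
    proj[[i]] <- gi
  }
  if (!combine) return(proj)
  Reduce(`+`, proj)
}
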