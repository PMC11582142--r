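#' Chain state of the iterative-imputation sampler
#'
#' Internal container updated by the imputation sweep and the pipeline: the
#' current fully imputed response matrix, the per-item auxiliary logistic
#' coefficients, and the retained draws of the half-vectorized parameter
#' matrix.  Observed cells of `y` are never modified by any operation; after
#' any number of sweeps they are bit-identical to the input data.
#'
#' @param y fully imputed integer 0/1 matrix.
#' @param betas `J x J` matrix; row `j` holds `beta_j`.
#' @param alpha current vech coordinate vector or `NULL`.
#' @param alpha_draws matrix of retained draws (rows = draws).
#' @param iteration sweep counter.
#' @return an object of class `chain_state`.
#' @keywords internal
chain_state <- function(y, betas, alpha = NULL, alpha_draws = NULL,
                        iteration = 0L) {
  structure(
    list(y = y, betas = betas, alpha = alpha,
         alpha_draws = alpha_draws, iteration = as.integer(iteration)),
    class = "chain_state"
  )
}

#' @export
print.chain_state <- function(x, ...) {
  nd <- if (is.null(x$alpha_draws)) 0L else nrow(x$alpha_draws)
  cat("chain_state: ", nrow(x$y), " x ", ncol(x$y), " imputed matrix, ",
      "iteration ", x$iteration, ", ", nd, " retained draws\n", sep = "")
  invisible(x)
}

#' Initialize the missing cells of a response matrix
#'
#' Fills each missing cell of item `j` with an independent Bernoulli draw at
#' the observed success rate of that item, clipped to `[0.05, 0.95]` to avoid
#' degenerate all-0/all-1 starting columns.  Observed cells are copied
#' unchanged.  Every item must have at least one observed value.
#'
#' @param data a [response_data] object.
#' @param seed optional integer seed.
#' @return a `chain_state` with zero-initialized auxiliary coefficients.
#' @export
initialize_missing <- function(data, seed = NULL) {
  stopifnot(inherits(data, "response_data"))
  maybe_set_seed(seed)
  y <- data$y
  J <- data$J
  n_obs <- colSums(data$mask)
  if (any(n_obs == 0L))
    stop("item(s) ", paste(which(n_obs == 0L), collapse = ", "),
         " have no observed values")
  for (j in seq_len(J)) {
    idx <- which(data$mask[, j] == 0L)
    if (length(idx) == 0L) next
    phat <- mean(y[data$mask[, j] == 1L, j])
    phat <- min(max(phat, 0.05), 0.95)
    y[idx, j] <- as.integer(runif(length(idx)) < phat)
  }
  storage.mode(y) <- "integer"
  chain_state(y = y, betas = matrix(0, J, J))
}

#' Redraw the missing cells of one item
#'
#' For the rows where item `j` is missing -- and only those -- redraws
#' `y_ij` from a Bernoulli with success probability
#' `plogis(beta_jj/2 + sum_{k != j} beta_jk * y_ik)`, using the most recent
#' values of the other items held in the chain state.  Intended to be called
#' right after `beta_j` has been refreshed by [sample_beta_j()].
#'
#' @param state a `chain_state`.
#' @param j item index.
#' @param data the [response_data] whose mask defines which cells are missing.
#' @param seed optional integer seed.
#' @return the updated `chain_state`.
#' @export
impute_item <- function(state, j, data, seed = NULL) {
  stopifnot(inherits(state, "chain_state"), inherits(data, "response_data"))
  J <- ncol(state$y)
  if (length(j) != 1L || j < 1L || j > J) stop("item index j out of range")
  idx <- which(data$mask[, j] == 0L)
  if (length(idx) == 0L) return(state)
  maybe_set_seed(seed)
  b <- state$betas[j, ]
  eta <- b[j] / 2 + as.vector(state$y[idx, -j, drop = FALSE] %*% b[-j])
  state$y[idx, j] <- as.integer(runif(length(idx)) < plogis(eta))
  state
}

#' One full-conditional-specification sweep
#'
#' Loops over the items in `order` (default `1:J`); for each item `j` it
#' refreshes `beta_j` from its posterior given the current fully imputed
#' matrix, then redraws the missing cells of item `j`, so the updated column
#' feeds the next item's step (sequential chained-equations updating).  With
#' no missing data the coefficients are still refreshed but the matrix is
#' untouched, reducing the sweep to complete-data Bayesian logistic fits.
#'
#' @param state a `chain_state` (from [initialize_missing()] or a previous
#'   sweep).
#' @param data the [response_data] being imputed.
#' @param priors an [default_priors()] object.
#' @param seed optional integer seed.
#' @param order item visit order, a permutation of `1:J`.
#' @return the updated `chain_state` (iteration counter incremented).
#' @export
fcs_sweep <- function(state, data, priors = default_priors(), seed = NULL,
                      order = NULL) {
  stopifnot(inherits(state, "chain_state"), inherits(data, "response_data"))
  J <- ncol(state$y)
  order <- as.integer(order %||% seq_len(J))
  if (!identical(sort(order), seq_len(J)))
    stop("order must be a permutation of 1:J")
  maybe_set_seed(seed)
  # duplicate before the in-place kernel so the caller's state is untouched
  y <- state$y + 0L
  betas <- state$betas + 0
  cpp_fcs_sweep_inplace(y, data$mask, betas, order - 1L,
                        priors$beta_intercept_var, priors$beta_slope_var)
  state$y <- y
  state$betas <- betas
  state$iteration <- state$iteration + 1L
  state
}
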