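#' Run one chain of the iterative-imputation pseudo-posterior sampler
#'
#' @description
#' The full procedure: initialize the missing cells, then run `iters`
#' full-conditional-specification sweeps.  After the burn-in (`burnin`
#' sweeps), every `thin`-th sweep is a *thinning event*: the half-vectorized
#' parameter matrix is updated once by the joint Polya-Gamma kernel
#' ([sample_alpha()]) on the current imputed matrix and the draw is retained,
#' giving `floor((iters - burnin) / thin)` retained draws.  The parameter
#' matrix is deliberately not sampled during burn-in or between thinning
#' events -- its update costs an order of `J^2` more than a sweep -- and the
#' auxiliary coefficients are refreshed every sweep throughout.
#'
#' With *fully observed* data the procedure reduces to standard
#' pseudo-posterior MCMC: there is nothing to impute, so the parameter
#' kernel is applied at every iteration, the first `burnin` of its draws are
#' discarded as the chain's own burn-in, and every `thin`-th draw thereafter
#' is retained (the retained count is unchanged).  This is the complete-data
#' special case used by the listwise and single-imputation baselines.
#'
#' The vech coordinates are initialized `Uniform(-0.1, 0.1)`; auxiliary
#' coefficients start at zero.
#'
#' @details
#' Randomness is split into two sub-streams derived from `seed`: one drives
#' the imputation machinery (initialization, auxiliary coefficients, imputed
#' cells), the other the parameter-matrix draws.  Consequently, with fully
#' observed data the retained draws are bit-identical to those of a sampler
#' that skips the imputation machinery altogether and only applies the
#' parameter kernel to the fixed data.
#'
#' @param data a [response_data] object.
#' @param iters total number of sweeps `T`.
#' @param burnin burn-in size `T0 < T` (`0 <= T0 <= T`; a schedule that
#'   retains no draw only warns, so schedules can be validated cheaply).
#' @param thin thinning gap `k0 >= 1` between parameter draws.
#' @param priors an [default_priors()] object.
#' @param seed optional integer seed.
#' @param sample_s if `FALSE`, skip the parameter-matrix updates entirely and
#'   only run the imputation chain (used by the single-imputation baseline).
#' @param item_order item visit order for the sweeps.
#' @param trace_file optional path; if given, a CSV diagnostic log with one
#'   row per sweep (iteration and per-item means of the imputed cells) is
#'   written.
#' @param force_sweeps run the imputation sweeps even when the data are
#'   fully observed.  With complete data every sweep is vacuous (there is
#'   nothing to impute, and the auxiliary coefficients do not enter the
#'   parameter kernel), so by default they are skipped; because the two RNG
#'   sub-streams are independent, the retained parameter draws are
#'   bit-identical either way.  Only useful for validating that property.
#' @return a `chain_state`; `$alpha_draws` holds the retained draws (one row
#'   per draw, vech coordinate columns `s_11, s_21, ...`).
#' @examples
#' S <- make_study2_truth()
#' d <- apply_missingness(sample_exact(S, 500, seed = 1),
#'                        missingness_spec("screening"), seed = 2)
#' st <- run_chain(d, iters = 60, burnin = 20, thin = 10, seed = 3)
#' posterior_mean(st)
#' @export
run_chain <- function(data, iters = 5000, burnin = 1000, thin = 10,
                      priors = default_priors(), seed = NULL,
                      sample_s = TRUE, item_order = NULL, trace_file = NULL,
                      force_sweeps = FALSE) {
  stopifnot(inherits(data, "response_data"))
  iters <- as.integer(iters); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (burnin < 0 || iters < burnin || thin < 1L)
    stop("invalid schedule: need iters >= burnin >= 0 and thin >= 1")
  n_retain <- (iters - burnin) %/% thin
  if (sample_s && n_retain == 0L)
    warning("schedule retains no parameter draws")
  J <- data$J
  M <- J * (J + 1L) / 2L
  order0 <- as.integer(item_order %||% seq_len(J))

  maybe_set_seed(seed)
  alpha <- runif(M, -0.1, 0.1)
  ss <- derive_seeds(2)

  # two RNG sub-streams: imputation/auxiliary vs parameter matrix
  set.seed(ss[1]); imp_state <- rng_state()
  set.seed(ss[2]); alpha_state <- rng_state()

  set_rng_state(imp_state)
  state <- initialize_missing(data)
  y <- state$y + 0L   # private copy: the sweep kernel mutates it in place
  betas <- state$betas
  draws <- matrix(NA_real_, n_retain, M)
  colnames(draws) <- vech_names(J)
  trace <- if (!is.null(trace_file)) vector("list", iters)

  has_missing <- any(data$mask == 0L)
  sweep_needed <- force_sweeps || has_missing
  # with complete data the chain is standard pseudo-posterior MCMC: the
  # parameter kernel runs every iteration and burn-in applies to its draws
  alpha_every_iter <- !has_missing
  r <- 0L
  for (t in seq_len(iters)) {
    if (sweep_needed) {
      cpp_fcs_sweep_inplace(y, data$mask, betas, order0 - 1L,
                            priors$beta_intercept_var, priors$beta_slope_var)
    }
    if (!is.null(trace_file)) {
      imp_mean <- vapply(seq_len(J), function(j) {
        idx <- data$mask[, j] == 0L
        if (any(idx)) mean(y[idx, j]) else NA_real_
      }, numeric(1))
      trace[[t]] <- c(iteration = t, imp_mean)
    }
    if (sample_s && (alpha_every_iter ||
                     (t > burnin && (t - burnin) %% thin == 0L))) {
      imp_state <- rng_state()
      set_rng_state(alpha_state)
      alpha <- as.vector(cpp_sample_alpha(y, alpha, rep(0, M),
                                          alpha_prior_var(J, priors)))
      alpha_state <- rng_state()
      set_rng_state(imp_state)
      if (t > burnin && (t - burnin) %% thin == 0L) {
        r <- r + 1L
        draws[r, ] <- alpha
      }
    }
  }
  if (!is.null(trace_file)) {
    tr <- as.data.frame(do.call(rbind, trace))
    names(tr) <- c("iteration", paste0("imputed_mean_", data$items))
    write.csv(tr, trace_file, row.names = FALSE)
  }
  storage.mode(y) <- "integer"
  dimnames(y) <- dimnames(data$y)
  out <- chain_state(y = y, betas = betas, alpha = alpha,
                     alpha_draws = draws[seq_len(r), , drop = FALSE],
                     iteration = iters)
  out$schedule <- list(iters = iters, burnin = burnin, thin = thin)
  out$items <- data$items
  out
}

#' Posterior-mean estimate of the Ising parameter matrix
#'
#' Elementwise mean of the retained parameter draws of a chain, returned as
#' a symmetric matrix.
#'
#' @param state a `chain_state` with at least one retained draw.
#' @return symmetric `J x J` matrix.
#' @export
posterior_mean <- function(state) {
  stopifnot(inherits(state, "chain_state"))
  if (is.null(state$alpha_draws) || nrow(state$alpha_draws) == 0L)
    stop("chain has no retained parameter draws")
  S <- unvech(colMeans(state$alpha_draws))
  if (!is.null(state$items)) dimnames(S) <- list(state$items, state$items)
  S
}

#' Gelman-Rubin convergence statistic
#'
#' The between/within variance-ratio diagnostic
#' \eqn{\hat R = \sqrt{(\frac{n-1}{n} W + \frac{B}{n}) / W}} computed per
#' scalar parameter from two or more chains of equal length.  Values near 1
#' indicate that the chains have mixed.  Degenerate cases: chains that are
#' constant and identical give 1; chains that are constant but different
#' (zero within-chain variance) give `Inf` with a warning.
#'
#' @param chains list (length >= 2) of equal-length numeric vectors or of
#'   draw matrices with one column per parameter.
#' @return named numeric vector of \eqn{\hat R} values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains")
  chains <- lapply(chains, function(ch) {
    ch <- if (is.matrix(ch)) ch else matrix(ch, ncol = 1)
    storage.mode(ch) <- "double"
    ch
  })
  n <- nrow(chains[[1]])
  p <- ncol(chains[[1]])
  ok <- vapply(chains, function(ch) nrow(ch) == n && ncol(ch) == p, logical(1))
  if (!all(ok)) stop("all chains must have identical dimensions")
  if (n < 2L) stop("chains must contain at least 2 draws")
  rhat <- numeric(p)
  for (k in seq_len(p)) {
    draws <- vapply(chains, function(ch) ch[, k], numeric(n))
    W <- mean(apply(draws, 2, var))
    B_over_n <- var(colMeans(draws))  # = B/n
    if (W == 0) {
      if (B_over_n == 0) { rhat[k] <- 1; next }
      warning("zero within-chain variance for parameter ", k,
              "; R-hat is infinite")
      rhat[k] <- Inf
      next
    }
    rhat[k] <- sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  names(rhat) <- colnames(chains[[1]]) %||% paste0("par", seq_len(p))
  rhat
}

#' Baseline: listwise-deletion (complete-case) estimate
#'
#' Drops every row containing a missing cell and runs the pseudo-posterior
#' sampler on the remaining complete cases with the same schedule and
#' averaging as the proposed method -- the complete-data special case of the
#' procedure, with the imputation steps vacuous.  Requires at least one
#' complete row.  Valid under MCAR, but biased under missingness that
#' depends on observed values; with screening-item missingness it suffers
#' from Berkson's paradox (a spuriously negative edge between the screening
#' items).
#'
#' @inheritParams run_chain
#' @return symmetric `J x J` posterior-mean estimate.
#' @export
listwise_estimate <- function(data, iters = 5000, burnin = 1000, thin = 10,
                              priors = default_priors(), seed = NULL) {
  stopifnot(inherits(data, "response_data"))
  keep <- complete_rows(data)
  if (!any(keep)) stop("no complete rows for listwise deletion")
  sub <- response_data(data$y[keep, , drop = FALSE],
                       data$mask[keep, , drop = FALSE])
  posterior_mean(run_chain(sub, iters = iters, burnin = burnin, thin = thin,
                           priors = priors, seed = seed))
}

#' Baseline: single-imputation estimate
#'
#' Runs the full iterative-imputation chain, freezes the imputed matrix at
#' the final sweep, and then runs a fresh complete-data chain (same schedule)
#' on that single completed dataset.  Unlike the proposed method, parameter
#' uncertainty from the imputation is not propagated, which inflates the
#' estimation error.
#'
#' @inheritParams run_chain
#' @return symmetric `J x J` posterior-mean estimate.
#' @export
single_imputation_estimate <- function(data, iters = 5000, burnin = 1000,
                                       thin = 10, priors = default_priors(),
                                       seed = NULL) {
  stopifnot(inherits(data, "response_data"))
  maybe_set_seed(seed)
  imp_seed <- derive_seeds(1)
  imp <- run_chain(data, iters = iters, burnin = burnin, thin = thin,
                   priors = priors, seed = imp_seed, sample_s = FALSE)
  completed <- response_data(imp$y)
  posterior_mean(run_chain(completed, iters = iters, burnin = burnin,
                           thin = thin, priors = priors, seed = seed))
}

#' Proposed estimate: iterative imputation with pooled parameter draws
#'
#' Convenience wrapper: [run_chain()] followed by [posterior_mean()].
#'
#' @inheritParams run_chain
#' @return symmetric `J x J` posterior-mean estimate.
#' @export
proposed_estimate <- function(data, iters = 5000, burnin = 1000, thin = 10,
                              priors = default_priors(), seed = NULL) {
  posterior_mean(run_chain(data, iters = iters, burnin = burnin, thin = thin,
                           priors = priors, seed = seed))
}

#' Fit an Ising network to data with missing values
#'
#' Top-level multi-chain interface.  Runs `chains` independent chains of the
#' chosen estimator with per-chain seeds derived from `seed`, pools the
#' retained draws of all chains for the reported estimate, and computes the
#' Gelman-Rubin statistic per parameter when two or more chains are run.
#'
#' @param data a [response_data] object.
#' @param method `"proposed"` (iterative imputation), `"single"` (single
#'   imputation), or `"listwise"` (complete-case analysis).
#' @param chains number of independent chains (default 10, a diagnostic
#'   setting; simulations typically use 1).
#' @inheritParams run_chain
#' @return an object of class `ising_fit`: list with `estimate` (posterior
#'   mean over all pooled draws), `draws` (list of per-chain draw matrices),
#'   `rhat`, `method`, `items`, `schedule`.
#' @export
fit_ising <- function(data, method = c("proposed", "single", "listwise"),
                      chains = 10, iters = 5000, burnin = 1000, thin = 10,
                      priors = default_priors(), seed = NULL) {
  stopifnot(inherits(data, "response_data"))
  method <- match.arg(method)
  maybe_set_seed(seed)
  chain_seeds <- derive_seeds(chains)
  states <- lapply(chain_seeds, function(s)
    method_chain(data, method, iters, burnin, thin, priors, s))
  draws <- lapply(states, `[[`, "alpha_draws")
  pooled <- do.call(rbind, draws)
  if (nrow(pooled) == 0L) stop("no retained draws; extend the schedule")
  estimate <- unvech(colMeans(pooled))
  dimnames(estimate) <- list(data$items, data$items)
  rhat <- if (chains >= 2L) gelman_rubin(draws) else NULL
  structure(
    list(estimate = estimate, draws = draws, rhat = rhat, method = method,
         items = data$items,
         schedule = list(iters = iters, burnin = burnin, thin = thin,
                         chains = chains)),
    class = "ising_fit"
  )
}

# one chain of a given estimator, returning its chain_state
method_chain <- function(data, method, iters, burnin, thin, priors, seed) {
  switch(method,
    proposed = run_chain(data, iters, burnin, thin, priors, seed),
    listwise = {
      keep <- complete_rows(data)
      if (!any(keep)) stop("no complete rows for listwise deletion")
      sub <- response_data(data$y[keep, , drop = FALSE],
                           data$mask[keep, , drop = FALSE])
      run_chain(sub, iters, burnin, thin, priors, seed)
    },
    single = {
      maybe_set_seed(seed)
      imp_seed <- derive_seeds(1)
      imp <- run_chain(data, iters, burnin, thin, priors, seed = imp_seed,
                       sample_s = FALSE)
      run_chain(response_data(imp$y), iters, burnin, thin, priors,
                seed = seed)
    }
  )
}

#' @export
print.ising_fit <- function(x, ...) {
  cat("ising_fit (", x$method, "): ", length(x$items), " items, ",
      x$schedule$chains, " chain(s) x ",
      nrow(x$draws[[1]]), " retained draws\n", sep = "")
  if (!is.null(x$rhat))
    cat("max Gelman-Rubin R-hat:", format(max(x$rhat), digits = 4), "\n")
  el <- edge_list(x$estimate, threshold = 0.5)
  cat("edges with |estimate| > 0.5:", nrow(el), "\n")
  if (nrow(el) > 0) print(utils::head(el, 10))
  invisible(x)
}

#' List edges above a visualization threshold
#'
#' Off-diagonal pairs whose estimated parameter exceeds `threshold` in
#' absolute value, with sign and magnitude.  Thresholding is a display
#' device, not an edge-selection procedure: entries below the threshold are
#' not inferred to be zero.
#'
#' @param S_hat estimated (symmetric) Ising parameter matrix.
#' @param threshold non-negative cutoff; pairs with `|s_jk| > threshold` are
#'   listed (default 0.5).
#' @return data frame with columns `item1`, `item2`, `weight`, ordered by
#'   decreasing `|weight|`.
#' @export
edge_list <- function(S_hat, threshold = 0.5) {
  S_hat <- validate_ising_matrix(S_hat)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("threshold must be a single non-negative number")
  J <- ncol(S_hat)
  items <- colnames(S_hat) %||% paste0("Y", seq_len(J))
  pairs <- which(upper.tri(S_hat), arr.ind = TRUE)
  w <- S_hat[pairs]
  sel <- abs(w) > threshold
  out <- data.frame(item1 = items[pairs[sel, 1]],
                    item2 = items[pairs[sel, 2]],
                    weight = w[sel])
  out[order(-abs(out$weight)), , drop = FALSE]
}
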