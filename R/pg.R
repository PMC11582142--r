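#' Polya-Gamma random variates
#'
#' Draws from the Polya-Gamma distribution PG(b, c), the augmentation
#' distribution that renders logistic likelihoods conditionally Gaussian.
#' The default method is the exact alternating-series rejection sampler for
#' integer `b` (built from PG(1, c) draws); `method = "gamma"` uses the
#' infinite sum-of-gammas representation truncated at `trunc` terms with the
#' discarded tail replaced by its exact expectation, and also covers
#' non-integer `b`.  The closed-form mean is
#' \eqn{E[PG(b, c)] = (b / 2c)\tanh(c/2)} (\eqn{b/4} at `c = 0`).
#'
#' @param n number of draws.
#' @param b shape parameter, strictly positive.
#' @param c tilting parameter; scalar or vector of length `n`.
#' @param method `"devroye"` (exact, integer `b`) or `"gamma"`.
#' @param trunc number of gamma terms kept by the fallback method.
#' @param seed optional integer seed.
#' @return numeric vector of `n` strictly positive draws.
#' @examples
#' mean(draw_pg(1e4, 1, 0, seed = 1))  # ~ 1/4
#' @export
draw_pg <- function(n = 1, b = 1, c = 0, method = c("devroye", "gamma"),
                    trunc = 200, seed = NULL) {
  method <- match.arg(method)
  if (length(b) != 1L || !is.finite(b) || b <= 0)
    stop("b must be a single positive number")
  if (method == "devroye" && abs(b - round(b)) > 1e-12)
    stop("the exact sampler requires integer b; use method = \"gamma\"")
  if (!(length(c) %in% c(1L, n)))
    stop("c must have length 1 or n")
  maybe_set_seed(seed)
  cpp_rpg(as.integer(n), b, as.numeric(c), method, as.integer(trunc))
}

#' One Polya-Gamma sweep of a Bayesian logistic regression
#'
#' Performs a single transition of the Polya-Gamma Gibbs kernel targeting the
#' posterior of a logistic regression with independent normal priors: first
#' augmentation variables \eqn{\omega_i \sim PG(1, x_i^\top \beta)} are drawn
#' independently for each row, then the coefficient vector is drawn from its
#' Gaussian full conditional with precision \eqn{X^\top \Omega X + V_0^{-1}}
#' and mean solving that precision times mean \eqn{= X^\top(u - 1/2) +
#' V_0^{-1} m_0}.  With zero rows the draw is from the prior.
#'
#' @param X design matrix (`n x p`).
#' @param u binary response vector of length `n`.
#' @param prior list with `mean` and `var` (each scalar or length `p`);
#'   `var` is the diagonal of the prior covariance.
#' @param current current coefficient vector (defaults to zeros).
#' @param seed optional integer seed.
#' @return coefficient vector of length `p` (one posterior draw).
#' @export
pg_logistic_update <- function(X, u, prior = list(mean = 0, var = 100),
                               current = NULL, seed = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  u <- as.numeric(u)
  if (length(u) != nrow(X)) stop("length(u) must equal nrow(X)")
  if (!all(u %in% c(0, 1))) stop("responses u must be coded 0/1")
  m0 <- rep_len(as.numeric(prior$mean %||% 0), p)
  v0 <- rep_len(as.numeric(prior$var %||% 100), p)
  if (any(!is.finite(v0)) || any(v0 <= 0))
    stop("prior variances must be positive and finite")
  current <- as.numeric(current %||% rep(0, p))
  if (length(current) != p) stop("current coefficient vector has wrong length")
  maybe_set_seed(seed)
  as.vector(cpp_pg_logistic_update(X, u, m0, v0, current))
}

#' Refresh the auxiliary logistic coefficients of one item
#'
#' Draws one update of \eqn{\beta_j}, the unconstrained coefficient vector of
#' the logistic regression of item `j` on all other items, from its posterior
#' given the current fully imputed data.  The design row for respondent `i`
#' has the constant 1/2 in position `j` -- so that \eqn{\beta_{jj}} matches
#' the diagonal convention of the Ising parameter matrix -- and `y_ik` in
#' every other position; the response is `y_ij`.
#'
#' @param j item index.
#' @param y fully observed 0/1 matrix (or a complete [response_data]).
#' @param priors an [default_priors()] object.
#' @param current current `beta_j` (defaults to zeros).
#' @param seed optional integer seed.
#' @return named coefficient vector of length `J`.
#' @export
sample_beta_j <- function(j, y, priors = default_priors(), current = NULL,
                          seed = NULL) {
  y <- complete_matrix(y)
  J <- ncol(y)
  if (length(j) != 1L || j < 1L || j > J) stop("item index j out of range")
  X <- matrix(as.double(y), nrow(y), J)
  X[, j] <- 0.5
  maybe_set_seed(seed)
  beta <- pg_logistic_update(
    X, y[, j],
    prior = list(mean = 0, var = beta_prior_var(J, j, priors)),
    current = current %||% rep(0, J)
  )
  names(beta) <- paste0("beta_", j, if (J > 9) "_" else "", seq_len(J))
  beta
}

#' Stacked pseudo-observation design for the joint vech(S) update
#'
#' Expands the pseudo-likelihood of a fully observed data matrix into `N * J`
#' logistic pseudo-observations over the half-vectorized parameter
#' coordinates: pseudo-observation `(i, j)` has response `y_ij` and linear
#' predictor \eqn{s_{jj}/2 + \sum_{k \ne j} s_{jk} y_{ik}}, i.e. coefficient
#' 1/2 on the diagonal coordinate `(j, j)` and `y_ik` on each pair coordinate
#' `{j, k}`.  Each pair coordinate thus receives `y_ik` from row `(i, j)` and
#' `y_ij` from row `(i, k)`.  Rows are ordered observation-major with the
#' item index varying fastest, matching the augmentation order used by
#' [sample_alpha()].
#'
#' Mainly a reference implementation: [sample_alpha()] streams the same
#' quantities without materializing this matrix.
#'
#' @param y fully observed 0/1 matrix (or a complete [response_data]).
#' @return list with `X` (`N*J x J(J+1)/2` design) and `u` (responses).
#' @export
build_alpha_design <- function(y) {
  y <- complete_matrix(y)
  N <- nrow(y); J <- ncol(y)
  M <- J * (J + 1L) / 2L
  X <- matrix(0, N * J, M)
  u <- numeric(N * J)
  for (i in seq_len(N)) {
    for (j in seq_len(J)) {
      r <- (i - 1L) * J + j
      X[r, vech_idx(j, j, J)] <- 0.5
      for (k in seq_len(J)[-j]) {
        if (y[i, k] == 1L) X[r, vech_idx(j, k, J)] <- 1
      }
      u[r] <- y[i, j]
    }
  }
  colnames(X) <- vech_names(J)
  list(X = X, u = u)
}

#' Joint pseudo-posterior update of the Ising parameter matrix
#'
#' One Polya-Gamma sweep targeting the pseudo-posterior of
#' \eqn{\alpha = vech(S)}: prior times the conditional (pseudo-) likelihood,
#' in which the `N * J` per-item conditional terms are deliberately treated
#' as independent contributions.  All `J(J+1)/2` coordinates are updated
#' jointly (not coordinate-wise), drawing `N * J` augmentation variables and
#' one multivariate normal.  The cross-product matrix is accumulated by
#' streaming over pseudo-observations, so the dense `N*J x J(J+1)/2` design
#' is never stored.
#'
#' @param y fully observed 0/1 matrix (or a complete [response_data]).
#' @param priors an [default_priors()] object.
#' @param current current vech coordinate vector (defaults to zeros).
#' @param seed optional integer seed.
#' @return named vech coordinate vector (one draw); `unvech()` of it is
#'   symmetric by construction.
#' @export
sample_alpha <- function(y, priors = default_priors(), current = NULL,
                         seed = NULL) {
  y <- complete_matrix(y)
  J <- ncol(y)
  M <- J * (J + 1L) / 2L
  current <- as.numeric(current %||% rep(0, M))
  if (length(current) != M)
    stop("current must have length J(J+1)/2 = ", M)
  maybe_set_seed(seed)
  a <- as.vector(cpp_sample_alpha(y, current, rep(0, M),
                                  alpha_prior_var(J, priors)))
  names(a) <- vech_names(J)
  a
}
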