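#' The Ising model for 0/1-coded binary responses
#'
#' @description
#' Functions for the Ising model used throughout this package: a distribution
#' over binary vectors \eqn{y \in \{0,1\}^J} with
#' \deqn{P(y \mid S) \propto \exp\Big(\sum_j s_{jj} y_j / 2 +
#'   \sum_{j<k} s_{jk} y_j y_k\Big),}
#' where `S` is a symmetric `J x J` parameter matrix on the log-odds scale:
#' diagonal entries are main effects (intercepts), off-diagonal entries are
#' conditional-association (edge) weights.
#'
#' **Coding convention.** Responses are coded 0/1, *not* -1/+1 as in parts of
#' the Ising literature.  Under 0/1 coding the conditional distribution of
#' item `j` given the rest is logistic with linear predictor
#' \eqn{s_{jj}/2 + \sum_{k \ne j} s_{jk} y_k}; note the factor 1/2 on the
#' diagonal.  The intercept reported to users is always `s_jj` itself.
#'
#' @name ising-model
NULL

#' Conditional success probability of one item given the rest
#'
#' Returns \eqn{P(Y_j = 1 \mid Y_{-j} = y_{rest})}, which under the Ising
#' model is `plogis(s_jj/2 + sum_{k != j} s_jk * y_k)`.  These logistic
#' conditionals are *exactly* compatible with the joint model: they equal the
#' conditionals derived from the joint pmf (see [pmf_table()]), which is what
#' makes chained-equations imputation with logistic conditionals coherent.
#'
#' @param S symmetric Ising parameter matrix.
#' @param j item index in `1:J`.
#' @param y_rest binary vector of length `J - 1`, the values of the other
#'   items in their original order with item `j` removed.
#' @return probability in (0, 1).
#' @examples
#' S <- matrix(c(0, log(2), log(2), 0), 2, 2)
#' conditional_probability(S, 1, 1)  # 2/3
#' @export
conditional_probability <- function(S, j, y_rest) {
  S <- validate_ising_matrix(S)
  J <- ncol(S)
  if (length(j) != 1L || j < 1L || j > J) stop("item index j out of range")
  y_rest <- check_binary(y_rest, J - 1L, "y_rest")
  eta <- S[j, j] / 2 + sum(S[j, -j] * y_rest)
  plogis(eta)
}

#' Log pseudo-likelihood (conditional composite likelihood) of one response
#'
#' The log of the product over items of each item's logistic conditional
#' given all others,
#' \deqn{\sum_j \big[(s_{jj}/2 + \textstyle\sum_{k \ne j} s_{jk} y_k)\, y_j -
#'   \log(1 + e^{s_{jj}/2 + \sum_{k \ne j} s_{jk} y_k})\big].}
#' This objective avoids the \eqn{2^J} normalizing constant of the joint
#' likelihood and is the likelihood part of the pseudo-posterior sampled by
#' [sample_alpha()].  Numerically stable for linear predictors up to ~700 in
#' absolute value.
#'
#' @param S symmetric Ising parameter matrix.
#' @param y binary vector of length `J` (no missing entries).
#' @return log pseudo-likelihood (scalar).
#' @examples
#' S <- matrix(0, 3, 3)
#' log_pseudo_likelihood(S, c(1, 0, 1))  # -3 * log(2)
#' @export
log_pseudo_likelihood <- function(S, y) {
  S <- validate_ising_matrix(S)
  J <- ncol(S)
  y <- check_binary(y, J, "y")
  eta <- as.vector(S %*% y) - diag(S) * y + diag(S) / 2
  sum(eta * y - softplus(eta))
}

#' Exact probability table of an Ising model by enumeration
#'
#' Enumerates all `2^J` response patterns and their normalized probabilities.
#' Infeasible beyond small `J`; a guard refuses `J > 20` ([sample_gibbs()] is
#' the sampler to use past the guard).
#'
#' @param S symmetric Ising parameter matrix with `J <= 20`.
#' @return data frame with the `J` pattern columns followed by `prob`;
#'   probabilities sum to one.
#' @examples
#' S <- matrix(c(0, log(2), log(2), 0), 2, 2)
#' pmf_table(S)  # P(1,1) = 2/5, the rest 1/5 each
#' @export
pmf_table <- function(S) {
  S <- validate_ising_matrix(S)
  J <- ncol(S)
  if (J > 20)
    stop("pmf_table enumerates 2^J patterns and is limited to J <= 20; ",
         "use sample_gibbs() for larger models")
  pats <- as.matrix(expand.grid(rep(list(0:1), J), KEEP.OUT.ATTRS = FALSE))
  storage.mode(pats) <- "double"
  colnames(pats) <- paste0("y", seq_len(J))
  logw <- 0.5 * rowSums((pats %*% S) * pats)
  logw <- logw - max(logw)
  prob <- exp(logw) / sum(exp(logw))
  out <- as.data.frame(pats)
  out$prob <- prob
  out
}

#' Draw i.i.d. responses from an Ising model by exact enumeration
#'
#' @param S symmetric Ising parameter matrix with `J <= 20`.
#' @param n number of respondents.
#' @param seed optional integer seed.
#' @return a fully observed [response_data] object.
#' @export
sample_exact <- function(S, n, seed = NULL) {
  maybe_set_seed(seed)
  tab <- pmf_table(S)
  J <- ncol(tab) - 1L
  idx <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$prob)
  y <- as.matrix(tab[idx, seq_len(J), drop = FALSE])
  rownames(y) <- NULL
  response_data(y)
}

#' Draw responses from an Ising model by systematic-scan Gibbs sampling
#'
#' Cycles through the items in order, redrawing each from its logistic full
#' conditional.  Intended for models too large to enumerate; at small `J` its
#' pattern frequencies agree with [sample_exact()].  Retained rows are taken
#' every `thin` full scans after `burnin` scans, which keeps the serial
#' dependence between retained rows negligible.
#'
#' @param S symmetric Ising parameter matrix.
#' @param n number of retained rows.
#' @param burnin number of initial full scans to discard (default 100).
#' @param thin number of full scans between retained rows (default 10).
#' @param seed optional integer seed.
#' @return a fully observed [response_data] object.
#' @export
sample_gibbs <- function(S, n, burnin = 100, thin = 10, seed = NULL) {
  S <- validate_ising_matrix(S)
  if (burnin < 0) stop("burnin must be non-negative")
  if (thin < 1) stop("thin must be at least 1")
  maybe_set_seed(seed)
  y <- cpp_ising_gibbs(S, as.integer(n), as.integer(burnin), as.integer(thin))
  colnames(y) <- paste0("Y", seq_len(ncol(S)))
  response_data(y)
}

# validate a 0/1 vector of a stated length
check_binary <- function(y, len, what) {
  y <- as.numeric(y)
  if (length(y) != len)
    stop(what, " must have length ", len, ", got ", length(y))
  if (anyNA(y)) stop(what, " must not contain missing entries")
  if (!all(y %in% c(0, 1))) stop(what, " must be coded 0/1")
  y
}
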