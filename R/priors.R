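#' Normal priors for the sampler
#'
#' Independent mean-zero normal priors are placed on every coefficient.  For
#' the per-item auxiliary logistic coefficients \eqn{\beta_j}, the intercept
#' \eqn{\beta_{jj}} gets a weakly informative variance (default 100) and the
#' slopes \eqn{\beta_{jk}}, which play the role of edge weights and are
#' typically sparse and moderate, get variance 1.  The prior on the
#' half-vectorized parameter matrix mirrors this shrinkage: variance 100 on
#' diagonal (intercept) coordinates, 1 on off-diagonal (edge) coordinates.
#'
#' @param beta_intercept_var prior variance of each \eqn{\beta_{jj}}.
#' @param beta_slope_var prior variance of each \eqn{\beta_{jk}}, `k != j`.
#' @param alpha_diag_var prior variance of diagonal vech coordinates `s_jj`.
#' @param alpha_offdiag_var prior variance of edge coordinates `s_jk`.
#' @return a list of class `ising_priors`.
#' @export
default_priors <- function(beta_intercept_var = 100, beta_slope_var = 1,
                           alpha_diag_var = 100, alpha_offdiag_var = 1) {
  vars <- c(beta_intercept_var, beta_slope_var, alpha_diag_var,
            alpha_offdiag_var)
  if (any(!is.finite(vars)) || any(vars <= 0))
    stop("prior variances must be positive and finite")
  structure(
    list(beta_intercept_var = beta_intercept_var,
         beta_slope_var = beta_slope_var,
         alpha_diag_var = alpha_diag_var,
         alpha_offdiag_var = alpha_offdiag_var),
    class = "ising_priors"
  )
}

# prior variance vector for beta_j (length J, intercept variance at j)
beta_prior_var <- function(J, j, priors) {
  v <- rep(priors$beta_slope_var, J)
  v[j] <- priors$beta_intercept_var
  v
}

# prior variance vector over vech coordinates (length J(J+1)/2)
alpha_prior_var <- function(J, priors) {
  info <- vech_info(J)
  ifelse(info$diag, priors$alpha_diag_var, priors$alpha_offdiag_var)
}
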