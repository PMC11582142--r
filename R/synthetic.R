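#' True parameter matrices and missingness mechanisms for simulation
#'
#' @description
#' Generators reproducing the two simulation regimes used to validate the
#' estimator, plus the missingness mechanisms applied to the complete data.
#' Both missing-at-random mechanisms decide masking from always-observed
#' values only, so the missingness process is ignorable for the estimation
#' of the Ising parameters.
#'
#' @name synthetic-data
NULL

#' Sparse random truth for the anchor-MAR recovery study
#'
#' A `J x J` symmetric matrix with zero diagonal (no main effects) in which
#' each upper-triangle edge is set to zero with probability `sparsity` and
#' otherwise drawn uniformly from \eqn{[-1, -0.4] \cup [0.4, 1]}, i.e. edges
#' are either absent or of clearly nonzero magnitude.
#'
#' @param J number of items (default 6).
#' @param sparsity probability an edge is zero (default 0.5).
#' @param seed optional integer seed.
#' @return symmetric `J x J` matrix.
#' @export
make_study1_truth <- function(J = 6, sparsity = 0.5, seed = NULL) {
  if (J < 2) stop("J must be at least 2")
  maybe_set_seed(seed)
  S <- matrix(0, J, J)
  up <- which(upper.tri(S))
  nz <- runif(length(up)) >= sparsity
  mag <- runif(sum(nz), 0.4, 1)
  sgn <- ifelse(runif(sum(nz)) < 0.5, -1, 1)
  S[up[nz]] <- sgn * mag
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

#' Truth for the screening-item study
#'
#' A six-item network whose first two items act as screening items: exactly
#' six strictly positive edges, one of which connects the two screening
#' items, all remaining edges zero.  The positive screening-pair edge is the
#' quantity that a complete-case analysis estimates with a large *negative*
#' bias (Berkson's paradox), making this configuration the canonical test of
#' the imputation-based estimators.  The exact configuration used in prior applied work is
#' not publicly printed, so this synthetic stand-in places the edges at a
#' configurable common weight.
#'
#' @param weight common edge weight (default 0.8).
#' @param edges two-column matrix of edge index pairs; defaults to
#'   `{1-2, 1-3, 2-4, 3-5, 4-6, 5-6}`.
#' @param intercepts diagonal values (default 0).
#' @return symmetric 6 x 6 matrix.
#' @export
make_study2_truth <- function(weight = 0.8,
                              edges = cbind(c(1, 1, 2, 3, 4, 5),
                                            c(2, 3, 4, 5, 6, 6)),
                              intercepts = 0) {
  if (weight <= 0) stop("edge weight must be strictly positive")
  S <- matrix(0, 6, 6)
  for (e in seq_len(nrow(edges)))
    S[edges[e, 1], edges[e, 2]] <- S[edges[e, 2], edges[e, 1]] <- weight
  diag(S) <- intercepts
  S
}

#' Specify a missingness mechanism
#'
#' @param kind one of:
#'   * `"mcar"`: every cell is masked independently with probability `rate`;
#'   * `"mar_anchor"`: the anchor item is always observed and every other
#'     cell of row `i` is masked independently with probability
#'     `p_miss[1]` when the anchor response is 1 and `p_miss[2]` when it is
#'     0 -- missing at random but not completely at random;
#'   * `"screening"`: the screening items are always observed and all other
#'     items of row `i` are masked exactly when every screening response is
#'     0 (the skip pattern of gated survey sections).
#' @param rate MCAR masking probability.
#' @param anchor anchor item index (`NULL` = last item).
#' @param p_miss length-2 masking probabilities `(anchor = 1, anchor = 0)`.
#' @param screening screening item indices (default `c(1, 2)`).
#' @return an object of class `missingness_spec`.
#' @export
missingness_spec <- function(kind = c("mcar", "mar_anchor", "screening"),
                             rate = 0.2, anchor = NULL,
                             p_miss = c(0.1, 0.4), screening = c(1, 2)) {
  kind <- match.arg(kind)
  if (kind == "mcar" &&
      (length(rate) != 1L || rate < 0 || rate > 1))
    stop("mcar rate must be a single probability")
  if (kind == "mar_anchor" &&
      (length(p_miss) != 2L || any(p_miss < 0) || any(p_miss > 1)))
    stop("p_miss must be two probabilities")
  structure(list(kind = kind, rate = rate, anchor = anchor,
                 p_miss = p_miss, screening = as.integer(screening)),
            class = "missingness_spec")
}

#' Mask a complete dataset under a missingness mechanism
#'
#' Applies a [missingness_spec()] to fully observed data.  Anchor and
#' screening items are never masked, and every masking decision reads only
#' always-observed values (the anchor or screening columns) or no values at
#' all (MCAR): the resulting missingness is genuinely missing at random.
#' Screening masking is deterministic given the screening responses.
#'
#' @param full a fully observed [response_data] (or 0/1 matrix).
#' @param spec a [missingness_spec()].
#' @param seed optional integer seed.
#' @return a [response_data] object with masked cells set to missing.
#' @export
apply_missingness <- function(full, spec, seed = NULL) {
  stopifnot(inherits(spec, "missingness_spec"))
  y <- complete_matrix(full)
  N <- nrow(y); J <- ncol(y)
  maybe_set_seed(seed)
  mask <- matrix(1L, N, J)
  if (spec$kind == "mcar") {
    mask[matrix(runif(N * J) < spec$rate, N, J)] <- 0L
  } else if (spec$kind == "mar_anchor") {
    anchor <- spec$anchor %||% J
    if (anchor < 1 || anchor > J) stop("anchor index out of range")
    p <- ifelse(y[, anchor] == 1L, spec$p_miss[1], spec$p_miss[2])
    for (j in seq_len(J)[-anchor])
      mask[runif(N) < p, j] <- 0L
  } else {  # screening
    scr <- spec$screening
    if (any(scr < 1) || any(scr > J)) stop("screening index out of range")
    gated <- rowSums(y[, scr, drop = FALSE]) == 0L
    mask[gated, seq_len(J)[-scr]] <- 0L
  }
  response_data(y, mask)
}
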