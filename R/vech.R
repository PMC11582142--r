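#' Half-vectorization of a symmetric Ising parameter matrix
#'
#' Stacks the lower triangle of a symmetric `J x J` matrix, including the
#' diagonal, column by column into a vector of length `J(J+1)/2`, i.e. in the
#' order \eqn{(s_{11}, \dots, s_{J1}, s_{22}, \dots, s_{J2}, \dots, s_{JJ})}.
#' This is the coordinate system in which the joint pseudo-posterior update
#' of the parameter matrix operates; `unvech()` inverts it exactly.
#'
#' @param S symmetric numeric matrix (validated to tolerance `1e-8`).
#' @return numeric vector of length `J(J+1)/2`, named `s_11, s_21, ...`
#'   (an underscore separates the indices when `J > 9`).
#' @examples
#' S <- matrix(c(1, 2, 2, 4), 2, 2)
#' vech(S)            # c(1, 2, 4)
#' unvech(vech(S))    # recovers S
#' @seealso [unvech()]
#' @export
vech <- function(S) {
  S <- validate_ising_matrix(S)
  a <- S[lower.tri(S, diag = TRUE)]
  names(a) <- vech_names(ncol(S))
  a
}

#' Rebuild a symmetric matrix from its half-vectorization
#'
#' @param a numeric vector of length `J(J+1)/2` in the ordering produced by
#'   [vech()].
#' @return symmetric `J x J` matrix.
#' @export
unvech <- function(a) {
  a <- as.numeric(a)
  J <- (sqrt(8 * length(a) + 1) - 1) / 2
  if (abs(J - round(J)) > 1e-8)
    stop("length(a) = ", length(a), " is not of the form J(J+1)/2")
  J <- as.integer(round(J))
  S <- matrix(0, J, J)
  S[lower.tri(S, diag = TRUE)] <- a
  S <- S + t(S)
  diag(S) <- diag(S) / 2
  S
}

# 1-based position of s_{rc} (any order of r, c) in vech coordinates
vech_idx <- function(r, c, J) {
  lo <- pmin(r, c)
  hi <- pmax(r, c)
  (lo - 1L) * J - (lo - 1L) * (lo - 2L) / 2 + (hi - lo + 1L)
}

# per-coordinate metadata: row >= col of the lower triangle, in vech order
vech_info <- function(J) {
  col <- rep(seq_len(J), times = J - seq_len(J) + 1L)
  row <- unlist(lapply(seq_len(J), function(c) seq.int(c, J)))
  data.frame(row = row, col = col, diag = row == col)
}

vech_names <- function(J) {
  info <- vech_info(J)
  sep <- if (J > 9) "_" else ""
  paste0("s_", info$row, sep, info$col)
}

# validate a J x J Ising parameter matrix: square, finite, symmetric
validate_ising_matrix <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("Ising parameter matrix must be square")
  if (!all(is.finite(S))) stop("Ising parameter matrix must be finite")
  asym <- max(abs(S - t(S)))
  if (asym > tol)
    stop("Ising parameter matrix is asymmetric (max |S - t(S)| = ",
         format(asym), ")")
  (S + t(S)) / 2
}
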