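# shared fixtures: random parameter matrices and enumeration oracles

# random symmetric Ising matrix with N(0, scale^2) entries
rand_sym <- function(J, scale = 1) {
  S <- matrix(rnorm(J * J, 0, scale), J, J)
  (S + t(S)) / 2
}

# exact conditional P(Y_j = 1 | Y_-j = y_rest) by enumeration of the pmf
enum_conditional <- function(S, j, y_rest) {
  tab <- pmf_table(S)
  J <- ncol(S)
  y1 <- y0 <- numeric(J)
  y1[-j] <- y0[-j] <- y_rest
  y1[j] <- 1
  match_row <- function(y) {
    hit <- apply(tab[, seq_len(J), drop = FALSE], 1,
                 function(r) all(r == y))
    tab$prob[hit]
  }
  p1 <- match_row(y1)
  p0 <- match_row(y0)
  p1 / (p1 + p0)
}

# all binary configurations of length n as a matrix
all_configs <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
}

# small response_data with MCAR missingness for pipeline tests
toy_missing_data <- function(N = 60, J = 3, rate = 0.2, seed = 42) {
  set.seed(seed)
  S <- rand_sym(J, 0.4)
  full <- sample_exact(S, N)
  apply_missingness(full, missingness_spec("mcar", rate = rate))
}
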