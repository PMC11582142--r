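test_that("logistic conditionals are exactly compatible with the joint pmf", {
  set.seed(101)
  for (J in 2:4) {
    for (rep in 1:5) {
      S <- rand_sym(J)
      configs <- all_configs(J - 1)
      for (j in seq_len(J)) {
        for (r in seq_len(nrow(configs))) {
          y_rest <- configs[r, ]
          expect_equal(conditional_probability(S, j, y_rest),
                       enum_conditional(S, j, y_rest),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("log pseudo-likelihood matches closed forms and composes from conditionals", {
  # zero matrix: every conditional is 1/2
  expect_equal(log_pseudo_likelihood(matrix(0, 3, 3), c(1, 0, 1)),
               -3 * log(2))
  # J = 2, s_12 = log 2, y = (1,1): each conditional is 2/3
  S2 <- matrix(c(0, log(2), log(2), 0), 2, 2)
  expect_equal(log_pseudo_likelihood(S2, c(1, 1)), log(4 / 9))
  # definitional consistency with conditional_probability
  set.seed(7)
  for (rep in 1:5) {
    S <- rand_sym(4)
    y <- rbinom(4, 1, 0.5)
    byhand <- sum(vapply(1:4, function(j) {
      p <- conditional_probability(S, j, y[-j])
      log(ifelse(y[j] == 1, p, 1 - p))
    }, numeric(1)))
    expect_equal(log_pseudo_likelihood(S, y), byhand)
  }
  # symmetry of storage does not matter (validator symmetrizes tiny noise)
  S <- rand_sym(3)
  Sp <- S; Sp[1, 2] <- Sp[1, 2] + 1e-10
  expect_equal(log_pseudo_likelihood(Sp, c(1, 1, 0)),
               log_pseudo_likelihood(S, c(1, 1, 0)), tolerance = 1e-9)
  expect_error(log_pseudo_likelihood(S, c(1, NA, 0)), "missing")
  expect_error(log_pseudo_likelihood(S, c(1, 1)), "length")
})

test_that("pmf_table normalizes and reproduces hand-computed tables", {
  expect_equal(pmf_table(matrix(0, 1, 1))$prob, c(0.5, 0.5))
  expect_equal(pmf_table(matrix(0, 2, 2))$prob, rep(0.25, 4))
  # weights 1,1,1,2 -> P(1,1) = 2/5
  S2 <- matrix(c(0, log(2), log(2), 0), 2, 2)
  tab <- pmf_table(S2)
  expect_equal(tab$prob[tab$y1 == 1 & tab$y2 == 1], 0.4)
  expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
  set.seed(5)
  S <- rand_sym(4)
  expect_equal(sum(pmf_table(S)$prob), 1, tolerance = 1e-12)
  expect_true(all(pmf_table(S)$prob > 0))
  expect_error(pmf_table(matrix(0, 21, 21)), "J <= 20")
})

test_that("pmf is invariant under simultaneous item permutation", {
  set.seed(9)
  S <- rand_sym(4)
  perm <- c(3, 1, 4, 2)
  tab <- pmf_table(S)
  tab_p <- pmf_table(S[perm, perm])
  # probability of pattern y under S equals that of y[perm] under permuted S
  key <- function(m) apply(m, 1, paste, collapse = "")
  pats <- as.matrix(tab[, 1:4])
  lookup <- stats::setNames(tab_p$prob, key(as.matrix(tab_p[, 1:4])))
  expect_equal(unname(lookup[key(pats[, perm, drop = FALSE])]), tab$prob,
               tolerance = 1e-12)
})

test_that("vech uses lower-triangle column-major order and round-trips", {
  expect_equal(unname(vech(matrix(c(1, 2, 2, 4), 2, 2))), c(1, 2, 4))
  S3 <- matrix(c(1, 2, 3,
                 2, 4, 5,
                 3, 5, 6), 3, 3, byrow = TRUE)
  expect_equal(unname(vech(S3)), c(1, 2, 3, 4, 5, 6))  # s11 s21 s31 s22 s32 s33
  set.seed(3)
  S <- rand_sym(5)
  expect_equal(unvech(vech(S)), S)
  A <- matrix(rnorm(9), 3, 3)  # asymmetric
  expect_error(vech(A), "asymmetric")
  expect_error(unvech(1:5), "J\\(J\\+1\\)/2")
})

test_that("exact sampler reproduces pattern probabilities and is deterministic", {
  S0 <- matrix(0, 2, 2)
  d <- sample_exact(S0, 40000, seed = 1)
  freq <- table(factor(paste(d$y[, 1], d$y[, 2]),
                       levels = c("0 0", "1 0", "0 1", "1 1"))) / d$N
  expect_true(all(abs(as.numeric(freq) - 0.25) < 0.01))
  S2 <- matrix(c(0, log(2), log(2), 0), 2, 2)
  d2 <- sample_exact(S2, 40000, seed = 2)
  expect_equal(mean(d2$y[, 1] == 1 & d2$y[, 2] == 1), 0.4, tolerance = 0.03)
  expect_identical(sample_exact(S2, 100, seed = 7)$y,
                   sample_exact(S2, 100, seed = 7)$y)
})

test_that("Gibbs sampler matches enumeration at small J", {
  set.seed(11)
  S <- rand_sym(6, 0.5)
  n <- 50000
  d <- sample_gibbs(S, n, burnin = 200, thin = 10, seed = 13)
  tab <- pmf_table(S)
  key <- apply(tab[, 1:6], 1, paste, collapse = "")
  emp <- table(factor(apply(d$y, 1, paste, collapse = ""), levels = key)) / n
  se <- sqrt(tab$prob * (1 - tab$prob) / n)
  expect_true(all(abs(as.numeric(emp) - tab$prob) < 3 * se + 1e-4))
  # zero matrix: item means 1/2
  d0 <- sample_gibbs(matrix(0, 8, 8), 20000, burnin = 50, thin = 2, seed = 1)
  expect_true(all(abs(colMeans(d0$y) - 0.5) < 0.02))
  expect_identical(sample_gibbs(S, 50, seed = 3)$y,
                   sample_gibbs(S, 50, seed = 3)$y)
})
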