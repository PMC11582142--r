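test_that("initialization copies observed cells and respects the clipping rule", {
  d <- toy_missing_data(N = 50, J = 3, rate = 0.3)
  st <- initialize_missing(d, seed = 1)
  obs <- d$mask == 1L
  expect_identical(st$y[obs], d$y[obs])
  expect_true(all(st$y %in% c(0L, 1L)))
  expect_identical(initialize_missing(d, seed = 5)$y,
                   initialize_missing(d, seed = 5)$y)
  # complete data: exact copy
  full <- response_data(st$y)
  expect_identical(initialize_missing(full, seed = 2)$y, full$y)
  # observed column mean 0 -> fills at the 0.05 floor
  y <- cbind(c(rep(0L, 30), rep(NA, 1000)), rep(1L, 1030))
  dz <- response_data(y)
  fills <- initialize_missing(dz, seed = 3)$y[31:1030, 1]
  expect_gt(mean(fills), 0)        # clipping keeps the start non-degenerate
  expect_lt(mean(fills), 0.1)
  # an all-missing column is an error
  expect_error(initialize_missing(response_data(cbind(NA, c(0L, 1L)))),
               "no observed values")
})

test_that("impute_item redraws only missing cells from the logistic conditional", {
  # beta_j = 0 -> fair coin on the missing cells
  set.seed(4)
  y <- cbind(c(rep(NA, 4000), rbinom(100, 1, 0.5)), rbinom(4100, 1, 0.5))
  d <- response_data(y)
  st <- initialize_missing(d, seed = 1)
  st2 <- impute_item(st, 1, d, seed = 2)
  expect_equal(mean(st2$y[1:4000, 1]), 0.5, tolerance = 0.03)
  expect_identical(st2$y[d$mask == 1L], d$y[d$mask == 1L])
  expect_identical(st2$y[, 2], st$y[, 2])
  # beta = (0, log 2) with y_2 = 1 -> success probability 2/3
  st$betas[1, ] <- c(0, log(2))
  d1 <- response_data(cbind(rep(NA_integer_, 4000), rep(1L, 4000)),
                      mask = cbind(rep(0L, 4000), rep(1L, 4000)))
  st$y <- cbind(rep(0L, 4000), rep(1L, 4000))
  st3 <- impute_item(st, 1, d1, seed = 3)
  expect_equal(mean(st3$y[, 1]), 2 / 3, tolerance = 0.03)
  # no missing cells in the item -> state untouched, no RNG consumed
  dfull <- response_data(matrix(rbinom(20, 1, 0.5), 10, 2))
  stf <- initialize_missing(dfull, seed = 9)
  expect_identical(impute_item(stf, 1, dfull), stf)
})

test_that("R-level sweep composition is bit-identical to the fused sweep", {
  d <- toy_missing_data(N = 40, J = 3, rate = 0.25, seed = 8)
  pri <- default_priors()
  st <- initialize_missing(d, seed = 1)
  # fused C++ sweep
  set.seed(33)
  st_f <- fcs_sweep(st, d, pri)
  # manual composition: per item, refresh beta_j then impute item j
  set.seed(33)
  st_m <- st
  for (j in 1:3) {
    st_m$betas[j, ] <- sample_beta_j(j, st_m$y, pri,
                                     current = st_m$betas[j, ])
    st_m <- impute_item(st_m, j, d)
  }
  expect_identical(st_f$y, st_m$y)
  expect_equal(st_f$betas, st_m$betas, tolerance = 1e-14)
})

test_that("observed cells are immutable over many sweeps", {
  d <- toy_missing_data(N = 80, J = 4, rate = 0.3, seed = 12)
  st <- initialize_missing(d, seed = 2)
  set.seed(3)
  for (t in 1:30) st <- fcs_sweep(st, d)
  obs <- d$mask == 1L
  expect_identical(st$y[obs], d$y[obs])
  expect_equal(st$iteration, 30L)
})

test_that("stationary imputation distribution matches the joint-model conditional", {
  # J = 3 toy: column 3 missing for a random subset; after convergence the
  # imputed values for rows with (y1, y2) = (1, 1) must follow the exact
  # conditional P(Y3 = 1 | Y1 = 1, Y2 = 1) of the generating Ising model.
  S0 <- matrix(c(0.2, 0.8, -0.5,
                 0.8, 0.0,  0.4,
                -0.5, 0.4, -0.3), 3, 3, byrow = TRUE)
  target <- enum_conditional(S0, 3, c(1, 1))
  set.seed(61)
  full <- sample_exact(S0, 3000)
  mask <- matrix(1L, 3000, 3)
  mask[runif(3000) < 0.2, 3] <- 0L
  d <- response_data(full$y, mask)
  rows <- which(d$mask[, 3] == 0L & d$y[, 1] == 1L & d$y[, 2] == 1L)
  expect_gt(length(rows), 50)
  st <- initialize_missing(d, seed = 1)
  set.seed(2)
  for (t in 1:100) st <- fcs_sweep(st, d)   # burn-in
  acc <- 0; nsw <- 300
  for (t in 1:nsw) {
    st <- fcs_sweep(st, d)
    acc <- acc + mean(st$y[rows, 3])
  }
  expect_equal(acc / nsw, target, tolerance = 0.05)
})

test_that("item visit order does not change the long-run imputation distribution", {
  S0 <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  set.seed(71)
  full <- sample_exact(S0, 2000)
  mask <- matrix(1L, 2000, 2)
  mask[runif(2000) < 0.25, 1] <- 0L
  d <- response_data(full$y, mask)
  run_mean <- function(order, seed) {
    st <- initialize_missing(d, seed = seed)
    set.seed(seed + 1)
    for (t in 1:50) st <- fcs_sweep(st, d, order = order)
    acc <- 0
    for (t in 1:150) {
      st <- fcs_sweep(st, d, order = order)
      acc <- acc + mean(st$y[d$mask[, 1] == 0L, 1])
    }
    acc / 150
  }
  m12 <- run_mean(c(1, 2), 5)
  m21 <- run_mean(c(2, 1), 6)
  expect_equal(m12, m21, tolerance = 0.04)
  expect_error(fcs_sweep(initialize_missing(d, seed = 1), d, order = c(1, 1)),
               "permutation")
})
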