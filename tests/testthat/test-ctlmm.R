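test_that("initial-state probabilities follow the logit model", {
  m <- transition_model(beta0 = 0, gamma0 = c(0, 0))
  expect_equal(unname(initial_state_probs(m)), c(0.5, 0.5))
  m2 <- transition_model(beta0 = -2.1972, gamma0 = c(0, 0))
  expect_equal(unname(initial_state_probs(m2)[2]), 0.10, tolerance = 1e-4)
  m3 <- transition_model(beta0 = 0.3, beta = c(z = 0), gamma0 = c(0, 0),
                         gamma12 = c(z = 0), gamma21 = c(z = 0),
                         covariates = "z", init_covariates = "z")
  expect_equal(initial_state_probs(m3, c(z = -3)),
               initial_state_probs(m3, c(z = 10)))
})

test_that("intensity matrix has log-linear off-diagonals and zero row sums", {
  m <- transition_model(beta0 = 0, gamma0 = c(0, 0))
  expect_equal(unname(intensity_matrix(m)),
               matrix(c(-1, 1, 1, -1), 2, 2))
  m2 <- transition_model(beta0 = 0, gamma0 = c(log(0.2), log(0.5)),
                         gamma12 = c(z = 0.5), gamma21 = c(z = 0),
                         covariates = "z")
  Q <- intensity_matrix(m2, c(z = 2))
  expect_equal(Q[1, 2], 0.2 * exp(1), tolerance = 1e-12)
  expect_equal(unname(rowSums(Q)), c(0, 0), tolerance = 1e-12)
})

test_that("interval transition probabilities equal the matrix exponential", {
  Q <- matrix(c(-1, 2, 1, -2), 2, 2)
  P <- transition_prob_matrix(Q, 0.5)
  expect_equal(unname(P), rbind(c(0.7410, 0.2590), c(0.5179, 0.4821)),
               tolerance = 1e-4)
  expect_equal(unname(transition_prob_matrix(Q, 0)), diag(2))
  expect_error(transition_prob_matrix(Q, -1), "nonnegative")
  # eigen-decomposition cross-check to 1e-12
  ev <- eigen(Q * 0.5)
  Pe <- ev$vectors %*% diag(exp(ev$values)) %*% solve(ev$vectors)
  expect_equal(unname(P), Pe, tolerance = 1e-12)
  # long horizon: both rows at the stationary distribution
  Pinf <- transition_prob_matrix(Q, 1e6)
  expect_equal(unname(Pinf[1, ]), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(unname(Pinf[2, ]), c(2 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("Chapman-Kolmogorov holds for split intervals", {
  set.seed(7)
  for (i in 1:20) {
    Q <- intensity_matrix(transition_model(0, gamma0 = rnorm(2)))
    d1 <- runif(1, 0, 3); d2 <- runif(1, 0, 3)
    expect_equal(transition_prob_matrix(Q, d1 + d2),
                 transition_prob_matrix(Q, d1) %*% transition_prob_matrix(Q, d2),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("forward recursion equals brute-force path enumeration", {
  d <- small_dataset()  # T = 3 and T = 2 respondents
  D <- rbind(c(0.95, 0.05), c(0.3, 0.7))
  set.seed(5)
  for (i in 1:10) {
    m <- transition_model(beta0 = rnorm(1), gamma0 = rnorm(2, -1),
                          gamma12 = c(z = rnorm(1, 0, 0.5)),
                          gamma21 = c(z = rnorm(1, 0, 0.5)),
                          covariates = "z")
    w <- sample(1:2, 5, replace = TRUE)
    expect_equal(forward_loglik(w, D, d, m),
                 enumerate_loglik(w, D, d, m), tolerance = 1e-10)
  }
  # T = 1 degenerate case and perfect measurement
  df1 <- small_ema_df()[1, ]
  d1 <- ema_dataset(df1, items = c("it1", "it2", "it3"), covariates = "z",
                    n_categories = 7)
  m0 <- transition_model(beta0 = qlogis(0.3), gamma0 = c(0, 0))
  expect_equal(forward_loglik(2L, diag(2), d1, m0), log(0.3))
  expect_equal(forward_loglik(2L, D, d1, m0), log(0.7 * 0.05 + 0.3 * 0.7))
})

test_that("transition-model fit recovers strong self-persistence", {
  truth <- transition_model(beta0 = qlogis(0.2),
                            gamma0 = c(log(0.05), log(0.3)))
  sim <- simulate_markov_dataset(truth, 150, 20, intervals = "uniform",
                                 seed = 31)
  fit <- fit_transition_model(sim$assignments, diag(2), sim$data)
  P1 <- predict_transition_probs(fit, delta = 1)
  P1true <- predict_transition_probs(truth, delta = 1)
  expect_lt(abs(P1[1, 1] - P1true[1, 1]), 0.02)
  expect_lt(abs(P1[2, 2] - P1true[2, 2]), 0.08)
  expect_equal(unname(rowSums(P1)), c(1, 1), tolerance = 1e-12)
})

test_that("Wald test and backward selection behave at the boundaries", {
  truth <- small_transition_model(slopes = c(0.8, -0.6))
  covgen <- function(N, T) data.frame(z = rnorm(N * T))
  sim <- simulate_markov_dataset(truth, 120, 15, covariate_gen = covgen,
                                 seed = 17)
  fit <- fit_transition_model(sim$assignments, diag(2), sim$data,
                              covariates = "z")
  wt <- wald_test(fit, "z")
  expect_equal(wt$df, 2L)
  expect_lt(wt$p_value, 0.05)  # strongly predictive covariate is detected
  expect_error(wald_test(fit, "nope"), "not in model")
  # zero slopes with a nonsingular covariance give statistic 0, p = 1
  fit0 <- fit
  fit0$gamma12[["z"]] <- 0; fit0$gamma21[["z"]] <- 0
  wt0 <- wald_test(fit0, "z")
  expect_equal(wt0$statistic, 0)
  expect_equal(wt0$p_value, 1)
  # alpha = 1 never removes anything
  sel <- backward_select(sim$assignments, diag(2), sim$data,
                         candidates = "z", alpha = 1)
  expect_equal(sel$covariates, "z")
  expect_equal(nrow(sel$removal_trail), 0L)
  # a strongly predictive covariate survives backward selection
  sel05 <- backward_select(sim$assignments, diag(2), sim$data,
                           candidates = "z", alpha = 0.05)
  expect_true("z" %in% sel05$covariates)
})

test_that("predicted transition probability is monotone in the intensity", {
  m <- transition_model(0, gamma0 = c(log(0.2), log(0.3)))
  m_hi <- transition_model(0, gamma0 = c(log(0.4), log(0.3)))
  for (delta in c(0.3, 1, 4)) {
    expect_gt(predict_transition_probs(m_hi, delta = delta)[1, 2],
              predict_transition_probs(m, delta = delta)[1, 2])
  }
  expect_equal(unname(predict_transition_probs(
    transition_model(0, gamma0 = c(-30, -30)), delta = 1)), diag(2),
    tolerance = 1e-10)
})
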