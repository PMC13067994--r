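test_that("surrogate generating models are well-formed", {
  att <- default_attentive_grm()
  expect_true(att$surrogate)
  expect_equal(att$n_items, 10L)
  expect_equal(sum(att$loadings < 0), 2L)       # two negatively worded items
  expect_true(all(apply(att$thresholds, 1, function(k) all(diff(k) < 0))))
  # non-degenerate marginal: every category reachable under theta ~ N(0,1)
  grid <- quadrature_grid()
  marg <- vapply(seq_len(10), function(j)
    ciermix:::grm_item_prob_table(att$loadings[j, 1], att$thresholds[j, ],
                                  grid$nodes) %*% grid$weights,
    numeric(7))
  expect_gt(min(marg), 0.01)
  ci <- default_cier_grm()
  expect_true(all(diff(ci$thresholds) < 0))
  expect_equal(ci$sigma2_xi, 1)
  # bimodal-extreme preference: extremes dominate the random-responding shape
  p <- random_responding_probs(ci)
  expect_gt(p[1] + p[7], 0.75)
})

test_that("attentive simulation matches model-implied marginals", {
  # zero-loading items: empirical frequencies match threshold-only probs
  m0 <- attentive_grm(matrix(0), matrix(c(1.2, 0.3, -0.6, -1.4), 1))
  y <- simulate_attentive(m0, 10000, seed = 2)
  want <- category_probs(c(1, plogis(c(1.2, 0.3, -0.6, -1.4)), 0))
  freq <- tabulate(y + 1, 5) / 10000
  expect_true(all(abs(freq - want) < 3 * sqrt(want * (1 - want) / 10000)))
  # determinism
  expect_equal(simulate_attentive(small_grm(), 50, seed = 9),
               simulate_attentive(small_grm(), 50, seed = 9))
  # goodness of fit of a moderate item against quadrature-implied marginals
  m <- attentive_grm(matrix(1.5), matrix(c(1.5, 0.5, -0.5, -1.5), 1))
  y2 <- simulate_attentive(m, 10000, seed = 3)
  grid <- quadrature_grid(121)
  pm <- drop(ciermix:::grm_item_prob_table(1.5, c(1.5, 0.5, -0.5, -1.5),
                                           grid$nodes) %*% grid$weights)
  gof <- chisq.test(tabulate(y2 + 1, 5), p = pm / sum(pm))
  expect_gt(gof$p.value, 0.01)
})

test_that("C/IER patterns have their defining shapes", {
  # stated midpoint probabilities sum to one
  expect_equal(0.80 + 2 * 0.05 + 4 * 0.025, 1)
  y_mid <- simulate_cier("midpoint", 4000, seed = 4)
  freq <- tabulate(y_mid + 1, 7) / length(y_mid)
  expect_equal(freq[4], 0.80, tolerance = 0.02)
  expect_equal(freq[3] + freq[5], 0.10, tolerance = 0.015)
  # straightlining rows have zero within-row variance
  y_sl <- simulate_cier("straightlining", 200, seed = 5)
  expect_true(all(apply(y_sl, 1, function(r) length(unique(r))) == 1))
  expect_gt(length(unique(y_sl[, 1])), 1)  # value varies across observations
  # uniform responding is uniform over categories
  y_u <- simulate_cier("uniform", 5000, seed = 6)
  fu <- tabulate(y_u + 1, 7) / length(y_u)
  expect_true(all(abs(fu - 1 / 7) < 3 * sqrt((1 / 7) * (6 / 7) / length(y_u))))
  expect_error(simulate_cier("nope", 10), "unknown C/IER pattern")
})

test_that("heterogeneity manipulation scales thresholds and flips signs", {
  att <- default_attentive_grm()
  low <- apply_heterogeneity(att, "low", n_negative = 0, seed = 3)
  expect_true(all(low$loadings > 0))
  expect_equal(low$thresholds, att$thresholds)
  hi <- apply_heterogeneity(att, "high", n_negative = 2, seed = 3)
  rec <- attr(hi, "manipulation")
  expect_length(rec$halved, 3L)
  expect_length(rec$doubled, 3L)
  expect_equal(hi$thresholds[rec$halved, ],
               att$thresholds[rec$halved, ] * 0.5)
  expect_equal(hi$thresholds[rec$doubled, ],
               att$thresholds[rec$doubled, ] * 2)
  expect_equal(sum(hi$loadings < 0), 2L)
  expect_true(all(apply(hi$thresholds, 1, function(k) all(diff(k) < 0))))
  expect_error(apply_heterogeneity(att, "low", n_negative = 11), "exceeds")
})

test_that("loading decay follows the geometric schedule", {
  att <- default_attentive_grm()
  none <- apply_loading_decay(att, d = 1, n_affected = 5, n_occasions = 60,
                              seed = 2)
  expect_true(all(apply(none$loadings, 2, function(v) length(unique(v)) == 1)))
  dec <- apply_loading_decay(attentive_grm(matrix(2), matrix(c(1, -1), 1)),
                             d = 0.99, n_affected = 1, n_occasions = 60)
  expect_equal(dec$loadings[60, 1], 2 * 0.99^59, tolerance = 1e-12)
  expect_equal(2 * 0.99^59, 1.106, tolerance = 1e-3)     # roughly halved
  dec95 <- apply_loading_decay(attentive_grm(matrix(2), matrix(c(1, -1), 1)),
                               d = 0.95, n_affected = 1, n_occasions = 60)
  expect_lt(dec95$loadings[60, 1], 0.1 * 2)              # essentially zero
})

test_that("two-factor violation draws correlated trait pairs", {
  att <- default_attentive_grm()
  tf <- apply_two_factor(att, proportion = 0.3, rho = 0.6, n_obs = 10000,
                         seed = 8)
  expect_equal(mean(tf$flags), 0.3, tolerance = 1e-6)
  expect_equal(tf$model2$n_traits, 2L)
  expect_equal(tf$model2$loadings[1:5, 2], rep(0, 5))
  expect_equal(abs(tf$model2$loadings[6:10, 2]), abs(att$loadings[6:10, 1]))
  set.seed(10)
  z <- matrix(rnorm(2e4), ncol = 2) %*% chol(tf$model2$trait_cor)
  expect_lt(abs(cor(z)[1, 2] - 0.6), 3 / sqrt(1e4))
  # rho = 1 collapses to a single factor: the two halves of the
  # questionnaire stay as coherent as under the unidimensional model
  tf1 <- apply_two_factor(att, 1, rho = 1, n_obs = 10, seed = 1)
  y1 <- simulate_attentive(tf1$model2, 500, seed = 21)
  half1 <- rowSums(y1[, c(1, 2, 4, 5)])        # positive items, factor 1
  half2 <- rowSums(y1[, c(6, 7, 9, 10)])       # positive items, factor 2
  expect_gt(cor(half1, half2), 0.9)
})

test_that("generate_condition is deterministic with complete truth records", {
  spec <- condition_spec(n_respondents = 20, n_occasions = 10)
  a <- generate_condition(spec, seed = 3)
  b <- generate_condition(spec, seed = 3)
  expect_equal(a$data$data, b$data$data)
  expect_equal(a$truth, b$truth)
  expect_equal(nrow(a$truth), 200L)
  expect_equal(a$data$n_obs, 200L)
  # pattern labels partition the C/IER set
  expect_true(all(is.na(a$truth$pattern) == (a$truth$state == "attentive")))
  # realized C/IER count close to binomial expectation at full scale
  big <- generate_condition(condition_spec(), seed = 4)
  n_cier <- sum(big$truth$state == "cier")
  expect_lt(abs(n_cier - 450), 3 * sqrt(4500 * 0.1 * 0.9))
  # equal hourly spacing by default
  expect_equal(unique(na.omit(big$data$data$.delta)), 1)
})

test_that("Markov simulation respects intensities and covariate effects", {
  # zero intensities: everyone stays in the initial state
  frozen <- transition_model(beta0 = qlogis(0.3), gamma0 = c(-30, -30))
  sim <- simulate_markov_dataset(frozen, 50, 6, seed = 2)
  states <- matrix(sim$states, nrow = 6)
  expect_true(all(apply(states, 2, function(s) length(unique(s)) == 1)))
  # long-run state frequency approaches the stationary distribution
  m <- transition_model(beta0 = 0, gamma0 = c(log(0.2), log(0.4)))
  sim2 <- simulate_markov_dataset(m, 3, 2000, seed = 3)
  expect_lt(abs(mean(sim2$states == 2) - 0.2 / 0.6), 0.05)
  # positive slope on z raises observed 1 -> 2 transition frequency at high z
  mz <- small_transition_model(slopes = c(1.2, 0))
  covgen <- function(N, T) data.frame(z = rnorm(N * T))
  sim3 <- simulate_markov_dataset(mz, 200, 30, covariate_gen = covgen,
                                  seed = 4)
  df <- sim3$data$data
  prev <- c(NA, sim3$states[-length(sim3$states)])
  first <- is.na(df$.delta)
  at_risk <- !first & prev == 1
  trans <- sim3$states == 2 & at_risk
  hi <- df$z > 0.5; lo <- df$z < -0.5
  expect_gt(mean(trans[at_risk & hi]), mean(trans[at_risk & lo]))
})
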