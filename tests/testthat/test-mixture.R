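test_that("posterior state probabilities follow Bayes rule", {
  # pi2 = 0.1, L_att = 0.02, L_cier = 0.08 -> posterior C/IER = 0.008 / 0.026
  post <- 0.1 * 0.08 / (0.9 * 0.02 + 0.1 * 0.08)
  expect_equal(post, 0.3077, tolerance = 1e-4)
  fit <- structure(list(
    attentive = small_grm(), cier = small_cier(), pi2 = 0.1,
    posterior = cbind(p_attentive = 1 - post, p_cier = post),
    settings = estimation_settings()), class = "mixture_fit")
  expect_equal(unname(posterior_state_probs(fit)[1, 2]), post,
               tolerance = 1e-4)
  # equal component likelihoods and pi2 = 0.5 -> (0.5, 0.5)
  expect_equal(0.5 * 1 / (0.5 * 1 + 0.5 * 1), 0.5)
})

test_that("start schedule is reproducible, sized and ordered", {
  st <- estimation_settings(n_starts = 10, seed = 5)
  s1 <- multi_start_schedule(st, 10, 6)
  s2 <- multi_start_schedule(st, 10, 6)
  expect_length(s1, 10)
  expect_equal(s1[[3]]$attentive$loadings, s2[[3]]$attentive$loadings)
  for (s in s1) {
    expect_true(all(apply(s$attentive$thresholds, 1, function(k)
      all(diff(k) < 0))))
    expect_true(all(diff(s$cier$thresholds) < 0))
    expect_gte(s$pi2, 0.05); expect_lte(s$pi2, 0.30)
  }
  # wording-declared signs are respected
  st2 <- estimation_settings(n_starts = 3, seed = 5,
                             wording = c(1, 1, -1, 1, -1))
  for (s in multi_start_schedule(st2, 5, 6))
    expect_equal(sign(s$attentive$loadings[, 1]), c(1, 1, -1, 1, -1))
})

test_that("EM log-likelihood is monotone and posteriors normalize", {
  set.seed(8)
  d <- generate_condition(condition_spec(n_respondents = 15, n_occasions = 12,
                                         patterns = c(uniform = 1)),
                          seed = 77)$data
  st <- estimation_settings(n_starts = 3, n_final = 2, stage_iters = 8,
                            max_iter = 150, seed = 2,
                            wording = c(1, 1, -1, 1, 1, 1, 1, -1, 1, 1))
  fit <- suppressWarnings(fit_mixture(d, st))
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_equal(unname(rowSums(fit$posterior)), rep(1, d$n_obs),
               tolerance = 1e-10)
  expect_gte(fit$pi2, 0); expect_lte(fit$pi2, 1)
  # the attentive component keeps attentive structure: not collapsed onto
  # the constrained unit-loading equal-threshold form
  expect_gt(sd(fit$attentive$loadings[, 1]), 0.01)
})

test_that("EM matches a direct optimizer of the observed likelihood", {
  # small mixed dataset; oracle = generic optimizer over all parameters,
  # written out independently of the EM path
  set.seed(30)
  n <- 400; J <- 3; G <- 2
  att_true <- attentive_grm(matrix(c(1.8, 1.4, 2.2)),
                            rbind(c(1, -0.8), c(0.6, -1), c(1.2, -0.4)))
  cier <- rbinom(n, 1, 0.15) == 1
  Y <- matrix(NA_integer_, n, J)
  Y[!cier, ] <- simulate_attentive(att_true, sum(!cier))
  Y[cier, ] <- matrix(sample(0:2, sum(cier) * J, TRUE), ncol = J)
  df <- data.frame(id = rep(1:20, each = 20), occasion = rep(1:20, 20),
                   time_hours = rep(0:19, 20))
  for (j in 1:J) df[[paste0("it", j)]] <- Y[, j]
  d <- ema_dataset(df, paste0("it", 1:J), n_categories = 3)
  # run EM to a tight optimum so the stationary-point comparison is exact
  st <- estimation_settings(n_starts = 4, n_final = 2, stage_iters = 10,
                            seed = 3, wording = rep(1, 3),
                            tol_param = 1e-7, tol_loglik = 1e-9,
                            max_iter = 3000)
  fit <- suppressWarnings(fit_mixture(d, st))

  grid <- quadrature_grid()
  cat_table <- function(eta, th) {
    # (G+1) x Q category probabilities at linear predictors eta (length Q)
    cum <- rbind(1, plogis(outer(th, eta, "+")), 0)
    pmax(cum[-nrow(cum), , drop = FALSE] - cum[-1, , drop = FALSE], 1e-300)
  }
  obs_negll <- function(p) {
    # p: 3 loadings, 3 x (k1, gap), cier (k1, gap), log sigma, logit pi2
    al <- p[1:3]
    th <- rbind(c(p[4], p[4] - exp(p[5])), c(p[6], p[6] - exp(p[7])),
                c(p[8], p[8] - exp(p[9])))
    ck <- c(p[10], p[10] - exp(p[11]))
    sg <- exp(p[12]); pi2 <- plogis(p[13])
    la <- matrix(0, n, length(grid$nodes))
    lc <- matrix(0, n, length(grid$nodes))
    tabC <- log(cat_table(sg * grid$nodes, ck))
    for (j in 1:3) {
      tabA <- log(cat_table(al[j] * grid$nodes, th[j, ]))
      la <- la + tabA[Y[, j] + 1, ]
      lc <- lc + tabC[Y[, j] + 1, ]
    }
    L1 <- exp(la) %*% grid$weights
    L2 <- exp(lc) %*% grid$weights
    -sum(log((1 - pi2) * L1 + pi2 * L2))
  }
  p0 <- c(fit$attentive$loadings[, 1],
          fit$attentive$thresholds[1, 1], log(-diff(fit$attentive$thresholds[1, ])),
          fit$attentive$thresholds[2, 1], log(-diff(fit$attentive$thresholds[2, ])),
          fit$attentive$thresholds[3, 1], log(-diff(fit$attentive$thresholds[3, ])),
          fit$cier$thresholds[1], log(-diff(fit$cier$thresholds)),
          log(sqrt(max(fit$cier$sigma2_xi, 1e-6))), qlogis(fit$pi2))
  direct <- nlminb(p0, obs_negll, control = list(iter.max = 150))
  # the EM solution is a stationary point of the observed likelihood: the
  # generic optimizer cannot improve on it by more than a small tolerance
  expect_lt(-direct$objective - fit$loglik, 1e-3)
  expect_equal(-obs_negll(p0), fit$loglik, tolerance = 1e-4)
})

test_that("pi2 is recovered without C/IER and with 10% planted C/IER", {
  set.seed(9)
  spec0 <- condition_spec(n_respondents = 40, n_occasions = 25,
                          cier_rate = 0, patterns = c(uniform = 1))
  sim0 <- generate_condition(spec0, seed = 5)
  st <- estimation_settings(n_starts = 4, n_final = 2, stage_iters = 8,
                            seed = 6, wording = c(1, 1, -1, 1, 1, 1, 1, -1, 1, 1))
  fit0 <- suppressWarnings(fit_mixture(sim0$data, st))
  expect_lte(fit0$pi2, 0.02)

  ests <- vapply(1:3, function(r) {
    sim <- generate_condition(condition_spec(n_respondents = 40,
                                             n_occasions = 25,
                                             patterns = c(uniform = 1)),
                              seed = 100 + r)
    suppressWarnings(fit_mixture(sim$data, st))$pi2
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.10), 0.03)
})
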