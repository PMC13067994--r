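# Small fixtures shared across the suite; everything is built in code.

# 3-item, 5-category attentive model with modest parameters.
small_grm <- function() {
  attentive_grm(
    loadings = matrix(c(1.2, -0.8, 1.6), ncol = 1),
    thresholds = rbind(c(2, 1, -0.5, -1.5),
                       c(1.5, 0.5, -0.5, -2),
                       c(2.2, 0.8, -0.8, -2.2)))
}

small_cier <- function(sigma2 = 1) {
  cier_grm(c(1.5, 0.5, -0.5, -1.5), sigma2_xi = sigma2)
}

# Long-format data frame for io tests: 2 respondents, uneven occasions.
small_ema_df <- function() {
  data.frame(
    id = c("a", "a", "a", "b", "b"),
    occasion = c(1, 2, 3, 1, 2),
    time_hours = c(8, 9.5, 12, 0, 2.5),
    it1 = c(0, 3, NA, 4, 1),
    it2 = c(2, 6, 5, 0, 0),
    it3 = c(1, 2, 3, 2, 6),
    z = c(0.5, 0.5, 0.5, -1, -1))
}

small_dataset <- function() {
  ema_dataset(small_ema_df(), items = c("it1", "it2", "it3"),
              covariates = "z", n_categories = 7)
}

# Transition model with mild covariate effects for step-3 tests.
small_transition_model <- function(slopes = c(0.4, -0.3)) {
  transition_model(beta0 = qlogis(0.15),
                   gamma0 = c(log(0.05), log(0.4)),
                   gamma12 = c(z = slopes[1]), gamma21 = c(z = slopes[2]),
                   covariates = "z")
}

# Brute-force path enumeration of the corrected latent Markov likelihood,
# independent of the package's forward recursion.
enumerate_loglik <- function(assignments, D, data, model) {
  df <- data$data
  ids <- unique(df[[data$id]])
  total <- 0
  for (i in ids) {
    rows <- which(df[[data$id]] == i)
    Tn <- length(rows)
    paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
    lik <- 0
    for (p in seq_len(nrow(paths))) {
      s <- as.integer(paths[p, ])
      z1 <- if (length(model$init_covariates))
        unlist(df[rows[1], model$init_covariates]) else numeric()
      pr <- unname(initial_state_probs(model, z1)[s[1]]) *
        D[s[1], assignments[rows[1]]]
      if (Tn > 1) for (t in 2:Tn) {
        zt <- if (length(model$covariates))
          unlist(df[rows[t], model$covariates]) else numeric()
        P <- transition_prob_matrix(intensity_matrix(model, zt),
                                    df$.delta[rows[t]])
        pr <- pr * P[s[t - 1], s[t]] * D[s[t], assignments[rows[t]]]
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}
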