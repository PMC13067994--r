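#' Transition-model parameter container (step 3)
#'
#' Two-state continuous-time latent Markov model on the error-prone modal
#' assignments: initial-state logit (attentive = reference), log-linear
#' transition intensities \eqn{\log q_{lk} = \gamma_{0lk} + \gamma_{lk}'z},
#' and the fixed classification-error matrix `D` as the measurement part.
#'
#' @param beta0 initial-state intercept \eqn{\beta_{02}}.
#' @param beta named vector of initial-state slopes (may be empty).
#' @param gamma0 length-2 vector of log-intensity intercepts
#'   (attentive-to-C/IER, C/IER-to-attentive).
#' @param gamma12,gamma21 named slope vectors over the covariates for the
#'   two transitions (may be empty).
#' @param covariates covariate names entering the intensities.
#' @param init_covariates covariate names entering the initial-state logit.
#' @param D 2 x 2 classification-error matrix.
#' @param vcov,loglik,convergence optional fit metadata.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(beta0, beta = numeric(), gamma0,
                             gamma12 = numeric(), gamma21 = numeric(),
                             covariates = names(gamma12),
                             init_covariates = names(beta),
                             D = diag(2), vcov = NULL, loglik = NA_real_,
                             convergence = NULL) {
  if (is.null(covariates)) covariates <- character()
  if (is.null(init_covariates)) init_covariates <- character()
  stopifnot(length(gamma0) == 2, length(gamma12) == length(covariates),
            length(gamma21) == length(covariates),
            length(beta) == length(init_covariates))
  names(gamma12) <- covariates; names(gamma21) <- covariates
  if (length(beta)) names(beta) <- init_covariates
  par_names <- c("beta0",
                 if (length(init_covariates)) paste0("beta_", init_covariates),
                 "gamma0_12",
                 if (length(covariates)) paste0("gamma12_", covariates),
                 "gamma0_21",
                 if (length(covariates)) paste0("gamma21_", covariates))
  structure(list(beta0 = beta0, beta = beta, gamma0 = gamma0,
                 gamma12 = gamma12, gamma21 = gamma21,
                 covariates = covariates, init_covariates = init_covariates,
                 D = D, vcov = vcov, loglik = loglik,
                 convergence = convergence, par_names = par_names),
            class = "transition_model")
}

pack_pars <- function(model) {
  c(model$beta0, model$beta, model$gamma0[1], model$gamma12,
    model$gamma0[2], model$gamma21)
}

unpack_pars <- function(par, covariates, init_covariates, D = diag(2)) {
  U <- length(covariates); V <- length(init_covariates)
  i <- 1
  beta0 <- par[i]; i <- i + 1
  beta <- if (V) stats::setNames(par[i:(i + V - 1)], init_covariates) else numeric()
  i <- i + V
  g012 <- par[i]; i <- i + 1
  g12 <- if (U) stats::setNames(par[i:(i + U - 1)], covariates) else numeric()
  i <- i + U
  g021 <- par[i]; i <- i + 1
  g21 <- if (U) stats::setNames(par[i:(i + U - 1)], covariates) else numeric()
  transition_model(beta0, beta, c(g012, g021), g12, g21, covariates,
                   init_covariates, D = D)
}

#' Initial-state probabilities
#'
#' Logit model for starting in the C/IER state:
#' \eqn{\pi_2 = \mathrm{logit}^{-1}(\beta_{02} + \beta_2' z_1)},
#' \eqn{\pi_1 = 1 - \pi_2}.
#'
#' @param model a [transition_model()].
#' @param z1 covariate vector at the first occasion (named or in
#'   `init_covariates` order; ignored when the model has no initial-state
#'   covariates).
#' @return Length-2 probability vector `(attentive, cier)`.
#' @export
initial_state_probs <- function(model, z1 = numeric()) {
  eta <- model$beta0
  if (length(model$init_covariates)) {
    z <- if (!is.null(names(z1))) z1[model$init_covariates] else z1
    if (length(z) != length(model$beta) || any(is.na(z)))
      stop("covariate vector does not match the initial-state model")
    eta <- eta + sum(model$beta * z)
  }
  p2 <- logistic(eta)
  c(attentive = 1 - p2, cier = p2)
}

#' Transition intensity matrix
#'
#' Off-diagonals \eqn{q_{lk} = \exp(\gamma_{0lk} + \gamma_{lk}'z)};
#' diagonals \eqn{-\sum_{k \ne l} q_{lk}}, so rows sum to 0 and intensities
#' are positive for any finite covariate values.
#'
#' @param model a [transition_model()].
#' @param z covariate vector (named or in `covariates` order).
#' @return 2 x 2 intensity matrix `Q`.
#' @export
intensity_matrix <- function(model, z = numeric()) {
  e12 <- model$gamma0[1]; e21 <- model$gamma0[2]
  if (length(model$covariates)) {
    zz <- if (!is.null(names(z))) z[model$covariates] else z
    if (length(zz) != length(model$covariates) || any(is.na(zz)))
      stop("covariate vector does not match the transition model")
    e12 <- e12 + sum(model$gamma12 * zz)
    e21 <- e21 + sum(model$gamma21 * zz)
  }
  q12 <- exp(e12); q21 <- exp(e21)
  matrix(c(-q12, q21, q12, -q21), 2, 2,
         dimnames = list(c("attentive", "cier"), c("attentive", "cier")))
}

#' Interval transition probabilities
#'
#' Matrix exponential of `Q * delta`, computed in closed form for the
#' two-state chain via the stationary decomposition
#' \eqn{P_\delta = \Pi + e^{-(q_{12}+q_{21})\delta}(I - \Pi)} with
#' stationary rows \eqn{\Pi = (q_{21}, q_{12})/(q_{12}+q_{21})}. Rows sum to
#' 1 and \eqn{P_0 = I}.
#'
#' @param Q 2 x 2 intensity matrix.
#' @param delta nonnegative interval (hours).
#' @return 2 x 2 row-stochastic matrix.
#' @export
transition_prob_matrix <- function(Q, delta) {
  if (delta < 0) stop("interval delta must be nonnegative")
  q12 <- Q[1, 2]; q21 <- Q[2, 1]
  s <- q12 + q21
  if (s <= 0) return(diag(2))
  pi_row <- c(q21, q12) / s
  e <- exp(-s * delta)
  P <- rbind(pi_row, pi_row) + e * (diag(2) - rbind(pi_row, pi_row))
  dimnames(P) <- dimnames(Q)
  P
}

# Per-row transition probabilities (p11, p12, p21, p22) for all data rows,
# vectorized over observations; rows at each respondent's first occasion are
# left as NA and ignored by the filter.
row_transition_probs <- function(model, data) {
  df <- data$data
  n <- nrow(df)
  e12 <- rep(model$gamma0[1], n); e21 <- rep(model$gamma0[2], n)
  for (u in model$covariates) {
    zu <- df[[u]]
    if (is.null(zu) || any(is.na(zu)))
      stop("missing covariate values for '", u, "'")
    e12 <- e12 + model$gamma12[[u]] * zu
    e21 <- e21 + model$gamma21[[u]] * zu
  }
  q12 <- exp(e12); q21 <- exp(e21)
  s <- q12 + q21
  eterm <- exp(-s * df$.delta)
  p11 <- (q21 + q12 * eterm) / s
  p22 <- (q12 + q21 * eterm) / s
  cbind(p11, 1 - p11, 1 - p22, p22)
}

respondent_index <- function(data) {
  rid <- as.factor(data$data[[data$id]])
  len <- as.integer(table(rid)[unique(rid)])
  first <- cumsum(c(1L, head(len, -1L)))
  list(first = first, len = len)
}

#' Forward log-likelihood of the corrected latent Markov model
#'
#' Scaled forward recursion over each respondent's assignment sequence,
#' with the step-2 assignments as manifest indicators emitted through the
#' fixed classification-error matrix `D`:
#' \deqn{\sum_i \log \sum_{s_1 \ldots s_T} \pi(s_1|z_1) D[s_1, w_1]
#'   \prod_{t>1} P_{\delta_t}(s_{t-1} \to s_t | z_t) D[s_t, w_t].}
#'
#' @param assignments integer vector (1/2) aligned with `data` rows.
#' @param D 2 x 2 classification-error matrix.
#' @param data an [ema_dataset()] carrying timestamps and covariates.
#' @param model a [transition_model()].
#' @return Scalar log-likelihood.
#' @export
forward_loglik <- function(assignments, D, data, model) {
  stopifnot(length(assignments) == data$n_obs)
  idx <- respondent_index(data)
  init2 <- vapply(idx$first, function(f) {
    z1 <- if (length(model$init_covariates))
      unlist(data$data[f, model$init_covariates]) else numeric()
    initial_state_probs(model, z1)[2]
  }, numeric(1))
  P <- row_transition_probs(model, data)
  P[idx$first, ] <- 0  # unused; avoids NA from the undefined first interval
  .forward_loglik_cpp(as.integer(assignments), idx$first, idx$len, init2, P, D)
}

#' Fit the continuous-time transition model (step 3)
#'
#' Maximizes [forward_loglik()] over the initial-state and log-intensity
#' parameters with the measurement part fixed at the step-2
#' classification-error matrix. Starts from a deterministic near-identity
#' chain (\eqn{\gamma_0 = \log 0.1}, slopes 0, intercept at the observed
#' first-occasion logit); the covariance matrix comes from the inverse
#' observed information.
#'
#' @inheritParams forward_loglik
#' @param covariates covariate names entering the transition intensities
#'   (taken at the destination occasion; intensities are piecewise constant
#'   within intervals).
#' @param init_covariates covariate names entering the initial-state logit
#'   (default none: intercept-only).
#' @param warn_constant warn when a covariate is constant within persons
#'   (person-level covariates repeated across occasions inflate the
#'   effective sample size).
#' @return A fitted [transition_model()] with `vcov`, `loglik` and
#'   convergence information.
#' @export
fit_transition_model <- function(assignments, D, data,
                                 covariates = character(),
                                 init_covariates = character(),
                                 warn_constant = TRUE) {
  stopifnot(inherits(data, "ema_dataset"))
  idx <- respondent_index(data)
  if (all(idx$len < 2)) stop("no respondent has 2 or more occasions")
  if (warn_constant && length(covariates)) {
    rid <- data$data[[data$id]]
    for (u in covariates) {
      if (all(tapply(data$data[[u]], rid, function(v) length(unique(v)) == 1L)))
        warning("covariate '", u, "' is constant within persons; ",
                "repeating it across occasions inflates the sample size")
    }
  }
  p1 <- mean(assignments[idx$first] == 2L)
  start_model <- transition_model(
    beta0 = qlogis(min(max(p1, 0.02), 0.98)),
    beta = stats::setNames(rep(0, length(init_covariates)), init_covariates),
    gamma0 = c(log(0.1), log(0.1)),
    gamma12 = stats::setNames(rep(0, length(covariates)), covariates),
    gamma21 = stats::setNames(rep(0, length(covariates)), covariates),
    covariates = covariates, init_covariates = init_covariates, D = D)
  negll <- function(par) {
    m <- unpack_pars(par, covariates, init_covariates, D)
    ll <- forward_loglik(assignments, D, data, m)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  p0 <- pack_pars(start_model)
  if (!is.finite(negll(p0)) || negll(p0) >= 1e10) p0 <- p0 * 0.5
  opt <- optim(p0, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  H <- optimHess(opt$par, negll)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(vc) || any(!is.finite(vc)) || any(diag(vc) <= 0)
  if (singular) {
    warning("observed information is singular; covariance flagged")
    sv <- svd(H)
    pos <- sv$d > max(sv$d) * 1e-12
    vc <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  model <- unpack_pars(opt$par, covariates, init_covariates, D)
  model$loglik <- -opt$value
  model$vcov <- vc
  dimnames(model$vcov) <- list(model$par_names, model$par_names)
  model$convergence <- list(code = opt$convergence, singular = singular)
  model
}

#' Wald test for a covariate's transition slopes
#'
#' Quadratic form of the covariate's two transition slopes against the
#' corresponding covariance block; chi-square with 2 degrees of freedom.
#'
#' @param model a fitted [transition_model()].
#' @param covariate covariate name.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(model, covariate) {
  if (!covariate %in% model$covariates)
    stop("covariate not in model: ", covariate)
  sl <- c(paste0("gamma12_", covariate), paste0("gamma21_", covariate))
  i <- match(sl, model$par_names)
  g <- c(model$gamma12[[covariate]], model$gamma21[[covariate]])
  Vb <- model$vcov[i, i]
  Vinv <- tryCatch(solve(Vb), error = function(e)
    stop("singular covariance block for covariate ", covariate))
  W <- drop(t(g) %*% Vinv %*% g)
  list(statistic = W, df = 2L, p_value = pchisq(W, 2L, lower.tail = FALSE))
}

#' Backward covariate selection via Wald tests
#'
#' Starts from the model with all candidate covariates and iteratively
#' removes the covariate with the largest non-significant Wald p-value,
#' refitting after each removal, until all remaining covariates are
#' significant at level `alpha`.
#'
#' @inheritParams fit_transition_model
#' @param candidates candidate covariate names.
#' @param alpha significance level (default 0.05).
#' @return The final fitted [transition_model()], with a `removal_trail`
#'   data.frame attached (covariate removed, statistic, p-value per round).
#' @export
backward_select <- function(assignments, D, data, candidates, alpha = 0.05,
                            init_covariates = character(),
                            warn_constant = FALSE) {
  stopifnot(length(candidates) >= 1)
  current <- candidates
  trail <- data.frame(covariate = character(), statistic = numeric(),
                      p_value = numeric())
  repeat {
    model <- fit_transition_model(assignments, D, data, covariates = current,
                                  init_covariates = init_covariates,
                                  warn_constant = warn_constant)
    if (!length(current)) break
    tests <- lapply(current, function(u) wald_test(model, u))
    p <- vapply(tests, `[[`, numeric(1), "p_value")
    worst <- which.max(p)
    if (p[worst] <= alpha) break
    trail <- rbind(trail, data.frame(covariate = current[worst],
                                     statistic = tests[[worst]]$statistic,
                                     p_value = p[worst]))
    current <- current[-worst]
  }
  model$removal_trail <- trail
  model
}

#' Predicted interval transition probabilities at a covariate profile
#'
#' Composes [intensity_matrix()] and [transition_prob_matrix()]; used to
#' compare transition probabilities at low versus high covariate values
#' while holding other covariates at their means.
#'
#' @param model a [transition_model()].
#' @param z covariate profile.
#' @param delta interval in hours (default 1).
#' @return 2 x 2 row-stochastic matrix.
#' @export
predict_transition_probs <- function(model, z = numeric(), delta = 1) {
  transition_prob_matrix(intensity_matrix(model, z), delta)
}

#' @export
print.transition_model <- function(x, ...) {
  cat("transition_model (2-state continuous-time latent Markov)\n")
  cat(sprintf("  beta0 = %.3f; gamma0 = (%.3f, %.3f); logLik = %.2f\n",
              x$beta0, x$gamma0[1], x$gamma0[2], x$loglik))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
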