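#' Attentive graded response model parameters
#'
#' Container for the attentive mixture component: a (possibly
#' multidimensional) graded response model with cumulative logits
#' \eqn{P(y_{j} \ge g \mid \theta) = \mathrm{logit}^{-1}(\sum_m \alpha_{jm}
#' \theta_m + \kappa_{jg})}. Raw responses are modelled, so negatively worded
#' items carry negative loadings rather than being recoded. For
#' identification the latent traits have mean 0 and variance 1. The `+kappa`
#' sign convention means each item's thresholds must be strictly decreasing
#' in `g`, which is what makes all category probabilities nonnegative.
#'
#' @param loadings numeric `J x M` matrix of item loadings (a vector is taken
#'   as one column). Estimation supports `M = 1`; `M = 2` is used by the
#'   simulator's two-factor violation designs.
#' @param thresholds numeric `J x G` matrix, row `j` strictly decreasing.
#' @param trait_cor `M x M` trait correlation matrix (diagonal 1); only used
#'   when simulating multidimensional traits.
#' @param surrogate logical flag marking parameter sets that stand in for
#'   unpublished empirical estimates.
#' @return An object of class `attentive_grm`.
#' @export
attentive_grm <- function(loadings, thresholds, trait_cor = NULL,
                          surrogate = FALSE) {
  loadings <- as.matrix(loadings)
  thresholds <- as.matrix(thresholds)
  if (nrow(loadings) != nrow(thresholds))
    stop("loadings and thresholds must describe the same number of items")
  if (any(apply(thresholds, 1L, function(k) any(diff(k) >= 0))))
    stop("item thresholds must be strictly decreasing across categories")
  M <- ncol(loadings)
  if (is.null(trait_cor)) trait_cor <- diag(M)
  structure(list(loadings = loadings, thresholds = thresholds,
                 trait_cor = trait_cor, n_items = nrow(loadings),
                 n_thresholds = ncol(thresholds), n_traits = M,
                 surrogate = surrogate),
            class = "attentive_grm")
}

#' Constrained C/IER graded response model parameters
#'
#' The inattentive component: a unidimensional GRM over a latent category
#' preference \eqn{\xi \sim N(0, \sigma^2_\xi)} in which all item loadings
#' are fixed to 1 and the thresholds are shared across items, so the model
#' carries no item content. In the \eqn{\sigma^2_\xi \to 0} limit the
#' thresholds alone determine the category distribution of purely random
#' responding.
#'
#' @param thresholds numeric length-`G` vector, strictly decreasing.
#' @param sigma2_xi variance of the category-preference trait
#'   (`0 <= sigma2_xi <= 100`; straightlining data push the estimate towards
#'   the upper bound, which is flagged during estimation).
#' @param surrogate see [attentive_grm()].
#' @return An object of class `cier_grm`.
#' @export
cier_grm <- function(thresholds, sigma2_xi = 1, surrogate = FALSE) {
  thresholds <- as.numeric(thresholds)
  if (any(diff(thresholds) >= 0))
    stop("C/IER thresholds must be strictly decreasing across categories")
  if (sigma2_xi < 0) stop("sigma2_xi must be nonnegative")
  structure(list(thresholds = thresholds, sigma2_xi = sigma2_xi,
                 n_thresholds = length(thresholds), surrogate = surrogate),
            class = "cier_grm")
}

#' Normal quadrature grid
#'
#' Equally spaced nodes on a standard-normal range with density weights
#' normalized to sum to 1, used for marginal maximum likelihood integration
#' over the latent traits (the category-preference trait is rescaled by
#' \eqn{\sigma_\xi} at evaluation time).
#'
#' @param n number of nodes (default 61).
#' @param range half-width of the grid in standard deviations (default 6).
#' @return List with `nodes` and `weights` (weights sum to 1).
#' @export
quadrature_grid <- function(n = 61, range = 6) {
  nodes <- seq(-range, range, length.out = n)
  w <- dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' Cumulative category probability of the attentive GRM
#'
#' \eqn{P(y_j \ge g \mid \theta)}: equal to 1 at `g = 0`, 0 at `g = G + 1`,
#' and the logistic of the item's cumulative logit in between; nonincreasing
#' in `g`.
#'
#' @param model an [attentive_grm()].
#' @param trait numeric length-`M` trait vector.
#' @param item item index.
#' @param g category index in `0..G+1`.
#' @export
attentive_cumulative_prob <- function(model, trait, item, g) {
  G <- model$n_thresholds
  if (item < 1 || item > model$n_items) stop("invalid item index")
  if (g < 0 || g > G + 1) stop("g must lie in 0..G+1")
  if (g == 0) return(1)
  if (g == G + 1) return(0)
  logistic(sum(model$loadings[item, ] * trait) + model$thresholds[item, g])
}

#' Cumulative category probability of the C/IER component
#'
#' \eqn{P(y_j \ge g \mid \xi)} with unit loading and shared thresholds, so
#' the value is identical for every item.
#'
#' @param model a [cier_grm()].
#' @param xi category-preference value.
#' @param g category index in `0..G+1`.
#' @export
cier_cumulative_prob <- function(model, xi, g) {
  G <- model$n_thresholds
  if (g < 0 || g > G + 1) stop("g must lie in 0..G+1")
  if (g == 0) return(1)
  if (g == G + 1) return(0)
  logistic(xi + model$thresholds[g])
}

#' Category probabilities from a cumulative vector
#'
#' Adjacent differences of the `(G+2)`-vector
#' \eqn{(P(y \ge 0), \ldots, P(y \ge G+1)) = (1, \ldots, 0)}; the result is
#' a proper distribution over the `G+1` categories.
#'
#' @param cumulative nonincreasing numeric vector starting at 1, ending at 0.
#' @export
category_probs <- function(cumulative) {
  if (abs(cumulative[1] - 1) > 1e-12 ||
      abs(cumulative[length(cumulative)]) > 1e-12)
    stop("cumulative vector must start at 1 and end at 0")
  if (any(diff(cumulative) > 1e-12))
    stop("cumulative probabilities must be nonincreasing")
  -diff(cumulative)
}

#' Category distribution of purely random responding
#'
#' The \eqn{\sigma^2_\xi \to 0} limit of the marginal C/IER category
#' distribution: category probabilities evaluated at \eqn{\xi = 0}, where
#' the shared thresholds alone fix the distribution.
#'
#' @param model a [cier_grm()].
#' @return `(G+1)`-vector of category probabilities.
#' @export
random_responding_probs <- function(model) {
  cum <- c(1, logistic(model$thresholds), 0)
  category_probs(cum)
}

# (G+1) x Q category probability table for one item at the given nodes.
grm_item_prob_table <- function(loading, thresholds, nodes) {
  eta <- outer(thresholds, nodes, function(k, x) loading * x + k)  # G x Q
  cum <- rbind(1, logistic(eta), 0)                                # (G+2) x Q
  p <- cum[-nrow(cum), , drop = FALSE] - cum[-1, , drop = FALSE]   # (G+1) x Q
  pmax(p, 1e-300)
}

# List of per-item log category-probability tables for either component.
# For the C/IER component the trait axis is xi = sigma_xi * node.
log_prob_tables <- function(model, nodes) {
  if (inherits(model, "attentive_grm")) {
    if (model$n_traits != 1L)
      stop("likelihood tables require a unidimensional model")
    lapply(seq_len(model$n_items), function(j)
      log(grm_item_prob_table(model$loadings[j, 1], model$thresholds[j, ], nodes)))
  } else if (inherits(model, "cier_grm")) {
    sg <- sqrt(model$sigma2_xi)
    list(log(grm_item_prob_table(sg, model$thresholds, nodes)))
  } else stop("unknown measurement model")
}

#' Conditional pattern log-likelihood given the latent trait
#'
#' Sum of log category probabilities over the non-missing items (local
#' independence given the trait). Missing items are simply skipped, which is
#' equivalent to marginalizing them out.
#'
#' @param model an [attentive_grm()] (unidimensional) or [cier_grm()].
#' @param responses length-`J` integer vector of codes `0..G`, `NA` missing.
#'   For a `cier_grm`, any length is accepted (items are exchangeable).
#' @param trait scalar latent value: \eqn{\theta} for the attentive model,
#'   \eqn{\xi} (on its own scale) for the C/IER model.
#' @export
pattern_loglik_given_trait <- function(model, responses, trait) {
  if (all(is.na(responses))) stop("all responses missing for this observation")
  obs <- which(!is.na(responses))
  if (inherits(model, "attentive_grm")) {
    sum(vapply(obs, function(j) {
      cum <- c(1, logistic(model$loadings[j, 1] * trait + model$thresholds[j, ]), 0)
      log(max(cum[responses[j] + 1] - cum[responses[j] + 2], 1e-300))
    }, numeric(1)))
  } else {
    cum <- c(1, logistic(trait + model$thresholds), 0)
    p <- pmax(cum[-length(cum)] - cum[-1], 1e-300)
    sum(log(p[responses[obs] + 1]))
  }
}

#' Marginal pattern log-likelihood
#'
#' Integrates the conditional pattern likelihood over the latent trait with
#' a [quadrature_grid()], using log-sum-exp stabilization:
#' \eqn{\log \sum_q w_q \exp \ell(y \mid x_q)}. For the C/IER component the
#' node axis is rescaled by \eqn{\sigma_\xi}.
#'
#' @inheritParams pattern_loglik_given_trait
#' @param grid a [quadrature_grid()].
#' @export
marginal_pattern_loglik <- function(model, responses, grid = quadrature_grid()) {
  scale <- if (inherits(model, "cier_grm")) sqrt(model$sigma2_xi) else 1
  ll <- vapply(grid$nodes * scale, function(x)
    pattern_loglik_given_trait(model, responses, x), numeric(1))
  m <- max(ll + log(grid$weights))
  m + log(sum(exp(ll + log(grid$weights) - m)))
}

# n x Q conditional log-likelihood matrix for all observations (compiled).
component_loglik_matrix <- function(model, Y, nodes) {
  tabs <- log_prob_tables(model, nodes)
  if (inherits(model, "cier_grm")) tabs <- rep(tabs, ncol(Y))
  .pattern_loglik_matrix(Y, tabs)
}
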