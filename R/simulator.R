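#' Surrogate attentive GRM generating parameters
#'
#' A documented stand-in for the empirical attentive measurement model used
#' as the data-generating model of the simulation designs: 10
#' momentary-satisfaction-style items on a 7-point scale with steep,
#' homogeneous item characteristic curves (|alpha| in 3.5-6, consistent
#' with the scale's near-perfect reported reliability), two negatively
#' worded items (3 and 8) carrying negative loadings, and six strictly
#' decreasing, widely spaced thresholds per item (about +-7 around a +1
#' shift). Positively worded items are right-skewed (agreement common) and
#' the negatively worded items carry the mirrored, left-skewed thresholds;
#' every marginal category probability under a standard-normal trait
#' exceeds 0.01. Flagged `surrogate = TRUE`.
#'
#' @return An [attentive_grm()].
#' @export
default_attentive_grm <- function() {
  loadings <- c(5.25, 4.75, -4.0, 5.75, 5.0, 5.5, 3.75, -3.5, 4.25, 6.0)
  base <- seq(1, -1, length.out = 6) * 7 + 1
  shift <- seq(-0.2, 0.2, length.out = 10)
  thresholds <- t(vapply(seq_len(10), function(j) {
    if (loadings[j] > 0) base + shift[j] else -rev(base) + shift[j]
  }, numeric(6)))
  attentive_grm(matrix(loadings, ncol = 1), thresholds, surrogate = TRUE)
}

#' Surrogate C/IER GRM generating parameters
#'
#' Stand-in for the empirical C/IER component estimates: category-preference
#' variance 1 and tightly spaced shared thresholds, which make the middle
#' categories nearly dead and concentrate inattentive responses on the two
#' extreme categories (the bimodal-extreme preference shape). Flagged
#' `surrogate = TRUE`.
#'
#' @return A [cier_grm()].
#' @export
default_cier_grm <- function() {
  cier_grm(seq(0.25, -0.25, length.out = 6), sigma2_xi = 1, surrogate = TRUE)
}

# Draw GRM responses: traits n x M, loadings J x M, thresholds J x G.
sample_grm_responses <- function(loadings, thresholds, traits) {
  n <- nrow(traits); J <- nrow(loadings)
  Y <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    eta <- drop(traits %*% loadings[j, ])
    cum <- logistic(outer(eta, thresholds[j, ], "+"))  # n x G, decreasing in g
    Y[, j] <- as.integer(rowSums(runif(n) <= cum))
  }
  Y
}

#' Simulate attentive responses
#'
#' One latent trait draw per observation (standard normal, or correlated
#' standard normals for a multidimensional model), then independent
#' categories per item from the graded response model.
#'
#' @param grm an [attentive_grm()].
#' @param n number of observations.
#' @param seed optional integer seed.
#' @param traits optional pre-drawn `n x M` trait matrix.
#' @return `n x J` integer response matrix.
#' @export
simulate_attentive <- function(grm, n, seed = NULL, traits = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- grm$n_traits
  if (is.null(traits)) {
    z <- matrix(rnorm(n * M), n, M)
    traits <- if (M > 1) {
      # symmetric square root; handles the degenerate rho = 1 limit
      e <- eigen(grm$trait_cor, symmetric = TRUE)
      z %*% (e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
    } else z
  }
  sample_grm_responses(grm$loadings, grm$thresholds, traits)
}

#' Simulate C/IER responses of a given pattern
#'
#' Patterns: `"uniform"` (iid uniform over the categories per item),
#' `"midpoint"` (strong midpoint preference: probability 0.80 for the
#' middle category, 0.05 for each adjacent and 0.025 for the remaining
#' categories of a 7-point scale), `"straightlining"` (one uniformly drawn
#' category per observation copied to all items), and `"grm"` (the
#' constrained category-preference GRM with
#' \eqn{\xi \sim N(0, \sigma^2_\xi)}).
#'
#' @param pattern one of `"uniform"`, `"midpoint"`, `"straightlining"`,
#'   `"grm"`.
#' @param n number of observations.
#' @param n_items,n_categories response matrix dimensions.
#' @param seed optional integer seed.
#' @param model a [cier_grm()] for `pattern = "grm"`.
#' @return `n x J` integer response matrix.
#' @export
simulate_cier <- function(pattern, n, n_items = 10, n_categories = 7,
                          seed = NULL, model = default_cier_grm()) {
  if (!is.null(seed)) set.seed(seed)
  G <- n_categories - 1L
  switch(pattern,
    uniform = matrix(sample(0:G, n * n_items, replace = TRUE), n, n_items),
    midpoint = {
      if (n_categories != 7L)
        stop("the midpoint-preference pattern is defined for 7 categories")
      probs <- c(0.025, 0.025, 0.05, 0.80, 0.05, 0.025, 0.025)
      matrix(sample(0:6, n * n_items, replace = TRUE, prob = probs),
             n, n_items)
    },
    straightlining = {
      v <- sample(0:G, n, replace = TRUE)
      matrix(rep(v, n_items), n, n_items)
    },
    grm = {
      xi <- rnorm(n, 0, sqrt(model$sigma2_xi))
      cum <- logistic(outer(xi, model$thresholds, "+"))
      Y <- matrix(0L, n, n_items)
      for (j in seq_len(n_items))
        Y[, j] <- as.integer(rowSums(runif(n) <= cum))
      Y
    },
    stop("unknown C/IER pattern: ", pattern))
}

#' Apply questionnaire-heterogeneity manipulations
#'
#' High item heterogeneity multiplies the thresholds of three randomly
#' selected items by 0.50 and of three others by 2.00 (proportional set
#' sizes for `J != 10`); low heterogeneity leaves thresholds unchanged.
#' Wording: `n_negative = NA` keeps the model's own loading signs,
#' `n_negative = 0` takes absolute values of all loadings, and
#' `n_negative = k > 0` takes absolute values and then flips the sign of
#' `k` randomly selected items. Selections are recorded in the
#' `"manipulation"` attribute.
#'
#' @param grm an [attentive_grm()].
#' @param level `"low"` or `"high"`.
#' @param n_negative `NA`, 0 or a positive count.
#' @param seed optional integer seed.
#' @return A modified [attentive_grm()].
#' @export
apply_heterogeneity <- function(grm, level = c("low", "high"),
                                n_negative = NA, seed = NULL) {
  level <- match.arg(level)
  if (!is.null(seed)) set.seed(seed)
  J <- grm$n_items
  loadings <- grm$loadings
  thresholds <- grm$thresholds
  record <- list(level = level, n_negative = n_negative)
  if (level == "high") {
    k <- max(1L, round(0.3 * J))
    pick <- sample(seq_len(J), 2L * k)
    halved <- pick[seq_len(k)]
    doubled <- pick[k + seq_len(k)]
    thresholds[halved, ] <- thresholds[halved, , drop = FALSE] * 0.5
    thresholds[doubled, ] <- thresholds[doubled, , drop = FALSE] * 2
    record$halved <- halved
    record$doubled <- doubled
  }
  if (!is.na(n_negative)) {
    if (n_negative > J) stop("n_negative exceeds the number of items")
    loadings <- abs(loadings)
    if (n_negative > 0) {
      neg <- sample(seq_len(J), n_negative)
      loadings[neg, ] <- -loadings[neg, , drop = FALSE]
      record$negative_items <- neg
    }
  }
  out <- attentive_grm(loadings, thresholds, grm$trait_cor,
                       surrogate = grm$surrogate)
  attr(out, "manipulation") <- record
  out
}

#' Occasion-indexed loading decay
#'
#' For randomly selected affected items, loadings decay geometrically
#' across occasions: \eqn{\alpha_{jt} = \alpha_{j1} d^{(t-1)}}; other items
#' stay constant.
#'
#' @param grm an [attentive_grm()].
#' @param d decay factor in (0, 1].
#' @param n_affected number of affected items.
#' @param n_occasions number of occasions `T`.
#' @param seed optional integer seed.
#' @return List with `loadings` (`T x J` matrix of occasion-specific
#'   loadings) and `affected` (item indices).
#' @export
apply_loading_decay <- function(grm, d, n_affected, n_occasions,
                                seed = NULL) {
  stopifnot(d > 0, d <= 1, n_affected <= grm$n_items)
  if (!is.null(seed)) set.seed(seed)
  J <- grm$n_items
  affected <- if (n_affected > 0) sample(seq_len(J), n_affected) else integer()
  L <- matrix(rep(grm$loadings[, 1], each = n_occasions), n_occasions, J)
  for (j in affected)
    L[, j] <- grm$loadings[j, 1] * d^(seq_len(n_occasions) - 1)
  list(loadings = L, affected = affected, d = d)
}

#' Two-factor attentive structure for a subset of observations
#'
#' Flags a random proportion of observations for which the attentive traits
#' are drawn from a bivariate standard normal with correlation `rho`; items
#' 1..J/2 load on the first factor and the rest on the second, with the
#' same loading magnitudes and thresholds as the unidimensional model.
#'
#' @param grm a unidimensional [attentive_grm()].
#' @param proportion proportion of observations affected, in \[0, 1\].
#' @param rho factor correlation in (-1, 1\].
#' @param n_obs total number of observations to flag from.
#' @param seed optional integer seed.
#' @return List with `model2` (the two-factor [attentive_grm()]) and
#'   `flags` (logical vector of length `n_obs`).
#' @export
apply_two_factor <- function(grm, proportion, rho, n_obs, seed = NULL) {
  stopifnot(proportion >= 0, proportion <= 1, rho > -1, rho <= 1)
  if (!is.null(seed)) set.seed(seed)
  J <- grm$n_items
  half <- floor(J / 2)
  L2 <- matrix(0, J, 2)
  L2[seq_len(half), 1] <- grm$loadings[seq_len(half), 1]
  L2[(half + 1):J, 2] <- grm$loadings[(half + 1):J, 1]
  model2 <- attentive_grm(L2, grm$thresholds,
                          matrix(c(1, rho, rho, 1), 2, 2),
                          surrogate = grm$surrogate)
  flags <- seq_len(n_obs) %in% sample(n_obs, round(proportion * n_obs))
  list(model2 = model2, flags = flags, rho = rho)
}

#' Simulation condition specification
#'
#' Defaults reproduce the baseline design: 75 respondents by 60 occasions
#' of 10 seven-point items, 10% C/IER split half-and-half between uniform
#' random responding and the category-preference GRM, surrogate empirical
#' generating parameters (two negatively worded items, low heterogeneity),
#' no measurement-model violations, and equal 1-hour spacing.
#'
#' @param n_respondents,n_occasions,n_items,n_categories design size.
#' @param cier_rate true C/IER rate (observations are flagged iid).
#' @param patterns named numeric vector of C/IER pattern proportions
#'   (names among `"uniform"`, `"midpoint"`, `"straightlining"`, `"grm"`;
#'   must sum to 1).
#' @param heterogeneity `"low"` or `"high"` threshold heterogeneity.
#' @param n_negative number of negatively worded items (`NA` = keep the
#'   surrogate's own two, 0 = all positive, `k` = flip `k` random items).
#' @param decay_d,decay_items loading-decay severity and affected-item count.
#' @param two_factor_prop,rho proportion of attentive observations following
#'   a two-factor model, and the factor correlation.
#' @param spacing_hours interval between consecutive occasions.
#' @param seed master seed of the condition.
#' @return List of class `condition_spec`.
#' @export
condition_spec <- function(n_respondents = 75, n_occasions = 60,
                           n_items = 10, n_categories = 7,
                           cier_rate = 0.10,
                           patterns = c(uniform = 0.5, grm = 0.5),
                           heterogeneity = "low", n_negative = NA,
                           decay_d = 1, decay_items = 0,
                           two_factor_prop = 0, rho = 1,
                           spacing_hours = 1, seed = 1) {
  if (abs(sum(patterns) - 1) > 1e-8) stop("pattern proportions must sum to 1")
  stopifnot(cier_rate >= 0, cier_rate <= 1, decay_d > 0, decay_d <= 1)
  structure(as.list(environment()), class = "condition_spec")
}

#' Generate a full simulation-condition dataset with ground truth
#'
#' Applies the condition's questionnaire manipulations to the surrogate
#' generating parameters, flags an iid `cier_rate` share of the `N x T`
#' observations as C/IER, fills them from the condition's pattern mix, and
#' generates the remaining observations from the (possibly
#' occasion-varying or two-factor) attentive model. Occasions are
#' timestamped at equal spacing. Pure function of (spec, seed).
#'
#' @param spec a [condition_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return List with `data` (an [ema_dataset()]), `truth` (one record per
#'   observation: true state and generating pattern), and `params`
#'   (generating models and manipulation records).
#' @export
generate_condition <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "condition_spec"))
  if (is.null(seed)) seed <- spec$seed
  N <- spec$n_respondents; Tocc <- spec$n_occasions
  J <- spec$n_items; G <- spec$n_categories - 1L
  n <- N * Tocc

  base <- default_attentive_grm()
  if (J != 10L || G != 6L)
    stop("the surrogate generating model is defined for 10 items, 7 categories")
  set.seed(derive_seed(seed, 1L))  # item-selection sub-seed, logged in params
  grm <- apply_heterogeneity(base, spec$heterogeneity, spec$n_negative)
  decay <- if (spec$decay_d < 1 && spec$decay_items > 0)
    apply_loading_decay(grm, spec$decay_d, spec$decay_items, Tocc) else NULL

  set.seed(derive_seed(seed, 2L))
  state_cier <- rbinom(n, 1L, spec$cier_rate) == 1L
  pattern <- rep(NA_character_, n)
  idx_cier <- which(state_cier)
  if (length(idx_cier)) {
    labs <- names(spec$patterns)
    pattern[idx_cier] <- labs[sample.int(length(labs), length(idx_cier),
                                         replace = TRUE, prob = spec$patterns)]
  }
  twof <- NULL
  if (spec$two_factor_prop > 0) {
    att_idx <- which(!state_cier)
    twof <- apply_two_factor(grm, spec$two_factor_prop, spec$rho,
                             length(att_idx))
  }

  occ <- rep(seq_len(Tocc), N)
  rid <- rep(seq_len(N), each = Tocc)
  Y <- matrix(NA_integer_, n, J)

  set.seed(derive_seed(seed, 3L))
  # attentive observations
  att_idx <- which(!state_cier)
  flags2 <- if (is.null(twof)) rep(FALSE, length(att_idx)) else twof$flags
  uni_idx <- att_idx[!flags2]
  if (length(uni_idx)) {
    if (is.null(decay)) {
      Y[uni_idx, ] <- simulate_attentive(grm, length(uni_idx))
    } else {
      for (t in seq_len(Tocc)) {
        rows <- uni_idx[occ[uni_idx] == t]
        if (!length(rows)) next
        gt <- attentive_grm(matrix(decay$loadings[t, ], ncol = 1),
                            grm$thresholds)
        Y[rows, ] <- simulate_attentive(gt, length(rows))
      }
    }
  }
  two_idx <- att_idx[flags2]
  if (length(two_idx))
    Y[two_idx, ] <- simulate_attentive(twof$model2, length(two_idx))
  # C/IER observations
  for (lab in unique(pattern[!is.na(pattern)])) {
    rows <- which(!is.na(pattern) & pattern == lab)
    Y[rows, ] <- simulate_cier(lab, length(rows), J, spec$n_categories)
  }

  df <- data.frame(id = rid, occasion = occ,
                   time_hours = (occ - 1) * spec$spacing_hours)
  for (j in seq_len(J)) df[[paste0("item_", j)]] <- Y[, j]
  data <- ema_dataset(df, items = paste0("item_", seq_len(J)),
                      n_categories = spec$n_categories)
  truth <- data.frame(id = rid, occasion = occ,
                      state = ifelse(state_cier, "cier", "attentive"),
                      pattern = pattern,
                      two_factor = seq_len(n) %in%
                        (if (is.null(twof)) integer() else
                           which(!state_cier)[twof$flags]))
  list(data = data, truth = truth,
       params = list(attentive = grm, cier = default_cier_grm(),
                     decay = decay,
                     two_factor = if (is.null(twof)) NULL else
                       twof[c("rho", "model2")],
                     manipulation = attr(grm, "manipulation"),
                     seed = seed))
}

#' Simulate a covariate-driven latent Markov dataset
#'
#' Per respondent: initial state from the initial-state logit, subsequent
#' states through the interval transition probabilities implied by the
#' covariate-dependent intensities, item responses from the active state's
#' measurement model, and (optionally) error-prone modal assignments drawn
#' through a classification-error matrix. Intervals may be fixed or drawn
#' uniformly between 1 and 3 hours to exercise the continuous-time
#' machinery.
#'
#' @param model a [transition_model()] holding the generating parameters.
#' @param n_respondents,n_occasions design size.
#' @param covariate_gen `NULL`, or a function `(n_respondents, n_occasions)`
#'   returning a data.frame with one row per respondent-by-occasion
#'   observation (respondent-major order) and one column per covariate.
#' @param intervals `"fixed"` (1 h) or `"uniform"` (1-3 h).
#' @param attentive,cier measurement models for response generation.
#' @param error_matrix 2 x 2 matrix used to corrupt the true states into
#'   manifest assignments (identity = perfect measurement).
#' @param seed integer seed.
#' @return List with `data` (an [ema_dataset()] including covariates),
#'   `states` (true state per observation, 1/2), and `assignments`
#'   (error-prone manifest states).
#' @export
simulate_markov_dataset <- function(model, n_respondents, n_occasions,
                                    covariate_gen = NULL,
                                    intervals = c("fixed", "uniform"),
                                    attentive = default_attentive_grm(),
                                    cier = default_cier_grm(),
                                    error_matrix = diag(2), seed = 1) {
  intervals <- match.arg(intervals)
  set.seed(seed)
  N <- n_respondents; Tocc <- n_occasions; n <- N * Tocc
  Z <- if (is.null(covariate_gen)) NULL else covariate_gen(N, Tocc)
  if (!is.null(Z)) stopifnot(nrow(Z) == n)
  occ <- rep(seq_len(Tocc), N); rid <- rep(seq_len(N), each = Tocc)
  delta <- if (intervals == "fixed") rep(1, n) else runif(n, 1, 3)
  time <- as.vector(vapply(seq_len(N), function(i) {
    d <- delta[rid == i]; cumsum(c(0, d[-1]))
  }, numeric(Tocc)))

  zrow <- function(r) if (is.null(Z)) numeric() else unlist(Z[r, , drop = TRUE])
  states <- integer(n)
  for (t in seq_len(Tocc)) {
    rows <- which(occ == t)
    if (t == 1) {
      p2 <- vapply(rows, function(r)
        initial_state_probs(model, zrow(r))[2], numeric(1))
      states[rows] <- 1L + (runif(N) < p2)
    } else {
      prev <- states[rows - 1L]
      pmove <- vapply(seq_along(rows), function(k) {
        P <- transition_prob_matrix(intensity_matrix(model, zrow(rows[k])),
                                    time[rows[k]] - time[rows[k] - 1L])
        P[prev[k], 3L - prev[k]]
      }, numeric(1))
      move <- runif(N) < pmove
      states[rows] <- ifelse(move, 3L - prev, prev)
    }
  }

  J <- attentive$n_items
  Y <- matrix(NA_integer_, n, J)
  ia <- which(states == 1L); ic <- which(states == 2L)
  if (length(ia)) Y[ia, ] <- simulate_attentive(attentive, length(ia))
  if (length(ic)) Y[ic, ] <- simulate_cier("grm", length(ic), J,
                                           attentive$n_thresholds + 1L,
                                           model = cier)
  flip <- runif(n) < error_matrix[cbind(states, 3L - states)]
  w <- ifelse(flip, 3L - states, states)

  df <- data.frame(id = rid, occasion = occ, time_hours = time)
  for (j in seq_len(J)) df[[paste0("item_", j)]] <- Y[, j]
  if (!is.null(Z)) df <- cbind(df, Z)
  data <- ema_dataset(df, items = paste0("item_", seq_len(J)),
                      covariates = if (is.null(Z)) character() else names(Z),
                      n_categories = attentive$n_thresholds + 1L)
  list(data = data, states = states, assignments = as.integer(w))
}
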