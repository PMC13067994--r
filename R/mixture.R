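#' Estimation settings for the step-1 mixture fit
#'
#' @param n_starts number of random start-value sets (default 10).
#' @param stage_iters EM burn-in iterations run for every start before the
#'   best candidates continue (multi-start staging; set `>= max_iter` to run
#'   every start to convergence).
#' @param n_final maximum number of best-burn-in starts run to full
#'   convergence.
#' @param stage_margin only starts whose burn-in log-likelihood is within
#'   this margin of the best burn-in solution are continued (up to
#'   `n_final`); clearly dominated starts are dropped.
#' @param max_iter EM iteration cap (default 1000).
#' @param tol_param convergence threshold on the maximum absolute parameter
#'   change between iterations (default 1e-4).
#' @param tol_loglik convergence threshold on the log-likelihood change
#'   between iterations (default 1e-4, the customary EM default of standard
#'   marginal-ML IRT engines; EM stops when either threshold is met).
#' @param n_quad,quad_range quadrature nodes and half-range, see
#'   [quadrature_grid()].
#' @param sigma_max upper bound on \eqn{\sigma_\xi} (so
#'   \eqn{\sigma^2_\xi \le} `sigma_max^2`); estimates at the bound are
#'   flagged as straightlining-degenerate.
#' @param wording optional length-`J` sign vector (+1/-1) declaring item
#'   wording; start-value loading signs are drawn from it, or at random when
#'   `NULL`.
#' @param seed integer seed for the start-value schedule.
#' @return List of settings.
#' @export
estimation_settings <- function(n_starts = 10, stage_iters = 15, n_final = 2,
                                stage_margin = 25, max_iter = 1000,
                                tol_param = 1e-4, tol_loglik = 1e-4,
                                n_quad = 61, quad_range = 6, sigma_max = 10,
                                wording = NULL, seed = 1) {
  list(n_starts = n_starts, stage_iters = stage_iters,
       n_final = max(1L, min(n_final, n_starts)),
       stage_margin = stage_margin, max_iter = max_iter,
       tol_param = tol_param, tol_loglik = tol_loglik, n_quad = n_quad,
       quad_range = quad_range, sigma_max = sigma_max, wording = wording,
       seed = seed)
}

#' Random start-value schedule for the mixture EM
#'
#' Reproducible given the seed: loading magnitudes uniform on (0.5, 2.5)
#' with signs from the declared wording vector (random if undeclared),
#' thresholds as sorted standard-normal draws rescaled to span about
#' \eqn{\pm 2.5}, mixing proportion uniform on (0.05, 0.30) and
#' \eqn{\sigma^2_\xi} uniform on (0.25, 4).
#'
#' @param settings an [estimation_settings()] list.
#' @param n_items,n_thresholds dimensions `J` and `G`.
#' @param seed overrides `settings$seed` when given.
#' @return List of start sets, each with elements `attentive`, `cier`, `pi2`.
#' @export
multi_start_schedule <- function(settings, n_items, n_thresholds,
                                 seed = NULL) {
  if (is.null(seed)) seed <- settings$seed
  set.seed(seed)
  sorted_thresholds <- function(G) {
    v <- sort(rnorm(G), decreasing = TRUE)
    v <- v / max(abs(v), 0.5) * 2.5
    while (any(diff(v) >= -1e-6)) v <- v - cumsum(c(0, diff(v) >= -1e-6)) * 0.05
    v
  }
  lapply(seq_len(settings$n_starts), function(s) {
    magn <- runif(n_items, 0.5, 2.5)
    signs <- if (is.null(settings$wording)) sample(c(-1, 1), n_items, TRUE)
             else sign(settings$wording)
    thr <- t(vapply(seq_len(n_items), function(j) sorted_thresholds(n_thresholds),
                    numeric(n_thresholds)))
    list(attentive = attentive_grm(matrix(magn * signs, ncol = 1), thr),
         cier = cier_grm(sorted_thresholds(n_thresholds),
                         sigma2_xi = runif(1, 0.25, 4)),
         pi2 = runif(1, 0.05, 0.30))
  })
}

# --- internal EM machinery -------------------------------------------------

# Ordered-threshold parameterization: p = (k1, u2..uG), kappa = k1 - cumsum(exp(u)).
kappa_to_par <- function(kappa) {
  c(kappa[1], log(pmax(-diff(kappa), 1e-6)))
}
par_to_kappa <- function(p) {
  p[1] - c(0, cumsum(exp(p[-1])))
}

# Negative expected complete-data log-likelihood for one GRM item given
# expected counts r ((G+1) x Q) at the quadrature nodes (compiled, with
# analytic gradient).
item_negQ <- function(par, r, nodes) {
  .item_negQ(par, r, nodes, FALSE)[1]
}
item_negQ_grad <- function(par, r, nodes) {
  .item_negQ(par, r, nodes, TRUE)[-1]
}

mstep_item <- function(par0, r, nodes, lower1 = -30, upper1 = 30) {
  G <- length(par0) - 1L
  fit <- nlminb(par0, item_negQ, gradient = item_negQ_grad,
                r = r, nodes = nodes,
                lower = c(lower1, -30, rep(-12, G - 1)),
                upper = c(upper1, 30, rep(4, G - 1)),
                control = list(iter.max = 30))
  if (item_negQ(fit$par, r, nodes) <= item_negQ(par0, r, nodes)) fit$par else par0
}

flatten_pars <- function(att, cier, pi2) {
  c(att$loadings[, 1], as.vector(att$thresholds), sqrt(cier$sigma2_xi),
    cier$thresholds, pi2)
}

# Full EM run from one start; expected category counts at the quadrature
# nodes come from the compiled E-step. Returns parameters, trace, status.
em_run <- function(start, Y, quad, settings, max_iter,
                   check_convergence = TRUE) {
  J <- ncol(Y)
  nodes <- quad$nodes; logw <- log(quad$weights)
  att <- start$attentive; cier <- start$cier; pi2 <- start$pi2
  trace <- numeric(0)
  converged <- FALSE
  prev_par <- flatten_pars(att, cier, pi2)
  prev_ll <- -Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- .mixture_estep(Y, lapply(log_prob_tables(att, nodes), t),
                         t(log_prob_tables(cier, nodes)[[1]]), logw,
                         log(max(1 - pi2, 1e-300)), log(max(pi2, 1e-300)))
    ll <- es$loglik
    trace <- c(trace, ll)
    new_att_load <- att$loadings
    new_att_thr <- att$thresholds
    for (j in seq_len(J)) {
      p0 <- c(att$loadings[j, 1], kappa_to_par(att$thresholds[j, ]))
      pj <- mstep_item(p0, t(es$r_att[[j]]), nodes)
      new_att_load[j, 1] <- pj[1]
      new_att_thr[j, ] <- par_to_kappa(pj[-1])
    }
    p0 <- c(sqrt(cier$sigma2_xi), kappa_to_par(cier$thresholds))
    pc <- mstep_item(p0, t(es$r_cier), nodes, lower1 = 0,
                     upper1 = settings$sigma_max)
    att <- attentive_grm(new_att_load, new_att_thr)
    cier <- cier_grm(par_to_kappa(pc[-1]), sigma2_xi = pc[1]^2)
    pi2 <- mean(es$p2)
    cur_par <- flatten_pars(att, cier, pi2)
    dpar <- max(abs(cur_par - prev_par))
    dll <- ll - prev_ll
    prev_par <- cur_par; prev_ll <- ll
    if (check_convergence &&
        (dpar < settings$tol_param || abs(dll) < settings$tol_loglik)) {
      converged <- TRUE
      break
    }
  }
  sigma_flag <- sqrt(cier$sigma2_xi) >= settings$sigma_max - 1e-8
  list(attentive = att, cier = cier, pi2 = pi2, loglik = prev_ll,
       trace = trace, n_iter = it, converged = converged,
       sigma_at_bound = sigma_flag)
}

#' Fit the two-component attentive/C-IER mixture (step 1)
#'
#' Marginal maximum-likelihood estimation of the confirmatory mixture over
#' all respondent-by-occasion observations treated as independent. Each
#' observation's likelihood is \eqn{(1-\pi_2) L_{att}(y) + \pi_2
#' L_{cier}(y)} with component marginals integrated over the latent traits
#' by quadrature. Estimation uses EM with expected category counts at the
#' quadrature nodes and ordered-threshold transforms, run from multiple
#' random starts; the best log-likelihood solution is returned.
#'
#' @param data an [ema_dataset()].
#' @param settings an [estimation_settings()] list.
#' @return An object of class `mixture_fit`: component parameter objects,
#'   mixing proportion `pi2`, per-observation posterior matrix, final
#'   log-likelihood and trace, convergence flag, iteration count, index of
#'   the best start and the number of finished starts replicating the best
#'   log-likelihood (within 0.01).
#' @export
fit_mixture <- function(data, settings = estimation_settings()) {
  stopifnot(inherits(data, "ema_dataset"))
  if (data$n_items < 2) stop("at least 2 items are required")
  Y <- response_matrix(data)
  G <- data$n_categories - 1L
  if (G < 1) stop("at least 2 response categories are required")
  quad <- quadrature_grid(settings$n_quad, settings$quad_range)
  starts <- multi_start_schedule(settings, data$n_items, G)

  stage <- lapply(seq_along(starts), function(s)
    em_run(starts[[s]], Y, quad, settings,
           max_iter = min(settings$stage_iters, settings$max_iter),
           check_convergence = FALSE))
  ll_stage <- vapply(stage, `[[`, numeric(1), "loglik")
  if (all(!is.finite(ll_stage)))
    stop("all starts yielded a non-finite log-likelihood")
  keep <- order(ll_stage, decreasing = TRUE)[seq_len(settings$n_final)]
  keep <- keep[ll_stage[keep] >= max(ll_stage) - settings$stage_margin]

  finals <- lapply(keep, function(s) {
    res <- em_run(list(attentive = stage[[s]]$attentive,
                       cier = stage[[s]]$cier, pi2 = stage[[s]]$pi2),
                  Y, quad, settings,
                  max_iter = max(1L, settings$max_iter - stage[[s]]$n_iter))
    res$trace <- c(stage[[s]]$trace, res$trace)
    res$n_iter <- res$n_iter + stage[[s]]$n_iter
    res$start_index <- s
    res
  })
  ll_final <- vapply(finals, `[[`, numeric(1), "loglik")
  best <- finals[[which.max(ll_final)]]
  n_replicated <- sum(ll_final >= max(ll_final) - 0.01)

  post <- mixture_posteriors(best$attentive, best$cier, best$pi2, Y, quad)
  if (best$pi2 < 1e-4 || best$pi2 > 1 - 1e-4)
    warning("mixing proportion at boundary (pi2 = ",
            signif(best$pi2, 3), ")")
  structure(list(
    attentive = best$attentive, cier = best$cier, pi2 = best$pi2,
    posterior = post, loglik = best$loglik, loglik_trace = best$trace,
    converged = best$converged, n_iter = best$n_iter,
    best_start = best$start_index, n_replicated = n_replicated,
    sigma_at_bound = best$sigma_at_bound,
    settings = settings), class = "mixture_fit")
}

mixture_posteriors <- function(att, cier, pi2, Y, quad) {
  logw <- log(quad$weights)
  la <- log_sum_exp_rows(sweep(component_loglik_matrix(att, Y, quad$nodes),
                               2L, logw, "+"))
  lc <- log_sum_exp_rows(sweep(component_loglik_matrix(cier, Y, quad$nodes),
                               2L, logw, "+"))
  l1 <- log(max(1 - pi2, 1e-300)) + la
  l2 <- log(max(pi2, 1e-300)) + lc
  m <- pmax(l1, l2)
  denom <- m + log(exp(l1 - m) + exp(l2 - m))
  cbind(p_attentive = exp(l1 - denom), p_cier = exp(l2 - denom))
}

#' Posterior state probabilities under a fitted mixture
#'
#' Bayes rule per observation:
#' \eqn{P(\mathrm{C/IER} \mid y) = \pi_2 L_{cier}(y) / [(1-\pi_2)
#' L_{att}(y) + \pi_2 L_{cier}(y)]}.
#'
#' @param fit a `mixture_fit`.
#' @param data an [ema_dataset()] (defaults to recomputing nothing and
#'   returning the posteriors stored in the fit).
#' @return `n x 2` matrix with columns `p_attentive`, `p_cier`, rows sum to 1.
#' @export
posterior_state_probs <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (is.null(data)) return(fit$posterior)
  quad <- quadrature_grid(fit$settings$n_quad, fit$settings$quad_range)
  mixture_posteriors(fit$attentive, fit$cier, fit$pi2,
                     response_matrix(data), quad)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "mixture_fit: pi2 = %.4f, logLik = %.2f, %sconverged in %d iterations\n",
    "best start %d, best log-likelihood replicated by %d finished start(s)\n"),
    x$pi2, x$loglik, if (x$converged) "" else "NOT ", x$n_iter,
    x$best_start, x$n_replicated))
  if (isTRUE(x$sigma_at_bound))
    cat("note: sigma_xi at its upper bound (straightlining-degenerate)\n")
  invisible(x)
}
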