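#' Score one simulation replication
#'
#' Computes the evaluation metrics of the simulation designs from the
#' planted truth, the step-1 fit and the modal assignments. Sensitivity and
#' specificity follow the harness's literal definitions — sensitivity =
#' TP / (TP + FP), the proportion of correctly identified C/IER
#' observations out of all observations *classified* as C/IER, and
#' specificity = TN / (TN + FN) — with the conventional recall
#' (TP / (TP + FN)) and true-negative rate (TN / (TN + FP)) reported as
#' secondary outputs. Mean posterior C/IER probabilities are reported for
#' the four confusion cells.
#'
#' @param truth character or logical vector: `"cier"`/`TRUE` for true C/IER
#'   observations, aligned with the fit's observations.
#' @param fit a `mixture_fit`.
#' @param assignments integer modal assignments (1/2); computed from the
#'   fit's posteriors if missing.
#' @return One-row data.frame of class `replication_metrics`.
#' @export
score_replication <- function(truth, fit, assignments = NULL) {
  if (is.null(assignments)) assignments <- modal_assign(fit$posterior)
  truth_cier <- if (is.logical(truth)) truth else truth == "cier"
  stopifnot(length(truth_cier) == length(assignments))
  assigned_cier <- assignments == 2L
  p2 <- fit$posterior[, 2]
  tp <- truth_cier & assigned_cier
  tn <- !truth_cier & !assigned_cier
  fp <- !truth_cier & assigned_cier
  fn <- truth_cier & !assigned_cier
  cellmean <- function(sel) if (any(sel)) mean(p2[sel]) else NA_real_
  out <- data.frame(
    converged = fit$converged,
    pi2 = fit$pi2,
    sensitivity = if (any(assigned_cier)) sum(tp) / sum(assigned_cier)
                  else NA_real_,
    specificity = if (any(!assigned_cier)) sum(tn) / sum(!assigned_cier)
                  else NA_real_,
    recall = if (any(truth_cier)) sum(tp) / sum(truth_cier) else NA_real_,
    tnr = if (any(!truth_cier)) sum(tn) / sum(!truth_cier) else NA_real_,
    post_tp = cellmean(tp), post_tn = cellmean(tn),
    post_fp = cellmean(fp), post_fn = cellmean(fn))
  class(out) <- c("replication_metrics", class(out))
  out
}

#' Run one simulation condition for several replications
#'
#' For each replication (counter-derived seed, so results do not depend on
#' execution order): generate the condition's dataset, fit the step-1
#' mixture, classify by modal assignment, and score against the truth.
#'
#' @param spec a [condition_spec()].
#' @param R number of replications.
#' @param seed master seed.
#' @param settings an [estimation_settings()] list; its wording vector is
#'   overridden per replication with the generating item signs (the
#'   questionnaire's wording is known to the analyst).
#' @return data.frame with one row per replication (plus the replication
#'   index and seed).
#' @export
run_condition <- function(spec, R = 10, seed = 1,
                          settings = estimation_settings()) {
  rows <- lapply(seq_len(R), function(r) {
    rep_seed <- derive_seed(seed, r)
    sim <- generate_condition(spec, seed = rep_seed)
    settings$wording <- sign(sim$params$attentive$loadings[, 1])
    settings$seed <- derive_seed(rep_seed, 1L, stream = 9L)
    fit <- fit_mixture(sim$data, settings)
    m <- score_replication(sim$truth$state, fit)
    cbind(replication = r, seed = rep_seed, m)
  })
  do.call(rbind, rows)
}

#' Summarize replications into one condition row
#'
#' Bias and SD of the estimated C/IER proportion and mean
#' sensitivity/specificity/posterior columns, computed over the converged
#' replications only; the convergence rate is converged / R.
#'
#' @param metrics data.frame from [run_condition()].
#' @param true_rate the data-generating C/IER rate (default 0.10).
#' @return One-row data.frame.
#' @export
summarize_condition <- function(metrics, true_rate = 0.10) {
  conv <- metrics[metrics$converged, , drop = FALSE]
  R <- nrow(metrics)
  mean_or_na <- function(v) if (nrow(conv)) mean(v, na.rm = TRUE) else NA_real_
  data.frame(
    R = R,
    conv = nrow(conv) / R,
    bias_pi2 = mean_or_na(conv$pi2) - true_rate,
    sd_pi2 = if (nrow(conv) > 1) sd(conv$pi2) else NA_real_,
    sensitivity = mean_or_na(conv$sensitivity),
    specificity = mean_or_na(conv$specificity),
    post_tp = mean_or_na(conv$post_tp), post_tn = mean_or_na(conv$post_tn),
    post_fp = mean_or_na(conv$post_fp), post_fn = mean_or_na(conv$post_fn))
}

study_grid <- function(study) {
  base <- list()
  if (study == "I") {
    g <- expand.grid(heterogeneity = c("low", "high"), n_negative = c(0, 2),
                     pattern = c("uniform", "midpoint", "straightlining"),
                     stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) {
      p <- stats::setNames(1, g$pattern[i])
      modifyList(base, list(heterogeneity = g$heterogeneity[i],
                            n_negative = g$n_negative[i], patterns = p,
                            label = sprintf("H=%s Jn=%d %s",
                                            g$heterogeneity[i],
                                            g$n_negative[i], g$pattern[i])))
    })
  } else if (study == "II") {
    g <- expand.grid(d = c(0.99, 0.98, 0.95), items = c(2, 5, 10))
    c(list(list(label = "baseline")),
      lapply(seq_len(nrow(g)), function(i)
        list(decay_d = g$d[i], decay_items = g$items[i],
             label = sprintf("d=%.2f Jd=%d", g$d[i], g$items[i]))))
  } else if (study == "III") {
    g <- expand.grid(rho = c(0.80, 0.60, 0.40), prop = c(0.20, 0.30, 0.50))
    c(list(list(label = "baseline")),
      lapply(seq_len(nrow(g)), function(i)
        list(rho = g$rho[i], two_factor_prop = g$prop[i],
             label = sprintf("rho=%.2f obs=%.2f", g$rho[i], g$prop[i]))))
  } else stop("study must be 'I', 'II' or 'III'")
}

#' Run a full simulation study grid
#'
#' Study I crosses item heterogeneity (low/high) and negatively worded
#' items (0/2) with three pure C/IER patterns; Study II adds loading decay
#' (d in 0.99/0.98/0.95 on 2/5/10 items) to the baseline mixed-pattern
#' design; Study III adds two-factor attentive structure (rho in
#' 0.80/0.60/0.40 for 20/30/50% of attentive observations). Returns one
#' summary row per condition.
#'
#' @param study `"I"`, `"II"` or `"III"`.
#' @param R replications per condition (default 10; 50 reproduces the
#'   original scale).
#' @param seed master seed.
#' @param settings an [estimation_settings()] list.
#' @param conditions optional integer subset of condition indices (e.g. to
#'   run a single condition).
#' @param overrides named list applied to every condition's
#'   [condition_spec()] call.
#' @return data.frame of condition summaries with a `condition` label.
#' @export
run_study <- function(study = c("I", "II", "III"), R = 10, seed = 1,
                      settings = estimation_settings(), conditions = NULL,
                      overrides = list()) {
  study <- match.arg(study)
  grid <- study_grid(study)
  if (!is.null(conditions)) grid <- grid[conditions]
  rows <- lapply(seq_along(grid), function(i) {
    cond <- grid[[i]]
    label <- cond$label
    cond$label <- NULL
    spec <- do.call(condition_spec, modifyList(cond, overrides))
    metrics <- run_condition(spec, R = R, seed = derive_seed(seed, i, 5L),
                             settings = settings)
    cbind(condition = label, summarize_condition(metrics, spec$cier_rate))
  })
  do.call(rbind, rows)
}
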