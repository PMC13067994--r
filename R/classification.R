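#' Modal state assignment (step 2)
#'
#' Assigns every observation to its most probable latent state. Ties
#' (posterior exactly 0.5) are broken toward the attentive state.
#'
#' @param posteriors `n x 2` matrix with columns attentive, C/IER (rows sum
#'   to 1), e.g. from [posterior_state_probs()].
#' @return Integer vector of assignments: 1 = attentive, 2 = C/IER.
#' @export
modal_assign <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  if (any(abs(rowSums(posteriors) - 1) > 1e-8))
    stop("posterior rows must sum to 1")
  ifelse(posteriors[, 2] > 0.5, 2L, 1L)
}

#' Classification-error matrix of modal assignment (step 2)
#'
#' The modal assignments are treated as error-prone manifest indicators of
#' the true latent states. The error matrix `D` has entries
#' \deqn{D[k, l] = \frac{\sum_i P(\mathrm{true}\ k \mid y_i)\,
#'   1[\mathrm{assigned}\ l]}{\sum_i P(\mathrm{true}\ k \mid y_i)},}
#' i.e. total-posterior-weighted misclassification rates. `D` is
#' row-stochastic; with all posteriors at 0/1 it is the identity. Zero
#' entries are floored at 1e-10 so step 3 can take logs.
#'
#' @param posteriors as in [modal_assign()].
#' @param assignments integer assignments derived from the same posteriors
#'   (computed if missing).
#' @return List with `D` (2 x 2 matrix, rows = true state, columns =
#'   assigned state), `error_probs` (per-state `1 - D[k, k]`), and the
#'   `assignments`.
#' @export
classification_error_matrix <- function(posteriors, assignments = NULL) {
  posteriors <- as.matrix(posteriors)
  if (is.null(assignments)) assignments <- modal_assign(posteriors)
  if (length(assignments) != nrow(posteriors))
    stop("assignments and posteriors are misaligned")
  mass <- colSums(posteriors)
  if (any(mass <= 0))
    stop("a state has zero total posterior mass; the mixture is degenerate")
  D <- matrix(0, 2, 2, dimnames = list(true = c("attentive", "cier"),
                                       assigned = c("attentive", "cier")))
  for (l in 1:2) {
    sel <- assignments == l
    D[, l] <- colSums(posteriors[sel, , drop = FALSE]) / mass
  }
  D <- pmax(D, 1e-10)
  D <- D / rowSums(D)
  list(D = D, error_probs = 1 - diag(D), assignments = assignments)
}

#' Run step 2 on a fitted mixture
#'
#' Convenience wrapper: modal assignment plus classification-error matrix
#' from a step-1 fit.
#'
#' @param fit a `mixture_fit`.
#' @return A `classification_result`: list with `assignments`, `D`,
#'   `error_probs` and the C/IER assignment rate.
#' @export
classify_observations <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  res <- classification_error_matrix(fit$posterior)
  structure(list(assignments = res$assignments, D = res$D,
                 error_probs = res$error_probs,
                 cier_rate = mean(res$assignments == 2L)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("classification_result: %.1f%% assigned C/IER\n",
              100 * x$cier_rate))
  cat(sprintf("classification error: attentive %.3f, C/IER %.3f\n",
              x$error_probs[1], x$error_probs[2]))
  invisible(x)
}
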