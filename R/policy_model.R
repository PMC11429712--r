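#' Smooth action values across neighbouring contrast levels
#'
#' Applies a triangular kernel (w, 1 - 2w, w) over contrast-adjacent states
#' to each action column of Q, capturing a small amount of state
#' (stimulus) uncertainty. Edge states renormalise over their available
#' neighbours. `w = 0` is the identity.
#'
#' @param q States x actions matrix, rows ordered by signed contrast.
#' @param weight Kernel weight w in \[0, 0.5).
#' @return Smoothed matrix of the same shape.
#' @export
smooth_values <- function(q, weight = 0.25) {
  if (weight < 0 || weight >= 0.5) stop("`weight` must be in [0, 0.5)")
  if (weight == 0) return(q)
  q <- as.matrix(q)
  n <- nrow(q)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    k[i, i] <- 1 - 2 * weight
    if (i > 1) k[i, i - 1] <- weight
    if (i < n) k[i, i + 1] <- weight
  }
  k <- k / rowSums(k)
  k %*% q
}

#' Capacity-limited optimal policy given values and an action marginal
#'
#' The optimal policy under a constraint on policy complexity is
#' `P(a|s) = P(a) exp[beta Q(s,a)] / sum_a' P(a') exp[beta Q(s,a')]`:
#' a softmax over action values tilted towards high-marginal-probability
#' (frequent) actions. Low beta yields compressed, perseverative policies;
#' high beta yields reward-maximising ones.
#'
#' @param q States x actions expected-reward matrix.
#' @param marginal Strictly positive action marginal P(a) (length 2).
#' @param beta Inverse temperature >= 0.
#' @return A [new_policy()] object (marginal stored as supplied; state
#'   distribution uniform unless given via `state_probs`).
#' @param state_probs Optional P(s); default uniform.
#' @examples
#' q <- rbind(c(1, 0), c(0, 1))
#' optimal_policy(q, marginal = c(0.5, 0.5), beta = 1)$cond
#' @export
optimal_policy <- function(q, marginal, beta, state_probs = NULL) {
  q <- as.matrix(q)
  if (beta < 0) stop("`beta` must be >= 0")
  if (any(marginal <= 0)) stop("`marginal` entries must be strictly positive")
  marginal <- marginal / sum(marginal)
  if (is.null(state_probs)) state_probs <- rep(1 / nrow(q), nrow(q))
  z <- sweep(beta * q, 2, log(marginal), "+")
  z <- z - apply(z, 1, max)              # max-subtraction for stability
  ez <- exp(z)
  new_policy(ez / rowSums(ez), state_probs = state_probs, marginal = marginal)
}

#' Empirical action-value table for a session
#'
#' Q(s,a) as the mean delivered reward per (state, action) cell of the
#' session, with cells never visited filled from the task's programmed
#' (block-averaged) expected rewards.
#'
#' @param trials One session's trial table.
#' @param task The [make_task()] object.
#' @return A states x actions matrix.
#' @export
empirical_q <- function(trials, task) {
  n_states <- task$n_states
  a <- match(trials$action, task$actions)
  s <- as.integer(trials$state_index) + 1L
  q <- true_q(task, "average")
  for (i in seq_len(n_states)) for (j in 1:2) {
    sel <- s == i & a == j
    if (any(sel)) q[i, j] <- mean(trials$reward[sel])
  }
  q
}

#' Fit the capacity-limited policy to a session's choices
#'
#' Maximum-likelihood fit of the inverse temperature beta in
#' `P(a|s) ∝ P(a) exp[beta Q(s,a)]`. The action marginal (the session's
#' choice bias) is plugged in from the empirical choice frequencies rather
#' than optimised, so beta is the single free parameter; a bias-free
#' variant fixes the marginal at (0.5, 0.5). The summed log-likelihood is
#' concave in beta, so a bounded golden-section search cannot be trapped.
#'
#' @param trials Trial table for one session.
#' @param task The [make_task()] the trials came from; used to fill Q cells
#'   never visited. Required unless `q` is supplied.
#' @param q Optional states x actions value matrix; default the smoothed
#'   empirical per-(s,a) mean reward (see Details).
#' @param smoothing_w Triangular smoothing weight passed to
#'   [smooth_values()] (default 0.25); applied only when `q` is not given.
#' @param include_bias Use the session's empirical marginal (TRUE, default)
#'   or the unbiased marginal (0.5, 0.5).
#' @param beta_max Upper bound of the search interval (default 50).
#' @param k Parameter count for the BIC; default 2 when `include_bias`
#'   (beta plus the plug-in bias), 1 otherwise.
#' @return An object of class `policy_fit` with elements `beta_hat`, `bias`
#'   (fitted marginal P(right)), `loglik`, `bic`, `n_trials`, `q_used`,
#'   `marginal`, `include_bias`, `task`.
#' @examples
#' task <- make_task()
#' tr <- generate_session(task, beta = 2, bias = 0.6, n_trials = 1000, seed = 2)
#' fit <- fit_policy(tr, task)
#' coef(fit)
#' @export
fit_policy <- function(trials, task = NULL, q = NULL, smoothing_w = 0.25,
                       include_bias = TRUE, beta_max = 50,
                       k = if (include_bias) 2L else 1L) {
  if (nrow(trials) == 0L) stop("empty trial table")
  if (is.null(q)) {
    if (is.null(task)) stop("supply either `task` or `q`")
    q <- smooth_values(empirical_q(trials, task), smoothing_w)
  }
  q <- as.matrix(q)
  if (any(!is.finite(q))) stop("`q` must be finite")
  n <- nrow(trials)
  a <- match(trials$action, c("left", "right"))
  s <- as.integer(trials$state_index) + 1L
  if (include_bias) {
    p_right <- mean(a == 2L)
    eps <- 1 / (2 * n)
    if (p_right <= 0 || p_right >= 1) {
      warning("all trials chose one action; bias clipped away from {0, 1}")
      p_right <- min(max(p_right, eps), 1 - eps)
    }
    marginal <- c(1 - p_right, p_right)
  } else {
    marginal <- c(0.5, 0.5)
  }
  negll <- function(beta) {
    pol <- optimal_policy(q, marginal, beta)
    -sum(log(pol$cond[cbind(s, a)]))
  }
  opt <- stats::optimize(negll, interval = c(0, beta_max), tol = 1e-8)
  # the bound beta = 0 can beat the interior optimum when choices are flat
  beta_hat <- if (negll(0) <= opt$objective) 0 else opt$minimum
  ll <- -negll(beta_hat)
  structure(list(beta_hat = beta_hat,
                 bias = marginal[2L],
                 marginal = marginal,
                 loglik = ll,
                 bic = k * log(n) - 2 * ll,
                 k = k,
                 n_trials = n,
                 q_used = q,
                 include_bias = include_bias,
                 task = task),
            class = "policy_fit")
}

#' @export
print.policy_fit <- function(x, ...) {
  cat("Capacity-limited policy fit (", x$n_trials, " trials)\n", sep = "")
  cat(sprintf("  beta_hat = %.4f   bias P(right) = %.4f%s\n", x$beta_hat,
              x$bias, if (x$include_bias) "" else " (fixed)"))
  cat(sprintf("  logLik = %.3f   BIC = %.3f (k = %d)\n", x$loglik, x$bic, x$k))
  invisible(x)
}

#' @export
summary.policy_fit <- function(object, ...) {
  print(object)
  pol <- optimal_policy(object$q_used, object$marginal, object$beta_hat)
  cat(sprintf("  implied policy complexity = %.4f bits\n",
              mutual_information(pol)))
  invisible(object)
}

#' @export
coef.policy_fit <- function(object, ...) {
  c(beta = object$beta_hat, bias = object$bias)
}

#' @export
logLik.policy_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_trials,
            class = "logLik")
}

#' @export
BIC.policy_fit <- function(object, ...) object$bic

#' Predicted psychometric curve from a policy fit
#'
#' Evaluates the fitted capacity-limited policy over the task's contrast
#' levels, giving P(choose right | contrast). With a symmetric Q the curve
#' is symmetric about zero contrast; a bias above 0.5 shifts it upward at
#' every contrast; beta = 0 gives a flat curve at the bias.
#'
#' @param object A [fit_policy()] object.
#' @param task Task providing the contrast levels; defaults to the task
#'   stored in the fit.
#' @param ... Unused.
#' @return A data.frame with columns `contrast` and `p_right`.
#' @export
predict.policy_fit <- function(object, task = object$task, ...) {
  pol <- optimal_policy(object$q_used, object$marginal, object$beta_hat)
  contrast <- if (!is.null(task)) task$contrasts
              else seq_len(nrow(object$q_used))
  data.frame(contrast = contrast, p_right = unname(pol$cond[, 2L]))
}

#' @export
plot.policy_fit <- function(x, ...) {
  pr <- predict(x)
  graphics::plot(pr$contrast, pr$p_right, type = "b", ylim = c(0, 1),
                 xlab = "Signed contrast", ylab = "P(choose right)", ...)
  graphics::abline(h = x$bias, lty = 3)
  invisible(x)
}

#' @export
simulate.policy_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$task)) stop("fit carries no task; cannot simulate")
  lapply(seq_len(nsim), function(i) {
    generate_session(object$task, beta = object$beta_hat, bias = object$bias,
                     n_trials = object$n_trials,
                     seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
}

#' Psychometric prediction for arbitrary parameters
#'
#' Functional form of the fitted psychometric curve: P(choose right |
#' contrast) under the capacity-limited policy at the given beta and bias.
#'
#' @param fit A [fit_policy()] object.
#' @param task Optional [make_task()] object (defaults to the fit's task).
#' @return A data.frame with `contrast` and `p_right`.
#' @export
psychometric_prediction <- function(fit, task = fit$task) {
  predict(fit, task = task)
}

#' Compare the biased and bias-free capacity-limited policies by BIC
#'
#' Fits both variants to every session and returns
#' `delta_bic = BIC(bias-free) - BIC(with-bias)` summed over sessions
#' (positive values favour including the session-specific bias), along with
#' the same comparison on pooled trials.
#'
#' @param sessions A list of per-session trial tables, or a single trial
#'   table with a `session_id` column (split internally).
#' @param task The [make_task()] object.
#' @param smoothing_w Value-smoothing weight (default 0.25).
#' @return A list with `delta_bic` (summed over sessions), `per_session`
#'   data.frame (session, bic_bias, bic_nobias, beta_bias, beta_nobias)
#'   and `delta_bic_pooled` (single fit on all trials concatenated).
#' @export
compare_bias_models <- function(sessions, task, smoothing_w = 0.25) {
  if (is.data.frame(sessions))
    sessions <- split(sessions, sessions$session_id)
  if (length(sessions) < 1L) stop("need at least one session")
  per <- lapply(seq_along(sessions), function(i) {
    tr <- sessions[[i]]
    fb <- fit_policy(tr, task, smoothing_w = smoothing_w, include_bias = TRUE)
    f0 <- fit_policy(tr, task, smoothing_w = smoothing_w, include_bias = FALSE)
    data.frame(session = if (!is.null(tr$session_id)) tr$session_id[1] else i,
               beta_bias = fb$beta_hat, beta_nobias = f0$beta_hat,
               bic_bias = fb$bic, bic_nobias = f0$bic)
  })
  per <- do.call(rbind, per)
  pooled <- do.call(rbind, sessions)
  pb <- fit_policy(pooled, task, smoothing_w = smoothing_w, include_bias = TRUE)
  p0 <- fit_policy(pooled, task, smoothing_w = smoothing_w, include_bias = FALSE)
  list(delta_bic = sum(per$bic_nobias) - sum(per$bic_bias),
       per_session = per,
       delta_bic_pooled = p0$bic - pb$bic)
}
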