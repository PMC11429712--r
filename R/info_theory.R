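#' Construct a policy object
#'
#' A policy is the conditional distribution P(a|s) over the two actions in
#' each of the 9 stimulus states, together with the marginal action
#' distribution P(a) and the state distribution P(s).
#'
#' @param cond Numeric matrix of P(a|s), states x actions; rows must sum
#'   to 1 within 1e-10.
#' @param state_probs P(s), one entry per row of `cond`, summing to 1.
#' @param marginal P(a); if `NULL` it is computed self-consistently as
#'   `colSums(state_probs * cond)`.
#' @return An object of class `policy` with elements `cond`, `marginal`,
#'   `state_probs` and logical `self_consistent` (TRUE when `marginal`
#'   equals the state-weighted average of `cond` within 1e-10).
#' @export
new_policy <- function(cond, state_probs, marginal = NULL) {
  cond <- as.matrix(cond)
  if (ncol(cond) != 2L) stop("`cond` must have 2 action columns")
  if (length(state_probs) != nrow(cond))
    stop("`state_probs` length must match the number of states")
  if (any(abs(rowSums(cond) - 1) > 1e-10))
    stop("rows of `cond` must sum to 1")
  if (abs(sum(state_probs) - 1) > 1e-10 || any(state_probs < 0))
    stop("`state_probs` must be a probability vector")
  implied <- as.numeric(state_probs %*% cond)
  if (is.null(marginal)) marginal <- implied
  if (abs(sum(marginal) - 1) > 1e-10 || any(marginal < 0))
    stop("`marginal` must be a probability vector")
  if (is.null(colnames(cond)) || !all(nzchar(colnames(cond))))
    colnames(cond) <- c("left", "right")
  names(marginal) <- colnames(cond)
  structure(list(cond = cond,
                 marginal = marginal,
                 state_probs = as.numeric(state_probs),
                 self_consistent = max(abs(marginal - implied)) <= 1e-10),
            class = "policy")
}

#' @export
print.policy <- function(x, ...) {
  cat("Policy over", nrow(x$cond), "states x", ncol(x$cond), "actions\n")
  print(round(x$cond, 4))
  cat("marginal P(a):", paste(round(x$marginal, 4), collapse = " / "),
      if (x$self_consistent) "(self-consistent)" else "(from counts)", "\n")
  cat("complexity:", round(mutual_information(x), 4), "bits\n")
  invisible(x)
}

#' Estimate a policy from trial data
#'
#' Plug-in estimate of P(a|s), P(a) and P(s) from per-trial state/action
#' counts, with additive (pseudocount) smoothing. Distributions are intended
#' to be estimated separately for each session.
#'
#' @param trials A trial table (see [generate_session()]) with columns
#'   `state_index` (0-based, < `n_states`) and `action` (`"left"`/`"right"`).
#' @param pseudocount Additive smoothing constant alpha >= 0 applied to every
#'   state x action cell (default 1). With `pseudocount = 0`, states never
#'   visited get a uniform row and are flagged in the `unvisited` attribute.
#' @param n_states Number of stimulus states (default 9).
#' @return A [new_policy()] object. `state_probs` are empirical state
#'   frequencies; `marginal` comes from overall action counts (smoothed by
#'   `pseudocount` per action cell).
#' @examples
#' task <- make_task()
#' tr <- generate_session(task, beta = 2, bias = 0.6, n_trials = 500, seed = 1)
#' estimate_policy(tr)
#' @export
estimate_policy <- function(trials, pseudocount = 1, n_states = 9L) {
  if (nrow(trials) == 0L) stop("empty trial table")
  if (pseudocount < 0) stop("`pseudocount` must be >= 0")
  s <- as.integer(trials$state_index)
  if (any(s < 0L | s >= n_states)) stop("state_index out of range")
  a <- match(trials$action, c("left", "right"))
  if (anyNA(a)) stop("unknown action labels")
  counts <- matrix(0, n_states, 2L, dimnames = list(NULL, c("left", "right")))
  for (k in seq_along(s)) counts[s[k] + 1L, a[k]] <- counts[s[k] + 1L, a[k]] + 1
  unvisited <- rowSums(counts) == 0
  sm <- counts + pseudocount
  cond <- sm / rowSums(sm)
  if (pseudocount == 0 && any(unvisited)) cond[unvisited, ] <- 0.5
  n <- nrow(trials)
  marginal <- (colSums(counts) + pseudocount) / (n + 2 * pseudocount)
  pol <- new_policy(cond, state_probs = rowSums(counts) / n,
                    marginal = marginal)
  attr(pol, "counts") <- counts
  attr(pol, "pseudocount") <- pseudocount
  attr(pol, "unvisited") <- if (pseudocount == 0) which(unvisited) else integer(0)
  pol
}

#' Policy complexity: mutual information between states and actions
#'
#' I(S;A) = sum_s sum_a P(s) P(a|s) log2\[P(a|s) / P(a)\], with 0 log 0 := 0.
#' The marginal is recomputed self-consistently from `cond` and
#' `state_probs` before evaluation, so the result is a true mutual
#' information (non-negative, bounded by min(H(S), H(A))).
#'
#' @param policy A [new_policy()] object.
#' @return Policy complexity in bits.
#' @export
mutual_information <- function(policy) {
  p_s <- policy$state_probs
  cond <- policy$cond
  marg <- as.numeric(p_s %*% cond)
  joint <- p_s * cond                    # recycles p_s down columns
  terms <- joint * log2(sweep(cond, 2, marg, "/"))
  terms[joint == 0] <- 0
  sum(terms)
}

#' Per-trial policy cost
#'
#' The policy cost of taking action `a` in state `s` is
#' log\[P(a|s) / P(a)\] in nats: the information spent conditioning the
#' action on the state on that trial. Its state/action-frequency-weighted
#' average is the policy complexity.
#'
#' @param policy A [new_policy()] object.
#' @param state_index 0-based state index (vectorised).
#' @param action `"left"`/`"right"` labels or 1-based column indices
#'   (vectorised, recycled against `state_index`).
#' @return Numeric vector of costs in nats.
#' @examples
#' pol <- new_policy(rbind(c(.9, .1), c(.1, .9)), c(.5, .5))
#' policy_cost(pol, 0, "left")   # log(.9 / .5)
#' @export
policy_cost <- function(policy, state_index, action) {
  a <- if (is.numeric(action)) as.integer(action)
       else match(action, colnames(policy$cond))
  if (anyNA(a)) stop("unknown action")
  n <- max(length(state_index), length(a))
  s <- rep_len(as.integer(state_index), n) + 1L
  a <- rep_len(a, n)
  pa <- policy$marginal[a]
  if (any(pa <= 0)) stop("marginal probability is zero for a queried action")
  pas <- policy$cond[cbind(s, a)]
  if (any(pas == 0))
    stop("P(a|s) = 0 for an observed (state, action) pair; ",
         "use pseudocount smoothing when estimating the policy")
  unname(log(pas / pa))
}

#' Per-trial policy cost over a trial table
#'
#' Vectorised convenience wrapper producing the policy-cost regressor for
#' every trial in a table.
#'
#' @param policy A [new_policy()] object.
#' @param trials Trial table with `state_index` and `action` columns.
#' @return Numeric vector, one cost (nats) per trial.
#' @export
trial_costs <- function(policy, trials) {
  policy_cost(policy, trials$state_index, trials$action)
}

#' Optimal capacity-limited policy at a given trade-off beta
#'
#' Runs the Blahut-Arimoto alternating minimisation for the channel between
#' states and actions: repeat P(a|s) proportional to P(a) exp\[beta Q(s,a)\]
#' (row-normalised) and P(a) = sum_s P(s) P(a|s), from a uniform marginal,
#' until the marginal changes by less than `tol` in max-norm. The converged
#' policy attains the maximum expected reward at its policy complexity.
#'
#' @param q States x actions matrix Q(s,a) of expected rewards.
#' @param state_probs P(s).
#' @param beta Inverse temperature, >= 0.
#' @param tol Convergence tolerance on the marginal (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return A [new_policy()] object with attributes `complexity` (bits),
#'   `reward` (expected reward) and `iterations`.
#' @examples
#' task <- make_task()
#' pol <- blahut_arimoto(true_q(task), task$state_probs, beta = 2)
#' attr(pol, "complexity"); attr(pol, "reward")
#' @export
blahut_arimoto <- function(q, state_probs, beta, tol = 1e-10,
                           max_iter = 10000L) {
  q <- as.matrix(q)
  if (beta < 0) stop("`beta` must be >= 0")
  if (tol <= 0) stop("`tol` must be positive")
  marg <- rep(1 / ncol(q), ncol(q))
  bq <- beta * q
  bq <- bq - apply(bq, 1, max)           # stabilise exponentials
  ebq <- exp(bq)
  cond <- NULL
  for (it in seq_len(max_iter)) {
    w <- sweep(ebq, 2, marg, "*")
    cond <- w / rowSums(w)
    new_marg <- as.numeric(state_probs %*% cond)
    delta <- max(abs(new_marg - marg))
    marg <- new_marg
    if (delta < tol) {
      pol <- new_policy(cond, state_probs)
      attr(pol, "complexity") <- mutual_information(pol)
      attr(pol, "reward") <- sum(state_probs * rowSums(cond * q))
      attr(pol, "iterations") <- it
      return(pol)
    }
  }
  err <- simpleError(sprintf(
    "Blahut-Arimoto did not converge in %d iterations (last change %.3g)",
    max_iter, delta))
  err$last_policy <- new_policy(cond, state_probs)
  stop(err)
}

#' Optimal reward-complexity frontier
#'
#' Sweeps [blahut_arimoto()] over an ascending beta grid to trace the
#' maximum expected reward achievable at each level of policy complexity.
#' The beta = 0 endpoint is evaluated analytically: the best unconditional
#' policy earns `max_a sum_s P(s) Q(s,a)` at zero complexity. Points above
#' the frontier are unachievable.
#'
#' @param q States x actions expected-reward matrix.
#' @param state_probs P(s).
#' @param beta_grid Ascending grid of beta values; default 100 log-spaced
#'   points in \[0.01, 100\]. A 0 is prepended if absent.
#' @param ... Passed to [blahut_arimoto()].
#' @return An object of class `rc_frontier`: a data.frame with columns
#'   `beta`, `complexity` (bits), `reward`.
#' @export
frontier <- function(q, state_probs,
                     beta_grid = exp(seq(log(0.01), log(100), length.out = 100)),
                     ...) {
  if (is.unsorted(beta_grid)) stop("`beta_grid` must be ascending")
  if (any(beta_grid < 0)) stop("`beta_grid` must be non-negative")
  q <- as.matrix(q)
  pts <- lapply(beta_grid[beta_grid > 0], function(b) {
    pol <- blahut_arimoto(q, state_probs, b, ...)
    c(beta = b, complexity = attr(pol, "complexity"),
      reward = attr(pol, "reward"))
  })
  out <- as.data.frame(do.call(rbind, pts))
  # analytic zero-beta endpoint: best unconditional policy
  r0 <- max(as.numeric(state_probs %*% q))
  out <- rbind(data.frame(beta = 0, complexity = 0, reward = r0), out)
  # guard monotonicity against terminal-digit rounding
  out$complexity <- cummax(out$complexity)
  out$reward <- cummax(out$reward)
  class(out) <- c("rc_frontier", "data.frame")
  out
}

#' @export
print.rc_frontier <- function(x, ...) {
  cat("Reward-complexity frontier:", nrow(x), "points, beta in [",
      min(x$beta), ",", max(x$beta), "]\n")
  cat("  complexity range:", round(min(x$complexity), 4), "-",
      round(max(x$complexity), 4), "bits\n")
  cat("  reward range:    ", round(min(x$reward), 4), "-",
      round(max(x$reward), 4), "\n")
  invisible(x)
}

#' @export
plot.rc_frontier <- function(x, ...) {
  graphics::plot(x$complexity, x$reward, type = "l", col = "blue", lwd = 2,
                 xlab = "Policy complexity (bits)", ylab = "Average reward",
                 ...)
  invisible(x)
}

#' Vertical deviation of a (complexity, reward) point from the frontier
#'
#' Measures suboptimality as the reward gap to the frontier at matched
#' complexity, as a percentage of the optimal reward:
#' `100 * (R_opt(I) - R) / R_opt(I)`, with `R_opt(I)` linearly interpolated
#' on the frontier. Complexities outside the frontier's range are clamped to
#' the nearest endpoint. Negative values (points above the frontier, which
#' can arise from estimation noise) are returned as-is.
#'
#' @param complexity Policy complexity of the point (bits); vectorised.
#' @param reward Average reward of the point; vectorised.
#' @param front An [frontier()] object.
#' @return Percent deviation(s).
#' @export
frontier_deviation <- function(complexity, reward, front) {
  r_opt <- stats::approx(front$complexity, front$reward, xout = complexity,
                         rule = 2, ties = "ordered")$y
  if (any(r_opt <= 0)) stop("optimal reward at matched complexity is <= 0")
  100 * (r_opt - reward) / r_opt
}
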