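#' Cost-penalised reward prediction error
#'
#' The teaching signal of the compression-aware learner:
#' `delta = r - V - cost / beta`. The policy cost `log P(a|s)/P(a)` (nats)
#' is charged against the reward, so frequently-updated, state-specific
#' actions are penalised in proportion to the information they consume.
#' With `beta = 1` this is literally `r - V - log P(a|s)/P(a)`.
#'
#' @param r Reward outcome.
#' @param v Expected reward V.
#' @param cost Policy cost in nats.
#' @param beta Trade-off inverse temperature, > 0.
#' @return The prediction error delta (vectorised over the inputs).
#' @examples
#' rpe(1, 0.5, 0, beta = 1)            # 0.5
#' rpe(1, 0.5, log(1.8), beta = 1)     # about -0.0878
#' @export
rpe <- function(r, v, cost, beta = 1) {
  if (any(beta <= 0)) stop("`beta` must be > 0")
  r - v - cost / beta
}

#' Initialise a cost-penalised actor-critic agent
#'
#' The agent maintains state values `V(s)` (critic), policy preferences
#' `theta(s,a)` (actor) and a running estimate of its own marginal action
#' distribution. Its policy is `pi(a|s) ∝ exp[theta(s,a) + log P_hat(a)]`,
#' and all three components are updated from the cost-penalised prediction
#' error [rpe()], whose fixed point is the capacity-limited optimal policy
#' at the agent's `beta`.
#'
#' On a symmetric task the action marginal is a nearly neutral direction
#' of the learning dynamics (any tilt of the policy reproduces itself in
#' the actions the tracker sees, with a restoring gain of only a few
#' percent per update), so the marginal tracker must be slow relative to
#' the session or it random-walks; hence the small default
#' `alpha_marginal`.
#'
#' @param n_states Number of states (default 9).
#' @param beta Trade-off inverse temperature, > 0.
#' @param alpha_v,alpha_theta,alpha_marginal Learning rates in (0, 1] for
#'   the critic, the actor and the marginal tracker (defaults 0.1, 0.1,
#'   1e-4).
#' @return An object of class `agent_state` with elements `v`, `theta`,
#'   `marginal_hat`, `beta` and the learning rates.
#' @export
new_agent <- function(n_states = 9L, beta = 1,
                      alpha_v = 0.1, alpha_theta = 0.1,
                      alpha_marginal = 1e-4) {
  if (beta <= 0) stop("`beta` must be > 0")
  rates <- c(alpha_v, alpha_theta, alpha_marginal)
  if (any(rates <= 0) || any(rates > 1))
    stop("learning rates must be in (0, 1]")
  structure(list(v = numeric(n_states),
                 theta = matrix(0, n_states, 2L,
                                dimnames = list(NULL, c("left", "right"))),
                 marginal_hat = c(left = 0.5, right = 0.5),
                 beta = beta,
                 alpha_v = alpha_v, alpha_theta = alpha_theta,
                 alpha_marginal = alpha_marginal),
            class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat("Cost-penalised actor-critic (beta =", x$beta, ")\n")
  cat("  marginal_hat:", paste(round(x$marginal_hat, 4), collapse = " / "), "\n")
  cat("  V(s):", paste(round(x$v, 3), collapse = ", "), "\n")
  invisible(x)
}

# pi(a|s) for every state: softmax of theta(s,a) + log marginal_hat(a)
agent_policy_matrix <- function(agent) {
  z <- sweep(agent$theta, 2, log(agent$marginal_hat), "+")
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Sample an action from the agent's policy
#'
#' @param agent An [new_agent()] state.
#' @param s 0-based state index.
#' @return `"left"` or `"right"`.
#' @export
act <- function(agent, s) {
  z <- agent$theta[s + 1L, ] + log(agent$marginal_hat)
  p <- exp(z - max(z))
  p <- p / sum(p)
  if (stats::runif(1) < p[2L]) "right" else "left"
}

#' One learning step of the cost-penalised actor-critic
#'
#' Computes the policy cost of the taken action, the prediction error
#' [rpe()], and applies delta-rule updates: the critic moves `V(s)` toward
#' the cost-penalised return, the actor takes a likelihood-gradient
#' (softmax actor) step scaled by the error, and the marginal tracker
#' decays toward the one-hot action indicator.
#'
#' @param agent An [new_agent()] state.
#' @param s 0-based state index of the trial.
#' @param a Action taken (`"left"`/`"right"`).
#' @param r Reward delivered.
#' @return The updated agent, with attributes `delta` and `cost` recording
#'   the trial's prediction error and policy cost (nats).
#' @export
update_agent <- function(agent, s, a, r) {
  si <- s + 1L
  ai <- if (a == "right") 2L else 1L
  z <- agent$theta[si, ] + log(agent$marginal_hat)
  p <- exp(z - max(z)); p <- p / sum(p)
  cost <- log(p[ai] / agent$marginal_hat[ai])
  delta <- rpe(r, agent$v[si], cost, agent$beta)
  agent$v[si] <- agent$v[si] + agent$alpha_v * delta
  grad <- -p; grad[ai] <- grad[ai] + 1   # 1[a'=a] - pi(a'|s)
  agent$theta[si, ] <- agent$theta[si, ] + agent$alpha_theta * delta * grad
  onehot <- c(0, 0); onehot[ai] <- 1
  agent$marginal_hat <- agent$marginal_hat +
    agent$alpha_marginal * (onehot - agent$marginal_hat)
  attr(agent, "delta") <- unname(delta)
  attr(agent, "cost") <- unname(cost)
  agent
}

#' Run the cost-penalised actor-critic on a task
#'
#' Simulates a full session of trial-by-trial learning, logging the
#' prediction error, policy cost, state value and reward of every trial,
#' and averaging the policy over the final `avg_frac` of trials as the
#' agent's terminal (converged) policy. The critic and actor rates are
#' annealed on a Robbins-Monro-style schedule
#' `alpha_t = alpha * decay_tau / (decay_tau + t)` so the stochastic
#' approximation actually settles on its fixed point instead of
#' oscillating around it; set `decay_tau = Inf` for constant rates.
#'
#' @param task A [make_task()] object.
#' @param beta Trade-off inverse temperature, > 0.
#' @param n_trials Number of trials (default 50000).
#' @param seed Integer seed.
#' @param agent Optionally a pre-built [new_agent()] (its beta wins).
#' @param avg_frac Fraction of final trials over which the policy is
#'   averaged (default 0.4).
#' @param decay_tau Timescale (trials) of the learning-rate decay applied
#'   to the critic and actor (default 5000); the marginal tracker keeps
#'   its constant rate.
#' @return A list of class `agent_run`: `trials` (a trial table with
#'   `delta`, `cost`, `v` columns added), `agent` (final state),
#'   `policy_avg` (a [new_policy()] averaged over late trials, with
#'   `complexity` and `reward` attributes computed against the task's
#'   block-averaged Q), and `beta`.
#' @export
run_agent <- function(task, beta = 1, n_trials = 50000L, seed = NULL,
                      agent = NULL, avg_frac = 0.4, decay_tau = 5000) {
  if (is.null(agent)) agent <- new_agent(task$n_states, beta = beta)
  beta <- agent$beta
  n_avg_from <- floor(n_trials * (1 - avg_frac)) + 1L
  with_seed(seed, {
    first <- sample(c("left_large", "right_large"), 1L)
    block_seq <- c(first, setdiff(c("left_large", "right_large"), first))
    block_idx <- ((seq_len(n_trials) - 1L) %/% task$block_length) %% 2L + 1L
    block_type <- block_seq[block_idx]
    s <- sample.int(task$n_states, n_trials, replace = TRUE,
                    prob = task$state_probs)
    contrast <- task$contrasts[s]
    target <- ifelse(contrast < 0, "left", "right")
    zc <- contrast == 0
    if (any(zc))
      target[zc] <- sample(c("left", "right"), sum(zc), replace = TRUE)
    u_act <- stats::runif(n_trials)
    # flat state: loop with primitive updates, no S3 dispatch per trial
    v <- agent$v; theta <- agent$theta; marg <- agent$marginal_hat
    av <- agent$alpha_v; at <- agent$alpha_theta; am <- agent$alpha_marginal
    lmarg <- log(marg)
    action <- character(n_trials)
    reward <- delta_log <- cost_log <- v_log <- numeric(n_trials)
    pol_sum <- matrix(0, task$n_states, 2L)
    n_avg <- 0L
    for (t in seq_len(n_trials)) {
      dec <- if (is.finite(decay_tau)) decay_tau / (decay_tau + t) else 1
      si <- s[t]
      z <- theta[si, ] + lmarg
      p <- exp(z - max(z)); p <- p / sum(p)
      ai <- if (u_act[t] < p[2L]) 2L else 1L
      a_lab <- if (ai == 2L) "right" else "left"
      corr <- a_lab == target[t]
      r <- if (corr) task$reward_asym[block_type[t], a_lab] else 0
      cost <- log(p[ai] / marg[ai])
      delta <- r - v[si] - cost / beta
      v[si] <- v[si] + av * dec * delta
      grad <- -p; grad[ai] <- grad[ai] + 1
      theta[si, ] <- theta[si, ] + at * dec * delta * grad
      marg <- (1 - am) * marg
      marg[ai] <- marg[ai] + am
      lmarg <- log(marg)
      action[t] <- a_lab; reward[t] <- r
      delta_log[t] <- delta; cost_log[t] <- cost; v_log[t] <- v[si]
      if (t >= n_avg_from) {
        zz <- sweep(theta, 2, lmarg, "+")
        zz <- zz - apply(zz, 1, max)
        ezz <- exp(zz)
        pol_sum <- pol_sum + ezz / rowSums(ezz)
        n_avg <- n_avg + 1L
      }
    }
    agent$v <- v; agent$theta <- theta
    agent$marginal_hat <- marg / sum(marg)
    trials <- data.frame(session_id = "agent",
                         trial_index = seq_len(n_trials) - 1L,
                         contrast = contrast,
                         state_index = s - 1L,
                         block_type = block_type,
                         action = action,
                         correct = action == target,
                         reward = reward,
                         delta = delta_log,
                         cost = cost_log,
                         v = v_log,
                         stringsAsFactors = FALSE)
    class(trials) <- c("trial_table", "data.frame")
    pol_avg <- new_policy(pol_sum / n_avg, task$state_probs)
    q_avg <- true_q(task, "average")
    attr(pol_avg, "complexity") <- mutual_information(pol_avg)
    attr(pol_avg, "reward") <- sum(task$state_probs *
                                     rowSums(pol_avg$cond * q_avg))
    structure(list(trials = trials, agent = agent, policy_avg = pol_avg,
                   beta = beta),
              class = "agent_run")
  })
}

#' @export
print.agent_run <- function(x, ...) {
  cat("Actor-critic run: ", nrow(x$trials), " trials, beta = ", x$beta,
      "\n", sep = "")
  cat(sprintf("  terminal complexity = %.4f bits, reward = %.4f\n",
              attr(x$policy_avg, "complexity"), attr(x$policy_avg, "reward")))
  invisible(x)
}
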