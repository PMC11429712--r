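# shared fixtures, built in code

# default asymmetric-block task
fix_task <- function() make_task()

# symmetric 2AFC: unit reward for every correct response, no block asymmetry
fix_symmetric_task <- function() make_task(reward_asym = rbind(c(1, 1), c(1, 1)))

# random valid 9x2 policy with uniform states
random_policy <- function() {
  p <- stats::runif(9)
  new_policy(cbind(1 - p, p), rep(1 / 9, 9))
}

# independent brute-force MI oracle: explicit double loop over the joint
mi_bruteforce <- function(policy) {
  p_s <- policy$state_probs
  marg <- rep(0, ncol(policy$cond))
  for (s in seq_along(p_s)) for (a in seq_along(marg))
    marg[a] <- marg[a] + p_s[s] * policy$cond[s, a]
  mi <- 0
  for (s in seq_along(p_s)) for (a in seq_along(marg)) {
    pj <- p_s[s] * policy$cond[s, a]
    if (pj > 0) mi <- mi + pj * log2(policy$cond[s, a] / marg[a])
  }
  unname(mi)
}

# analytic complexity of the generating policy of generate_session():
# the capacity-limited policy at the task's block-averaged Ql
analytic_generating_mi <- function(task, beta, bias) {
  pol <- optimal_policy(true_q(task, "average"), c(1 - bias, bias), beta,
                        state_probs = task$state_probs)
  mutual_information(pol)
}
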