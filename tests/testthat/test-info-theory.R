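test_that("policy estimation reproduces count arithmetic", {
  # counts (30,10) and (10,30) over two visited states
  tr <- data.frame(
    state_index = rep(c(0, 1), times = c(40, 40)),
    action = c(rep("left", 30), rep("right", 10),
               rep("left", 10), rep("right", 30)))
  pol <- estimate_policy(tr, pseudocount = 0, n_states = 2)
  expect_equal(unname(pol$cond), rbind(c(0.75, 0.25), c(0.25, 0.75)))
  expect_equal(unname(pol$marginal), c(0.5, 0.5))
  # 0.75*log2(1.5) + 0.25*log2(0.5), by direct summation over the 4 cells
  expect_equal(mutual_information(pol), 0.1887219, tolerance = 1e-6)
  # degenerate: all trials one action
  tr1 <- data.frame(state_index = c(0, 1), action = c("right", "right"))
  expect_equal(unname(estimate_policy(tr1, 0, n_states = 2)$marginal), c(0, 1))
  # smoothing removes zeros everywhere
  pol1 <- estimate_policy(tr1, pseudocount = 1, n_states = 2)
  expect_true(all(pol1$cond > 0) && all(pol1$marginal > 0))
  expect_error(estimate_policy(tr[0, ]), "empty")
})

test_that("mutual information is zero under independence, one for an identity channel", {
  pol0 <- new_policy(rbind(c(0.3, 0.7), c(0.3, 0.7)), c(0.5, 0.5))
  expect_equal(mutual_information(pol0), 0)
  pol1 <- new_policy(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5))
  expect_equal(mutual_information(pol1), 1)
})

test_that("plug-in MI equals the brute-force joint sum on random policies", {
  set.seed(101)
  for (i in 1:1000) {
    pol <- random_policy()
    expect_equal(mutual_information(pol), mi_bruteforce(pol),
                 tolerance = 1e-12)
  }
})

test_that("complexity respects the data-processing bound min(H(S), H(A))", {
  set.seed(202)
  for (i in 1:200) {
    p_s <- stats::runif(9); p_s <- p_s / sum(p_s)
    pol <- new_policy(cbind(1 - (p <- stats::runif(9)), p), p_s)
    h_s <- -sum(p_s * log2(p_s))
    marg <- as.numeric(p_s %*% pol$cond)
    h_a <- -sum(ifelse(marg > 0, marg * log2(marg), 0))
    expect_lte(mutual_information(pol), min(h_s, h_a) + 1e-12)
  }
})

test_that("policy cost evaluates the log-ratio and averages to the complexity", {
  pol <- new_policy(rbind(c(0.1, 0.9), c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(policy_cost(pol, 0, "right"), log(0.9 / 0.7))
  expect_equal(policy_cost(pol, 1, "left"), log(0.5 / 0.3))
  pol_flat <- new_policy(rbind(c(0.4, 0.6), c(0.4, 0.6)), c(0.5, 0.5))
  expect_equal(policy_cost(pol_flat, 0, "left"), 0)
  # frequency-weighted mean per-trial cost (nats -> bits) = plug-in MI, exactly
  task <- fix_task()
  tr <- generate_session(task, beta = 2, bias = 0.6, n_trials = 3000, seed = 8)
  plug <- estimate_policy(tr, pseudocount = 0)
  expect_equal(mean(trial_costs(plug, tr)) / log(2),
               mutual_information(plug), tolerance = 1e-12)
})

test_that("cost errors on zero probabilities", {
  pol <- new_policy(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5))
  expect_error(policy_cost(pol, 0, "right"), "P\\(a\\|s\\) = 0")
})

test_that("Blahut-Arimoto hits analytic fixed points", {
  # beta = 0: conditional collapses to the marginal, zero complexity
  q <- rbind(c(1, 0), c(0, 1))
  p0 <- blahut_arimoto(q, c(0.5, 0.5), beta = 0)
  expect_equal(attr(p0, "complexity"), 0, tolerance = 1e-8)
  expect_equal(unname(p0$cond[1, ]), unname(p0$marginal), tolerance = 1e-8)
  # deterministic limit: 1 bit, reward 1
  p50 <- blahut_arimoto(q, c(0.5, 0.5), beta = 50)
  expect_equal(attr(p50, "complexity"), 1, tolerance = 1e-3)
  expect_equal(attr(p50, "reward"), 1, tolerance = 1e-3)
  # asymmetric rewards: the analytic zero-beta frontier endpoint is the
  # best unconditional policy (always-left earns 1.0, beating always-right)
  qa <- rbind(c(2, 0), c(0, 1))
  fa <- frontier(qa, c(0.5, 0.5))
  expect_equal(fa$reward[1], 1.0, tolerance = 1e-12)
  expect_equal(fa$complexity[1], 0)
  expect_error(blahut_arimoto(q, c(0.5, 0.5), beta = -1), "beta")
  expect_error(blahut_arimoto(qa, c(0.5, 0.5), beta = 1, max_iter = 1),
               "converge")
})

test_that("Blahut-Arimoto beats random policies on the trade-off objective", {
  task <- fix_task()
  q <- true_q(task, "average")
  set.seed(33)
  for (beta in c(0.5, 2, 5)) {
    pol <- blahut_arimoto(q, task$state_probs, beta)
    obj_opt <- attr(pol, "reward") -
      attr(pol, "complexity") * log(2) / beta   # complexity in nats / beta
    best_rand <- -Inf
    for (i in 1:1000) {
      rp <- random_policy()
      obj <- sum(task$state_probs * rowSums(rp$cond * q)) -
        mutual_information(rp) * log(2) / beta
      best_rand <- max(best_rand, obj)
    }
    expect_gte(obj_opt + 1e-9, best_rand)
  }
})

test_that("frontier endpoints, monotonicity and session placement are correct", {
  # symmetric 2AFC with unit rewards: endpoints (0, 0.5) -> (1 bit, 1.0)
  q <- rbind(c(1, 0), c(0, 1))
  f2 <- frontier(q, c(0.5, 0.5))
  expect_equal(f2$reward[1], 0.5)
  expect_equal(f2$complexity[1], 0)
  expect_equal(max(f2$reward), 1, tolerance = 1e-3)
  expect_equal(max(f2$complexity), 1, tolerance = 1e-3)
  expect_true(!is.unsorted(f2$complexity) && !is.unsorted(f2$reward))
  # sessions simulated from the generating policy sit on/below the frontier
  task <- fix_task()
  front <- frontier(true_q(task, "average"), task$state_probs)
  devs <- vapply(1:8, function(seed) {
    tr <- generate_session(task, beta = 0.5 * seed, bias = 0.55,
                           n_trials = 4000, seed = seed)
    pol <- estimate_policy(tr)
    frontier_deviation(mutual_information(pol), mean(tr$reward), front)
  }, 0)
  expect_true(all(devs > -2.5))   # above-frontier only within estimation noise
})

test_that("frontier deviation is a vertical percent gap", {
  front <- structure(data.frame(beta = c(0, 1, 2),
                                complexity = c(0, 0.5, 1),
                                reward = c(1, 1.5, 2)),
                     class = c("rc_frontier", "data.frame"))
  expect_equal(frontier_deviation(0.5, 1.5, front), 0)
  expect_equal(frontier_deviation(0.5, 0.75, front), 50)
  expect_equal(frontier_deviation(0.25, 1.25, front), 0)  # interpolated
  expect_equal(frontier_deviation(2, 2, front), 0)        # clamped endpoint
  expect_equal(frontier_deviation(0.5, 1.6, front), 100 * (1.5 - 1.6) / 1.5)
})
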