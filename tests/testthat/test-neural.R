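make_trace <- function(values_fn, n_trials = 4, dt = 10) {
  t <- seq(-200, 900, by = dt)
  vals <- sapply(seq_len(n_trials), function(i) values_fn(t, i))
  new_photometry(t, vals, 1000 / dt)
}

test_that("outcome-window averaging subtracts the peri-outcome baseline", {
  # constant trace: baseline cancels to zero
  tr_const <- make_trace(function(t, i) rep(7, length(t)))
  expect_equal(window_response(tr_const), rep(0, 4))
  # boxcar: baseline b, response window c -> c - b
  tr_box <- make_trace(function(t, i) ifelse(t >= 300 & t < 800, 2 + i, 0.5))
  expect_equal(window_response(tr_box), (2 + 1:4) - 0.5)
  # windows with no samples error
  expect_error(new_photometry(seq(-100, 900, 10), matrix(0, 101, 1), 100),
               "cover")
})

test_that("within-session z-scoring standardises, is affine-invariant and idempotent", {
  set.seed(55)
  y <- stats::rnorm(300)
  sid <- rep(c("a", "b", "c"), each = 100)
  z <- zscore_within_session(y, sid)
  for (s in unique(sid)) {
    expect_equal(mean(z[sid == s]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z[sid == s]), 1, tolerance = 1e-12)
  }
  # sessions differing by an affine map give identical z-scores
  y2 <- c(y[1:100], 5 + 3 * y[1:100])
  z2 <- zscore_within_session(y2, rep(c("a", "b"), each = 100))
  expect_equal(z2[1:100], z2[101:200], tolerance = 1e-12)
  # single grouping level equals a global z-score; idempotence
  zg <- zscore_within_session(y, rep("all", 300))
  expect_equal(zg, as.numeric(scale(y)), tolerance = 1e-12)
  expect_equal(zscore_within_session(z, sid), z, tolerance = 1e-12)
  expect_error(zscore_within_session(rep(1, 10), rep("a", 10)), "variance")
})

test_that("the regressor matrix encodes cost, chosen value and outcome", {
  task <- fix_task()
  tr <- generate_session(task, beta = 2, bias = 0.6, n_trials = 1500, seed = 61)
  pol <- estimate_policy(tr, pseudocount = 0)
  q <- matrix(1, 9, 2)  # constant values
  x <- build_regressors(tr, pol, q)
  expect_equal(colnames(x), c("intercept", "cost", "value", "outcome"))
  expect_equal(unname(x[, "outcome"]), tr$reward)
  expect_equal(unname(x[, "value"]), rep(1, nrow(tr)))
  # frequency-weighted mean cost equals session complexity in nats
  expect_equal(mean(x[, "cost"]), mutual_information(pol) * log(2),
               tolerance = 1e-12)
  # rewarded high-contrast trials pay 1 or 2 depending on the block
  won <- tr$correct & abs(tr$contrast) == 0.5
  expect_true(all(x[won, "outcome"] %in% c(1, 2)))
  # an unconditioned policy has zero cost everywhere
  flat <- new_policy(matrix(0.5, 9, 2), rep(1 / 9, 9))
  expect_equal(unname(build_regressors(tr, flat, q)[, "cost"]),
               rep(0, nrow(tr)))
})

test_that("OLS matches the normal equations and recovers noiseless coefficients", {
  set.seed(71)
  n <- 500
  x <- cbind(intercept = 1, cost = stats::rnorm(n), value = stats::rnorm(n),
             outcome = stats::rnorm(n))
  y0 <- as.numeric(x %*% c(0, -1, -1, 1))
  fit0 <- suppressWarnings(fit_outcome_regression(y0, x))  # zero-residual fit
  expect_equal(unname(fit0$coef), c(0, -1, -1, 1), tolerance = 1e-10)
  expect_equal(fit0$residuals, rep(0, n), tolerance = 1e-8)
  y <- y0 + stats::rnorm(n, 0, 0.5)
  fit <- fit_outcome_regression(y, x)
  beta_ne <- as.numeric(solve(crossprod(x), crossprod(x, y)))
  expect_equal(unname(fit$coef), beta_ne, tolerance = 1e-8)
  rss <- sum((y - x %*% beta_ne)^2)
  sigma2 <- rss / (n - 4)
  se_ne <- sqrt(diag(solve(crossprod(x))) * sigma2)
  expect_equal(unname(fit$se), unname(se_ne), tolerance = 1e-8)
  expect_equal(unname(fit$tstats), unname(fit$coef / fit$se))
  expect_equal(fit$bic, n * log(rss / n) + 4 * log(n))
  # residual orthogonality (normal equations)
  expect_lt(max(abs(crossprod(x, fit$residuals))), 1e-8)
  # rank deficiency is reported with the offending column
  xx <- cbind(x, dup = x[, "cost"])
  expect_error(fit_outcome_regression(y, xx), "collinear")
})

test_that("permuting responses destroys the non-intercept effects", {
  task <- fix_task()
  tr <- generate_session(task, beta = 2, bias = 0.6, n_trials = 2000, seed = 81)
  tr <- generate_responses(tr, task, noise_sd = 0.5, seed = 81)
  pol <- estimate_policy(tr)
  q <- smooth_values(true_q(task, "average"), 0.25)
  x <- build_regressors(tr, pol, q)
  set.seed(82)
  prop_null <- mean(replicate(40, {
    fit <- fit_outcome_regression(sample(tr$response), x)
    all(abs(fit$tstats[c("cost", "value", "outcome")]) < 2)
  }))
  expect_gte(prop_null, 0.8)
})

test_that("cost-model BIC comparison behaves under generative and null data", {
  set.seed(91)
  n <- 3000
  x <- cbind(intercept = 1, cost = stats::rnorm(n), value = stats::rnorm(n),
             outcome = stats::rnorm(n))
  y_gen <- as.numeric(x %*% c(0, -1, -1, 1)) + stats::rnorm(n, 0, 0.5)
  expect_gt(compare_cost_models(y_gen, x)$delta_bic, 0)
  y_null <- as.numeric(x %*% c(0, 0, -1, 1)) + stats::rnorm(n, 0, 0.5)
  expect_lte(compare_cost_models(y_null, x)$delta_bic, 0)
  # an all-zero cost column is flagged as collinear rather than fitted
  x0 <- x; x0[, "cost"] <- 0
  expect_error(compare_cost_models(y_gen, x0), "collinear")
})

test_that("partial residuals isolate one regressor exactly (Frisch-Waugh)", {
  set.seed(93)
  n <- 400
  x <- cbind(intercept = 1, cost = stats::rnorm(n),
             value = stats::rnorm(n), outcome = stats::rnorm(n))
  y <- as.numeric(x %*% c(0.2, -0.8, -1.1, 0.9)) + stats::rnorm(n, 0, 0.7)
  fit <- fit_outcome_regression(y, x)
  pr <- partial_residuals(fit, x, "cost")
  slope <- stats::coef(stats::lm(pr ~ x[, "cost"]))[2]
  expect_equal(unname(slope), unname(fit$coef["cost"]), tolerance = 1e-8)
  # noiseless fit: partial residual is the pure cost contribution
  fit0 <- suppressWarnings(
    fit_outcome_regression(as.numeric(x %*% c(0, -1, -1, 1)), x))
  expect_equal(partial_residuals(fit0, x, "cost"), -x[, "cost"],
               tolerance = 1e-8)
  expect_error(partial_residuals(fit, x, "nonsense"), "unknown")
})

test_that("beta-outcome correlation detects gain coupling and respects the null", {
  expect_equal(correlate_beta_outcome(1:10, 1:10)$r, 1)
  expect_error(correlate_beta_outcome(rep(1, 5), 1:5), "constant")
  expect_error(correlate_beta_outcome(1:2, 1:2), "3 sessions")
  set.seed(95)
  null_r <- replicate(200, correlate_beta_outcome(stats::rnorm(55),
                                                  stats::rnorm(55))$r)
  expect_gte(mean(abs(null_r) < 0.27), 0.93)
  beta <- stats::runif(55, 0.5, 5)
  oc <- beta / mean(beta) + stats::rnorm(55, 0, 0.3)
  expect_gt(correlate_beta_outcome(beta, oc)$r, 0)
})
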