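#' Simulate one behavioural session from the capacity-limited policy
#'
#' Draws stimuli i.i.d. from the task's state distribution within
#' alternating reward blocks, and samples choices from the capacity-limited
#' optimal policy `P(a|s) ∝ P(a) exp[beta Q(s,a)]` evaluated at the task's
#' true block-averaged expected rewards, with the action marginal set by
#' the session's bias. The policy conditions on the 9 stimulus states only
#' (not on the block), so a session's (complexity, reward) point lies on or
#' below the stimulus-state reward-complexity frontier up to sampling
#' noise. At `beta = 0` choices follow the marginal regardless of the
#' stimulus; as `beta` grows, choices approach the reward-maximising
#' action at every contrast.
#'
#' @param task A [make_task()] object.
#' @param beta Inverse temperature >= 0.
#' @param bias Marginal probability of choosing "right", in (0, 1).
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param session_id Identifier stored in the `session_id` column.
#' @return A `trial_table` data.frame with columns `session_id`,
#'   `trial_index` (0-based), `contrast`, `state_index` (0-based),
#'   `block_type`, `action`, `correct`, `reward`, `beta_true`, `bias_true`.
#'   Zero-contrast trials are rewarded on a uniformly random target side.
#' @examples
#' task <- make_task()
#' tr <- generate_session(task, beta = 2, bias = 0.6, n_trials = 200, seed = 1)
#' head(tr)
#' @export
generate_session <- function(task, beta, bias, n_trials, seed = NULL,
                             session_id = "s01") {
  if (beta < 0) stop("`beta` must be >= 0")
  if (bias <= 0 || bias >= 1) stop("`bias` must be in (0, 1)")
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  marginal <- c(1 - bias, bias)
  pol <- optimal_policy(true_q(task, "average"), marginal, beta,
                        state_probs = task$state_probs)
  with_seed(seed, {
    first <- sample(c("left_large", "right_large"), 1L)
    block_seq <- c(first, setdiff(c("left_large", "right_large"), first))
    block_idx <- ((seq_len(n_trials) - 1L) %/% task$block_length) %% 2L + 1L
    block_type <- block_seq[block_idx]
    s <- sample.int(task$n_states, n_trials, replace = TRUE,
                    prob = task$state_probs)
    contrast <- task$contrasts[s]
    # target side: the stimulus side; uniform random for zero contrast
    target <- ifelse(contrast < 0, "left", "right")
    zc <- contrast == 0
    if (any(zc))
      target[zc] <- sample(c("left", "right"), sum(zc), replace = TRUE)
    p_right <- pol$cond[s, "right"]
    action <- ifelse(stats::runif(n_trials) < p_right, "right", "left")
    correct <- action == target
    mags <- task$reward_asym[cbind(block_type, action)]
    reward <- ifelse(correct, mags, 0)
    out <- data.frame(session_id = session_id,
                      trial_index = seq_len(n_trials) - 1L,
                      contrast = contrast,
                      state_index = s - 1L,
                      block_type = block_type,
                      action = action,
                      correct = correct,
                      reward = reward,
                      beta_true = beta,
                      bias_true = bias,
                      stringsAsFactors = FALSE)
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' Attach outcome-locked responses generated by the compression model
#'
#' Generates the scalar outcome-window response of each trial from the
#' cost-penalised prediction-error model:
#' `response = gain * r - V(s) - cost + noise`, where `V(s)` is the
#' expected reward of the state under the generating policy, `cost` is the
#' generating policy's `log P(a|s)/P(a)` (nats), and the noise is
#' i.i.d. Gaussian. With `traces = TRUE` each response is also embedded as
#' a boxcar in the 300-800 ms post-outcome window of an otherwise flat
#' trace, so the trace-windowing step can be exercised end-to-end.
#'
#' @param trials A [generate_session()] table (carrying `beta_true` and
#'   `bias_true`).
#' @param task The [make_task()] the trials came from.
#' @param noise_sd Gaussian noise standard deviation, >= 0 (default 0.5).
#' @param seed Integer seed for the noise.
#' @param outcome_gain Multiplier on the reward term (default 1). Values
#'   proportional to the session's beta emulate inverse-temperature-scaled
#'   reward sensitivity.
#' @param traces Also build a [photometry] trace set (default FALSE);
#'   attached as attribute `"trace"`.
#' @param sampling_rate Trace sampling rate in Hz (default 100).
#' @return The trial table with added columns `response`, `cost_true`
#'   (nats) and `value_true` (`V(s)`).
#' @export
generate_responses <- function(trials, task, noise_sd = 0.5, seed = NULL,
                               outcome_gain = 1, traces = FALSE,
                               sampling_rate = 100) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(trials$beta_true) || is.null(trials$bias_true))
    stop("trials must carry `beta_true` and `bias_true` ",
         "(generate them with generate_session())")
  beta <- trials$beta_true[1L]
  bias <- trials$bias_true[1L]
  marginal <- c(left = 1 - bias, right = bias)
  n <- nrow(trials)
  s <- as.integer(trials$state_index) + 1L
  a <- match(trials$action, task$actions)
  q <- true_q(task, "average")
  pol <- optimal_policy(q, marginal, beta, state_probs = task$state_probs)
  v <- rowSums(pol$cond * q)[s]
  cost <- log(pol$cond[cbind(s, a)] / marginal[a])
  eps <- with_seed(seed, stats::rnorm(n, 0, noise_sd))
  trials$response <- outcome_gain * trials$reward - v - cost + eps
  trials$cost_true <- cost
  trials$value_true <- v
  if (traces) {
    time_ms <- seq(-200, 900, by = 1000 / sampling_rate)
    vals <- matrix(0, length(time_ms), n)
    in_box <- time_ms >= 300 & time_ms < 800
    vals[in_box, ] <- rep(trials$response, each = sum(in_box))
    attr(trials, "trace") <- new_photometry(time_ms, vals, sampling_rate)
  }
  trials
}

#' Construct an outcome-aligned photometry trace set
#'
#' @param time_ms Sample times relative to outcome delivery (ms); must be
#'   uniformly spaced and cover at least \[-200, 900\] ms.
#' @param values Samples x trials matrix of signal values.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `photometry`.
#' @export
new_photometry <- function(time_ms, values, sampling_rate) {
  values <- as.matrix(values)
  if (length(time_ms) != nrow(values))
    stop("`time_ms` must have one entry per row of `values`")
  dt <- diff(time_ms)
  if (max(abs(dt - dt[1])) > 1e-9) stop("sampling must be uniform")
  if (min(time_ms) > -200 || max(time_ms) < 900)
    stop("time grid must cover at least [-200, 900] ms around the outcome")
  structure(list(time_ms = as.numeric(time_ms), values = values,
                 sampling_rate = sampling_rate),
            class = "photometry")
}

#' @export
print.photometry <- function(x, ...) {
  cat("Outcome-aligned photometry:", ncol(x$values), "trials,",
      nrow(x$values), "samples at", x$sampling_rate, "Hz, t in [",
      min(x$time_ms), ",", max(x$time_ms), "] ms\n")
  invisible(x)
}

#' Simulate a multi-session synthetic dataset
#'
#' Generates a set of sessions emulating a photometry experiment: each
#' session gets an inverse temperature and a choice bias drawn uniformly
#' from the given ranges, choices from the capacity-limited policy, and
#' outcome responses from the cost-penalised prediction-error model. By
#' default the reward gain of each session scales with its inverse
#' temperature (normalised to mean 1 across the beta range), emulating
#' beta-controlled reward sensitivity of the outcome response.
#'
#' @param n_sessions Number of sessions (default 55).
#' @param beta_range Interval for session inverse temperatures
#'   (default `c(0.5, 5)`).
#' @param bias_range Interval for session biases P(right)
#'   (default `c(0.3, 0.8)`).
#' @param n_trials Trials per session (default 400).
#' @param seed Integer master seed; per-session seeds are derived from it.
#' @param task A [make_task()] object (default `make_task()`).
#' @param noise_sd Response noise SD (default 0.5); `NA` skips response
#'   generation.
#' @param beta_scaled_gain Scale each session's reward gain by
#'   `beta / mean(beta_range)` (default TRUE).
#' @return A named list of trial tables, one per session.
#' @examples
#' ds <- generate_dataset(n_sessions = 3, n_trials = 100, seed = 1)
#' names(ds)
#' @export
generate_dataset <- function(n_sessions = 55, beta_range = c(0.5, 5),
                             bias_range = c(0.3, 0.8), n_trials = 400,
                             seed = NULL, task = make_task(),
                             noise_sd = 0.5, beta_scaled_gain = TRUE) {
  if (n_sessions < 1) stop("`n_sessions` must be >= 1")
  if (length(beta_range) != 2L || diff(beta_range) < 0 || beta_range[1] < 0)
    stop("`beta_range` must be a non-empty interval of non-negative values")
  if (length(bias_range) != 2L || diff(bias_range) < 0 ||
      bias_range[1] <= 0 || bias_range[2] >= 1)
    stop("`bias_range` must be a non-empty interval inside (0, 1)")
  betas <- with_seed(seed, stats::runif(n_sessions, beta_range[1], beta_range[2]))
  biases <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                      stats::runif(n_sessions, bias_range[1], bias_range[2]))
  base <- if (is.null(seed)) 0L else as.integer(seed)
  sessions <- lapply(seq_len(n_sessions), function(i) {
    sid <- sprintf("s%02d", i)
    s_seed <- if (is.null(seed)) NULL else (base + 7919L * i) %% 2147483647L
    tr <- generate_session(task, beta = betas[i], bias = biases[i],
                           n_trials = n_trials, seed = s_seed,
                           session_id = sid)
    if (!is.na(noise_sd)) {
      gain <- if (beta_scaled_gain) betas[i] / mean(beta_range) else 1
      tr <- generate_responses(tr, task, noise_sd = noise_sd,
                               seed = if (is.null(s_seed)) NULL
                                      else (s_seed + 1L) %% 2147483647L,
                               outcome_gain = gain)
    }
    tr
  })
  names(sessions) <- vapply(sessions, function(x) x$session_id[1], "")
  sessions
}
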