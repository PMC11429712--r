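#' Scalar outcome-window response from an outcome-aligned trace
#'
#' Averages the signal between 300 and 800 ms after outcome delivery
#' (which encompasses the calcium-signal peak) and subtracts the signal
#' averaged over a 200 ms baseline window centred on the outcome
#' (interpreted as \[-100, 100) ms; sample intervals are half-open).
#'
#' @param trace A [new_photometry()] object.
#' @return Numeric vector, one baseline-corrected response per trial.
#' @export
window_response <- function(trace) {
  t <- trace$time_ms
  resp <- t >= 300 & t < 800
  base <- t >= -100 & t < 100
  if (!any(resp) || !any(base))
    stop("response or baseline window contains no samples")
  colMeans(trace$values[resp, , drop = FALSE]) -
    colMeans(trace$values[base, , drop = FALSE])
}

#' Z-score responses within each session
#'
#' Standardises responses to mean 0 and SD 1 separately per session, so
#' that sessions with different raw signal scales can be aggregated into
#' one regression. Idempotent: applying it twice equals applying it once.
#'
#' @param responses Numeric vector of scalar responses.
#' @param session Session identifier per response (a single grouping
#'   vector; pass a constant for global z-scoring).
#' @return Numeric vector of the same length.
#' @export
zscore_within_session <- function(responses, session) {
  if (length(session) != length(responses))
    stop("`session` must have one entry per response")
  out <- responses
  for (sid in unique(session)) {
    sel <- session == sid
    if (sum(sel) < 2) stop("session ", sid, " has fewer than 2 trials")
    sdv <- stats::sd(responses[sel])
    if (!is.finite(sdv) || sdv == 0)
      stop("session ", sid, " has zero response variance")
    out[sel] <- (responses[sel] - mean(responses[sel])) / sdv
  }
  out
}

#' Build the outcome-regression design matrix
#'
#' Per trial: the policy cost of the chosen action under the session's
#' estimated policy (nats), the action value `Q(s, a_chosen)` (the average
#' reward for the chosen action conditional on the stimulus), and the
#' outcome (delivered water amount), plus an intercept.
#'
#' @param trials One session's trial table.
#' @param policy The session's [estimate_policy()] result.
#' @param q The session's (smoothed) states x actions value matrix.
#' @return A numeric matrix with columns `intercept`, `cost`, `value`,
#'   `outcome`.
#' @export
build_regressors <- function(trials, policy, q) {
  q <- as.matrix(q)
  s <- as.integer(trials$state_index) + 1L
  a <- match(trials$action, c("left", "right"))
  cbind(intercept = 1,
        cost = trial_costs(policy, trials),
        value = q[cbind(s, a)],
        outcome = trials$reward)
}

#' Fit the outcome-response regression
#'
#' Ordinary least squares of (z-scored) outcome-locked responses on
#' intercept, policy cost, action value and outcome, pooled across trials.
#' Under the cost-penalised prediction-error model the outcome effect is
#' positive and the value and cost effects are negative.
#'
#' @param y Numeric response vector (use [zscore_within_session()] first
#'   when pooling sessions).
#' @param x Design matrix from [build_regressors()] (or any full-rank
#'   matrix whose first column is the intercept).
#' @return An object of class `da_regression`: list with `coef`, `se`,
#'   `tstats`, `pvals`, `loglik` (Gaussian, variance profiled out), `bic`
#'   (`n log(RSS/n) + k log n`), `n`, `k`, `residuals`, `fitted`, and the
#'   underlying `lm` fit.
#' @export
fit_outcome_regression <- function(y, x) {
  x <- as.matrix(x)
  if (length(y) <= ncol(x)) stop("need more observations than regressors")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[setdiff(seq_len(ncol(x)), qrx$pivot[seq_len(qrx$rank)])]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(y ~ x - 1)
  cf <- stats::coef(fit)
  names(cf) <- colnames(x)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- colnames(x)
  n <- length(y); k <- ncol(x)
  rss <- sum(stats::residuals(fit)^2)
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  ts <- cf / se
  structure(list(coef = cf, se = se, tstats = ts,
                 pvals = 2 * stats::pt(-abs(ts), df = n - k),
                 loglik = ll,
                 bic = n * log(rss / n) + k * log(n),
                 n = n, k = k,
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit)),
                 lm = fit),
            class = "da_regression")
}

#' @export
print.da_regression <- function(x, ...) {
  cat("Outcome-response regression (n =", x$n, ")\n")
  tab <- data.frame(coef = x$coef, se = x$se, t = x$tstats, p = x$pvals)
  print(round(tab, 4))
  cat(sprintf("logLik = %.2f   BIC = %.2f\n", x$loglik, x$bic))
  invisible(x)
}

#' @export
summary.da_regression <- function(object, ...) print(object)

#' @export
coef.da_regression <- function(object, ...) object$coef

#' @export
residuals.da_regression <- function(object, ...) object$residuals

#' @export
logLik.da_regression <- function(object, ...) {
  structure(object$loglik, df = object$k + 1, nobs = object$n,
            class = "logLik")
}

#' @export
BIC.da_regression <- function(object, ...) object$bic

#' @export
plot.da_regression <- function(x, design, regressor = "cost", bins = 10, ...) {
  pr <- partial_residuals(x, design, regressor)
  xx <- design[, regressor]
  b <- cut(xx, stats::quantile(xx, seq(0, 1, length.out = bins + 1)),
           include.lowest = TRUE)
  m <- tapply(pr, b, mean)
  ctr <- tapply(xx, b, mean)
  graphics::plot(ctr, m, xlab = paste(regressor, "(binned)"),
                 ylab = "Partial residual", ...)
  graphics::abline(0, x$coef[regressor], col = "blue")
  invisible(x)
}

#' BIC comparison: does the policy-cost regressor earn its keep?
#'
#' Refits the regression without the cost column and returns
#' `delta_bic = BIC(no cost) - BIC(full)`; positive values favour keeping
#' the cost term.
#'
#' @param y Response vector.
#' @param x Design matrix containing a `cost` column.
#' @return List with `delta_bic`, `fit_full`, `fit_reduced`.
#' @export
compare_cost_models <- function(y, x) {
  x <- as.matrix(x)
  if (!"cost" %in% colnames(x)) stop("design matrix has no `cost` column")
  full <- fit_outcome_regression(y, x)
  red <- fit_outcome_regression(y, x[, colnames(x) != "cost", drop = FALSE])
  list(delta_bic = red$bic - full$bic, fit_full = full, fit_reduced = red)
}

#' Partial residuals for one regressor
#'
#' `residual_i + coef[j] * x_ij`: the response with every other
#' regressor's fitted contribution removed. Regressing the result on the
#' regressor alone returns the multiple-regression coefficient exactly
#' (Frisch-Waugh), which makes this the right quantity for visualising a
#' single effect.
#'
#' @param fit A [fit_outcome_regression()] object.
#' @param x The design matrix the fit used.
#' @param regressor Column name.
#' @return Numeric vector of partial residuals.
#' @export
partial_residuals <- function(fit, x, regressor) {
  x <- as.matrix(x)
  if (!regressor %in% colnames(x))
    stop("unknown regressor: ", regressor)
  fit$residuals + fit$coef[regressor] * x[, regressor]
}

#' Correlate behavioural inverse temperature with the neural outcome effect
#'
#' If the inverse temperature controls both the reward-compression
#' trade-off and reward sensitivity of the prediction error, sessions with
#' higher fitted beta should show larger outcome coefficients. Pearson
#' correlation across sessions, two-sided p from the t distribution on
#' n - 2 df.
#'
#' @param beta_hat Per-session fitted inverse temperatures.
#' @param outcome_coef Per-session outcome regression coefficients.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_beta_outcome <- function(beta_hat, outcome_coef) {
  if (length(beta_hat) != length(outcome_coef))
    stop("inputs must have equal length")
  if (length(beta_hat) < 3) stop("need at least 3 sessions")
  if (stats::sd(beta_hat) == 0 || stats::sd(outcome_coef) == 0)
    stop("constant input vector")
  ct <- stats::cor.test(beta_hat, outcome_coef, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(beta_hat))
}
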