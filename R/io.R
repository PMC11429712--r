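#' Write a trial table (or list of tables) to CSV
#'
#' Columns are written in the documented schema order: `session_id`,
#' `trial_index`, `contrast`, `state_index`, `block_type`, `action`,
#' `correct`, `reward`, then any extras (`beta_true`, `bias_true`,
#' `response`, ...).
#'
#' @param trials A trial table or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (!is.data.frame(trials)) trials <- do.call(rbind, trials)
  core <- c("session_id", "trial_index", "contrast", "state_index",
            "block_type", "action", "correct", "reward")
  trials <- trials[, c(core, setdiff(names(trials), core)), drop = FALSE]
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read trial tables from CSV
#'
#' Validates the documented schema (required columns, numeric contrast,
#' known action labels, non-negative rewards, reward-correctness
#' consistency) and returns typed tables grouped by session, preserving
#' row order.
#'
#' @param path CSV path written by [write_trials()] (or matching its
#'   schema).
#' @param as_sessions Return a list split by `session_id` (default TRUE);
#'   otherwise one combined table.
#' @return A named list of `trial_table` data.frames (or one table).
#' @export
read_trials <- function(path, as_sessions = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("session_id", "trial_index", "contrast", "state_index",
           "block_type", "action", "correct", "reward")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(df$contrast)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$contrast))))[1]
    stop("non-numeric contrast at row ", bad, ", column `contrast`")
  }
  badact <- which(!df$action %in% c("left", "right"))
  if (length(badact))
    stop("unknown action label at row ", badact[1], ", column `action`: ",
         df$action[badact[1]])
  badr <- which(df$reward < 0)
  if (length(badr))
    stop("negative reward at row ", badr[1], ", column `reward`")
  df$correct <- as.logical(df$correct)
  incons <- which((df$reward > 0) != df$correct)
  if (length(incons))
    stop("reward-correctness inconsistency at row ", incons[1])
  class(df) <- c("trial_table", "data.frame")
  if (!as_sessions) return(df)
  out <- split(df, factor(df$session_id, levels = unique(df$session_id)))
  lapply(out, function(x) { class(x) <- c("trial_table", "data.frame"); x })
}

#' Write an outcome-aligned photometry trace set to CSV
#'
#' First column `time_ms`, one column per trial.
#'
#' @param trace A [new_photometry()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_photometry <- function(trace, path) {
  df <- data.frame(time_ms = trace$time_ms, trace$values)
  names(df) <- c("time_ms", paste0("trial_", seq_len(ncol(trace$values))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an outcome-aligned photometry trace set from CSV
#'
#' @param path CSV written by [write_photometry()].
#' @param sampling_rate Sampling rate in Hz; inferred from the time grid
#'   when `NULL`.
#' @return A [new_photometry()] object.
#' @export
read_photometry <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "time_ms") stop("first column must be `time_ms`")
  t <- df$time_ms
  if (is.null(sampling_rate)) sampling_rate <- 1000 / (t[2] - t[1])
  new_photometry(t, as.matrix(df[, -1, drop = FALSE]), sampling_rate)
}

#' Pipeline configuration with documented defaults
#'
#' Collects every tunable of the end-to-end analysis in one object.
#' Unknown keys are rejected. The configuration serialises losslessly to
#' JSON via [write_config()] / [read_config()].
#'
#' @param ... Named overrides of the defaults: `n_sessions` (55),
#'   `n_trials` (400), `beta_range` (c(0.5, 5)), `bias_range` (c(0.3,
#'   0.8)), `noise_sd` (0.5), `beta_scaled_gain` (TRUE), `pseudocount`
#'   (1), `smoothing_w` (0.25), `beta_grid_n` (100), `beta_grid_range`
#'   (c(0.01, 100)), `seed` (1), `input` (NULL: generate synthetically, or
#'   a trial CSV path), `output_dir` (NULL: keep results in memory only).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_sessions = 55, n_trials = 400,
              beta_range = c(0.5, 5), bias_range = c(0.3, 0.8),
              noise_sd = 0.5, beta_scaled_gain = TRUE,
              pseudocount = 1, smoothing_w = 0.25,
              beta_grid_n = 100, beta_grid_range = c(0.01, 100),
              seed = 1, input = NULL, output_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `run_config` object.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full policy-compression analysis pipeline
#'
#' Stages: (1) obtain trial data (synthetic by default, or a CSV via
#' `config$input`); (2) compute the optimal reward-complexity frontier for
#' the task; (3) per session, estimate the policy, its complexity, mean
#' reward, and percent deviation from the frontier; (4) fit the
#' capacity-limited policy with and without the session bias and compare
#' by BIC; (5) z-score the outcome responses within session, build the
#' cost/value/outcome regressors, fit the pooled outcome regression and
#' the cost-model BIC comparison; (6) correlate per-session fitted beta
#' with per-session outcome coefficients. When `config$output_dir` is set,
#' all result tables are written as CSV along with a JSON manifest
#' recording the config and seed.
#'
#' @param config A [pipeline_config()] object.
#' @param task A [make_task()] object (default `make_task()`).
#' @return A list of class `pipeline_result` with elements `sessions`,
#'   `frontier`, `session_summary`, `bias_comparison`, `regression`,
#'   `cost_comparison`, `beta_outcome`, `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(n_sessions = 5, n_trials = 200))
#' res$session_summary
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), task = make_task()) {
  stage <- "load-data"
  res <- tryCatch({
    sessions <- if (!is.null(config$input)) {
      read_trials(config$input)
    } else {
      generate_dataset(n_sessions = config$n_sessions,
                       beta_range = config$beta_range,
                       bias_range = config$bias_range,
                       n_trials = config$n_trials,
                       seed = config$seed, task = task,
                       noise_sd = config$noise_sd,
                       beta_scaled_gain = config$beta_scaled_gain)
    }

    stage <- "frontier"
    grid <- exp(seq(log(config$beta_grid_range[1]),
                    log(config$beta_grid_range[2]),
                    length.out = config$beta_grid_n))
    front <- frontier(true_q(task, "average"), task$state_probs, grid)

    stage <- "session-summaries"
    pols <- lapply(sessions, estimate_policy, pseudocount = config$pseudocount)
    qs <- lapply(sessions, function(tr)
      smooth_values(empirical_q(tr, task), config$smoothing_w))
    summ <- do.call(rbind, lapply(seq_along(sessions), function(i) {
      tr <- sessions[[i]]
      cx <- mutual_information(pols[[i]])
      rw <- mean(tr$reward)
      data.frame(session_id = names(sessions)[i],
                 n_trials = nrow(tr),
                 complexity = cx, reward = rw,
                 deviation_pct = frontier_deviation(cx, rw, front))
    }))

    stage <- "policy-fits"
    bias_cmp <- compare_bias_models(sessions, task,
                                    smoothing_w = config$smoothing_w)
    summ$beta_hat <- bias_cmp$per_session$beta_bias

    stage <- "outcome-regression"
    has_resp <- all(vapply(sessions, function(x) !is.null(x$response),
                           logical(1)))
    reg <- cost_cmp <- bcorr <- NULL
    if (has_resp) {
      xs <- lapply(seq_along(sessions), function(i)
        build_regressors(sessions[[i]], pols[[i]], qs[[i]]))
      x_all <- do.call(rbind, xs)
      y_raw <- unlist(lapply(sessions, function(x) x$response),
                      use.names = FALSE)
      sid <- rep(names(sessions), vapply(sessions, nrow, 0L))
      y <- zscore_within_session(y_raw, sid)
      cost_cmp <- compare_cost_models(y, x_all)
      reg <- cost_cmp$fit_full

      stage <- "beta-outcome-correlation"
      oc <- vapply(seq_along(sessions), function(i) {
        yi <- y[sid == names(sessions)[i]]
        fit_outcome_regression(yi, xs[[i]])$coef["outcome"]
      }, 0)
      summ$outcome_coef <- oc
      bcorr <- correlate_beta_outcome(summ$beta_hat, oc)
    }

    list(sessions = sessions, frontier = front, session_summary = summ,
         bias_comparison = bias_cmp, regression = reg,
         cost_comparison = cost_cmp, beta_outcome = bcorr, config = config)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$output_dir, f)
    write_trials(res$sessions, p("trials.csv"))
    utils::write.csv(as.data.frame(res$frontier), p("frontier.csv"),
                     row.names = FALSE)
    utils::write.csv(res$session_summary, p("session_summary.csv"),
                     row.names = FALSE)
    if (!is.null(res$regression)) {
      utils::write.csv(data.frame(term = names(res$regression$coef),
                                  coef = res$regression$coef,
                                  se = res$regression$se,
                                  t = res$regression$tstats,
                                  p = res$regression$pvals),
                       p("regression.csv"), row.names = FALSE)
    }
    manifest <- list(package = "policycompress",
                     version = as.character(utils::packageVersion("policycompress")),
                     seed = config$seed,
                     config = unclass(config),
                     delta_bic_bias = res$bias_comparison$delta_bic,
                     delta_bic_cost = if (!is.null(res$cost_comparison))
                       res$cost_comparison$delta_bic else NULL,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Policy-compression pipeline:", length(x$sessions), "sessions\n")
  cat(sprintf("  median frontier deviation: %.2f%%\n",
              stats::median(x$session_summary$deviation_pct)))
  cat(sprintf("  dBIC (bias model):  %.1f\n", x$bias_comparison$delta_bic))
  if (!is.null(x$cost_comparison))
    cat(sprintf("  dBIC (cost term):   %.1f\n", x$cost_comparison$delta_bic))
  if (!is.null(x$regression)) {
    ts <- x$regression$tstats
    cat(sprintf("  regression t: outcome %.2f, value %.2f, cost %.2f\n",
                ts["outcome"], ts["value"], ts["cost"]))
  }
  if (!is.null(x$beta_outcome))
    cat(sprintf("  beta-outcome correlation: r = %.3f (p = %.3g)\n",
                x$beta_outcome$r, x$beta_outcome$p))
  invisible(x)
}
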