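#' Define a 2AFC contrast-discrimination task
#'
#' Constructs the task structure for a two-alternative forced-choice
#' perceptual decision task: a grating of variable signed contrast appears on
#' the left (negative contrast) or right (positive contrast), the animal
#' reports the side, and correct responses are rewarded with water. Reward
#' magnitudes are asymmetric across blocks: in a "left_large" block the
#' correct response to a left stimulus pays twice as much as the correct
#' response to a right stimulus, and vice versa.
#'
#' @param contrasts Numeric vector of 9 signed contrast levels (fractions;
#'   negative = stimulus on the left), sorted ascending. Default
#'   `c(-0.5, -0.25, -0.125, -0.0625, 0, 0.0625, 0.125, 0.25, 0.5)`.
#' @param state_probs Probability of each contrast level; must be
#'   non-negative and sum to 1. Default uniform (1/9 each).
#' @param block_length Number of trials per reward block (default 100).
#' @param reward_asym 2 x 2 numeric matrix of water magnitudes for correct
#'   responses, rows = block types (`left_large`, `right_large`), columns =
#'   response side (`left`, `right`). Default `rbind(c(2, 1), c(1, 2))`,
#'   i.e. the large side pays double. All entries must be positive.
#' @param go_cue Ignored placeholder for timing realism (seconds).
#'
#' @return An object of class `task_spec`: a list with elements `contrasts`,
#'   `state_probs`, `block_length`, `reward_asym`, `go_cue`, `n_states`,
#'   `actions`.
#' @examples
#' task <- make_task()
#' task$contrasts
#' @export
make_task <- function(contrasts = c(-0.5, -0.25, -0.125, -0.0625, 0,
                                    0.0625, 0.125, 0.25, 0.5),
                      state_probs = rep(1 / 9, 9),
                      block_length = 100,
                      reward_asym = rbind(left_large = c(2, 1),
                                          right_large = c(1, 2)),
                      go_cue = 0.5) {
  if (length(contrasts) != 9L)
    stop("`contrasts` must have exactly 9 levels, got ", length(contrasts))
  if (is.unsorted(contrasts, strictly = TRUE))
    stop("`contrasts` must be strictly ascending")
  if (length(state_probs) != length(contrasts))
    stop("`state_probs` must have one entry per contrast level")
  if (any(state_probs < 0) || abs(sum(state_probs) - 1) > 1e-12)
    stop("`state_probs` must be non-negative and sum to 1")
  reward_asym <- as.matrix(reward_asym)
  if (!all(dim(reward_asym) == c(2L, 2L)))
    stop("`reward_asym` must be a 2 x 2 matrix (block type x response side)")
  if (any(!is.finite(reward_asym)) || any(reward_asym <= 0))
    stop("reward magnitudes must be positive and finite")
  if (block_length < 1)
    stop("`block_length` must be >= 1")
  dimnames(reward_asym) <- list(c("left_large", "right_large"),
                                c("left", "right"))
  structure(list(contrasts = as.numeric(contrasts),
                 state_probs = as.numeric(state_probs),
                 block_length = as.integer(block_length),
                 reward_asym = reward_asym,
                 go_cue = go_cue,
                 n_states = length(contrasts),
                 actions = c("left", "right")),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat("2AFC contrast-discrimination task\n")
  cat("  contrasts:   ", paste(x$contrasts, collapse = ", "), "\n")
  cat("  state probs: ", paste(signif(x$state_probs, 3), collapse = ", "), "\n")
  cat("  block length:", x$block_length, "trials\n")
  cat("  rewards (left_large block):  left", x$reward_asym[1, 1],
      "/ right", x$reward_asym[1, 2], "\n")
  cat("  rewards (right_large block): left", x$reward_asym[2, 1],
      "/ right", x$reward_asym[2, 2], "\n")
  invisible(x)
}

#' Expected-reward table Q(s,a) programmed by the task
#'
#' Q(s,a) is the expected water amount for taking action `a` in state `s`.
#' For non-zero contrasts the stimulus side is the rewarded side; for the
#' zero-contrast state the rewarded side is assigned uniformly at random, so
#' either action earns half its magnitude in expectation.
#'
#' @param task A [make_task()] object.
#' @param block_type `"left_large"`, `"right_large"`, or `"average"` (the
#'   long-run average over equally frequent block types).
#' @return A 9 x 2 matrix (states x actions `left`, `right`) of expected
#'   rewards.
#' @export
true_q <- function(task, block_type = c("average", "left_large", "right_large")) {
  block_type <- match.arg(block_type)
  mags <- if (block_type == "average") colMeans(task$reward_asym)
          else task$reward_asym[block_type, ]
  q <- matrix(0, task$n_states, 2L,
              dimnames = list(NULL, task$actions))
  for (i in seq_len(task$n_states)) {
    cc <- task$contrasts[i]
    if (cc < 0) q[i, "left"] <- mags["left"]
    else if (cc > 0) q[i, "right"] <- mags["right"]
    else q[i, ] <- mags / 2  # ambiguous stimulus: rewarded side is random
  }
  q
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic generators route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
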