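#' Configure a multiple-bandits task
#'
#' The task presents two decisions per trial; each decision pays out one of
#' two anti-correlated outcomes, `P` and `100 - P` points, where `P` follows
#' a bounded Gaussian random walk. Which decision produces which color-coded
#' outcome is hidden from the agent and must be inferred.
#'
#' @param n_blocks Number of blocks per session.
#' @param n_trials_per_block Trials per block (at least 2, so that
#'   stay/switch behavior is defined).
#' @param walk_sd Standard deviation of the Gaussian walk step, in points.
#' @param walk_bounds Closed interval the walk is confined to, in points.
#' @param win_threshold Points above which an outcome counts as a win.
#' @param bounds_scheme How a step that would leave `walk_bounds` is handled:
#'   `"negate"` applies the step in the opposite direction (the default; this
#'   scheme reproduces the task's outcome-stability statistic of roughly 5.7
#'   same-side trials, see the methods vignette), `"reflect"` mirrors the
#'   value off the bound, `"clip"` truncates at the bound.
#' @return A `bandit_task_config` list.
#' @export
task_config <- function(n_blocks = 3, n_trials_per_block = 100,
                        walk_sd = 15, walk_bounds = c(1, 99),
                        win_threshold = 50,
                        bounds_scheme = c("negate", "reflect", "clip")) {
  bounds_scheme <- match.arg(bounds_scheme)
  if (length(walk_bounds) != 2 || diff(walk_bounds) <= 0)
    stop("`walk_bounds` must be a non-degenerate interval", call. = FALSE)
  if (walk_sd < 0) stop("`walk_sd` must be non-negative", call. = FALSE)
  if (n_trials_per_block < 2)
    stop("`n_trials_per_block` must be at least 2", call. = FALSE)
  structure(
    list(n_blocks = as.integer(n_blocks),
         n_trials_per_block = as.integer(n_trials_per_block),
         walk_sd = walk_sd, walk_bounds = walk_bounds,
         win_threshold = win_threshold, bounds_scheme = bounds_scheme),
    class = "bandit_task_config")
}

#' @export
print.bandit_task_config <- function(x, ...) {
  cat("<multiple-bandits task config>\n")
  cat(sprintf("  %d block(s) x %d trials, walk N(0, %g) in [%g, %g] (%s), win > %g\n",
              x$n_blocks, x$n_trials_per_block, x$walk_sd,
              x$walk_bounds[1], x$walk_bounds[2], x$bounds_scheme,
              x$win_threshold))
  invisible(x)
}

scheme_code <- function(scheme) {
  match(scheme, c("negate", "reflect", "clip")) - 1L
}

#' Generate one bounded Gaussian random walk
#'
#' The first value is drawn uniformly from the integers in `bounds`; each
#' later value adds a `N(0, sd)` step, applies the boundary scheme, and is
#' rounded to the nearest integer point.
#'
#' @param n_trials Walk length.
#' @param sd Gaussian step standard deviation (points); `sd = 0` gives a
#'   constant walk.
#' @param bounds Closed interval, default `c(1, 99)`.
#' @param scheme Boundary scheme, see [task_config()].
#' @param start Optional fixed starting value; by default drawn uniformly.
#' @return Integer-valued numeric vector of length `n_trials`.
#' @export
generate_walk <- function(n_trials, sd = 15, bounds = c(1, 99),
                          scheme = c("negate", "reflect", "clip"),
                          start = NULL) {
  scheme <- match.arg(scheme)
  if (n_trials < 1) stop("`n_trials` must be at least 1", call. = FALSE)
  if (length(bounds) != 2 || diff(bounds) <= 0)
    stop("invalid `bounds`", call. = FALSE)
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (is.null(start)) start <- sample(seq(bounds[1], bounds[2]), 1)
  if (start < bounds[1] || start > bounds[2])
    stop("`start` outside `bounds`", call. = FALSE)
  walk_cpp(as.integer(n_trials), sd, bounds[1], bounds[2],
           scheme_code(scheme), start)
}

#' Generate one task block
#'
#' Draws the two independent outcome walks `P` (decision 1) and `Q`
#' (decision 2), a random decision-to-color mapping, and a random per-trial
#' presentation order of the two outcomes (relevant only for serial outcome
#' presentation; it never enters the model computations).
#'
#' @param config A [task_config()].
#' @param block Block index stored in the output.
#' @return A tibble with one row per trial: `block`, `trial`, walk values
#'   `p` and `q`, the block's `color_d1` ("blue" or "yellow", the color of
#'   decision 1's outcome), and `shown_first` ("o1"/"o2").
#' @export
generate_block <- function(config = task_config(), block = 1L) {
  n <- config$n_trials_per_block
  p <- generate_walk(n, config$walk_sd, config$walk_bounds,
                     config$bounds_scheme)
  q <- generate_walk(n, config$walk_sd, config$walk_bounds,
                     config$bounds_scheme)
  tibble::tibble(
    block = as.integer(block), trial = seq_len(n), p = p, q = q,
    color_d1 = sample(c("blue", "yellow"), 1),
    shown_first = sample(c("o1", "o2"), n, replace = TRUE))
}

#' Generate a full task session
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed.
#' @return Row-bound blocks from [generate_block()].
#' @export
generate_task <- function(config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(config$n_blocks),
                 function(b) generate_block(config, block = b))
}

#' Outcome delivered for an action
#'
#' Action 1 earns the walk value itself, action 2 its 100-point complement,
#' so the two candidate outcomes of a decision always sum to exactly 100.
#'
#' @param walk_value Walk value(s) in points.
#' @param action Action index, 1 or 2 (recycled against `walk_value`).
#' @return Outcome in points.
#' @export
outcome_for_action <- function(walk_value, action) {
  if (!all(action %in% c(1, 2))) stop("`action` must be 1 or 2", call. = FALSE)
  n <- max(length(walk_value), length(action))
  walk_value <- rep_len(walk_value, n)
  action <- rep_len(action, n)
  ifelse(action == 1, walk_value, 100 - walk_value)
}

#' Center an outcome to the reward scale
#'
#' Maps points in \[1, 99\] to rewards in \[-0.98, 0.98\] via `r/50 - 1`.
#'
#' @param points Outcome value(s) in points.
#' @return Centered rewards.
#' @export
center_outcome <- function(points) {
  if (any(points < 1 | points > 99))
    stop("outcomes must lie in [1, 99]", call. = FALSE)
  points / 50 - 1
}

#' Dichotomize an outcome into win or loss
#'
#' A win is strictly more than `threshold` points; an exact tie counts as a
#' loss (ties occur on about 1% of trials at the default integer walk).
#'
#' @param points Outcome value(s) in points.
#' @param threshold Win threshold, default 50.
#' @return Character vector of `"win"` / `"loss"`.
#' @export
dichotomize <- function(points, threshold = 50) {
  if (any(points < 1 | points > 99))
    stop("outcomes must lie in [1, 99]", call. = FALSE)
  ifelse(points > threshold, "win", "loss")
}

# signed coding (+1 win / -1 loss) used by the stay regressions
outcome_sign <- function(points, threshold = 50) {
  ifelse(points > threshold, 1, -1)
}

#' Same-side run lengths of a walk
#'
#' Lengths of the maximal stretches of consecutive trials on one side of the
#' win/loss threshold.
#'
#' @param x Walk values.
#' @param threshold Win threshold.
#' @return Integer vector of run lengths.
#' @export
walk_run_lengths <- function(x, threshold = 50) {
  rle(x > threshold)$lengths
}

#' Outcome stability of the task's random walk
#'
#' Monte-Carlo estimate of the mean number of consecutive trials an outcome
#' walk stays on one side of the win/loss threshold. Under the default walk
#' (SD 15 in \[1, 99\], step-negation bounds) this is about 5.7 trials.
#'
#' @param n_blocks Number of simulated blocks (default 10000).
#' @param config Task configuration.
#' @param seed Optional integer seed.
#' @return A tibble with the mean run length, its standard error, and the
#'   number of runs pooled.
#' @export
walk_stability <- function(n_blocks = 10000, config = task_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    x <- generate_walk(config$n_trials_per_block, config$walk_sd,
                       config$walk_bounds, config$bounds_scheme)
    lens[[b]] <- walk_run_lengths(x, config$win_threshold)
  }
  lens <- unlist(lens)
  tibble::tibble(mean_run_length = mean(lens),
                 se = sd(lens) / sqrt(length(lens)),
                 n_runs = length(lens))
}
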