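#' Monte-Carlo simulation study
#'
#' Simulates `n_runs` agents of the given model on fresh task sessions,
#' with parameters drawn per run from the empirical priors, and collects
#' per-run summaries: the final arbitration weight, the mean surprise of
#' each policy, and the drawn parameters.
#'
#' @param n_runs Number of runs (default 1000).
#' @param spec Model to simulate.
#' @param config Task configuration.
#' @param seed Optional integer seed.
#' @param keep_trials If `TRUE`, attach each run's trial table as a list
#'   column (memory permitting).
#' @return Tibble with one row per run.
#' @export
simulate_study <- function(n_runs = 1000, spec = model_spec(),
                           config = task_config(), seed = NULL,
                           keep_trials = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pars <- draw_params(spec, n_runs)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    task <- generate_task(config)
    sim <- simulate_agent(task, spec, unlist(pars[i, ]))
    l <- sim$latents
    row <- tibble::tibble(
      run = i,
      final_weight = sim$final_weight,
      mean_surprise_correct = mean(l$surprise_correct),
      mean_surprise_incorrect = mean(l$surprise_incorrect),
      prop_wins = mean(c(sim$trials$outcome_o1, sim$trials$outcome_o2) > 50))
    rows[[i]] <- dplyr::bind_cols(row, pars[i, ])
    if (keep_trials) rows[[i]]$trials <- list(sim$trials)
  }
  dplyr::bind_rows(rows)
}

#' Headline simulation statistics
#'
#' Recomputes the three desk-scale Monte-Carlo statistics of the
#' surprise-minimization account: (1) the number of runs (out of
#' `n_runs`) whose final arbitration weight favors the correct policy,
#' with a binomial confidence interval; (2) the Wilcoxon signed-rank Z
#' comparing each run's mean surprise under the correct versus incorrect
#' policy (at complete separation this equals the maximal
#' `(n(n+1)/4)/sqrt(n(n+1)(2n+1)/24)`); and (3) the mean same-side run
#' length of the outcome walk.
#'
#' @param n_runs Simulation runs for statistics 1 and 2.
#' @param n_walk_blocks Blocks for the walk-stability statistic.
#' @param spec Model to simulate.
#' @param config Task configuration.
#' @param seed Optional integer seed.
#' @return A `bandit_validation` list with `runs` (per-run summaries) and
#'   `stats` (tidy table of the three statistics).
#' @export
validate_simulation <- function(n_runs = 1000, n_walk_blocks = 10000,
                                spec = model_spec(),
                                config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runs <- simulate_study(n_runs, spec, config)
  n_above <- sum(runs$final_weight > 0.5)
  ci <- stats::binom.test(n_above, n_runs)$conf.int
  wz <- wilcoxon_z(runs$mean_surprise_incorrect,
                   runs$mean_surprise_correct)
  walk <- walk_stability(n_walk_blocks, config)
  stats_tab <- tibble::tibble(
    statistic = c("final_weight_correct", "surprise_wilcoxon_z",
                  "walk_mean_run_length"),
    value = c(n_above, wz$z, walk$mean_run_length),
    lower = c(ci[1] * n_runs, NA, walk$mean_run_length - 2 * walk$se),
    upper = c(ci[2] * n_runs, NA, walk$mean_run_length + 2 * walk$se),
    n = c(n_runs, wz$n, walk$n_runs))
  structure(list(runs = runs, stats = stats_tab),
            class = "bandit_validation")
}

#' @export
print.bandit_validation <- function(x, ...) {
  cat("<simulation validation>\n")
  print(x$stats)
  invisible(x)
}

# ---------------------------------------------------------------------------
# tabular and config I/O

#' Write / read trial records
#'
#' Trial tables round-trip losslessly through tab-separated text.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trials()` returns the tibble; `write_trials()` its input,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  prob <- readr::problems(out)
  if (nrow(prob) > 0)
    stop(sprintf("malformed rows in %s (first at line %d): %s", path,
                 prob$row[1] + 1L, prob$expected[1]), call. = FALSE)
  out
}

#' Write / read latent traces
#'
#' @param latents Latent-trace tibble.
#' @param path File path.
#' @export
write_latents <- function(latents, path) {
  readr::write_tsv(latents, path)
  invisible(latents)
}

#' @rdname write_latents
#' @export
read_latents <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Save / load a run configuration
#'
#' Nested key-value configuration (task settings, model id, seeds) as
#' YAML, sufficient to reproduce a run together with its seed.
#'
#' @param config A list, e.g. `list(task = task_config(), model =
#'   "surprise_min", seed = 1)`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  cfg <- rapply(config, unclass, how = "replace")
  yaml::write_yaml(cfg, path)
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$task)) cfg$task <- do.call(task_config, cfg$task)
  cfg
}

#' Write / read epochs
#'
#' Epochs are stored as a directory: `meta.json` (channels, times,
#' sampling rate, array dimensions), `events.tsv`, and `data.tsv.gz`
#' holding the flattened array in long form (event, channel, sample,
#' value). The layout round-trips exactly up to numeric printing
#' precision.
#'
#' @param ep A `bandit_epochs`.
#' @param dir Directory path (created if needed).
#' @export
write_epochs <- function(ep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(channels = ep$channels, times = ep$times,
         sampling_rate = ep$sampling_rate, dim = dim(ep$data)),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  readr::write_tsv(ep$events, file.path(dir, "events.tsv"))
  d <- dim(ep$data)
  long <- tibble::tibble(
    event = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(ep$data))
  readr::write_tsv(long, file.path(dir, "data.tsv.gz"))
  invisible(ep)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  events <- readr::read_tsv(file.path(dir, "events.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  long <- readr::read_tsv(file.path(dir, "data.tsv.gz"),
                          show_col_types = FALSE, progress = FALSE)
  arr <- array(long$value, dim = meta$dim)
  epochs(arr, meta$channels, meta$times, meta$sampling_rate, events)
}

#' Import epochs from per-event matrices
#'
#' Adapter for epoched-EEG exports that provide one channels x time matrix
#' per event plus an event metadata table.
#'
#' @param matrices List of channels x time matrices, one per event.
#' @param events Event metadata tibble (one row per matrix).
#' @param channels Channel labels.
#' @param times Time vector in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `bandit_epochs`.
#' @export
epochs_from_matrices <- function(matrices, events, channels, times,
                                 sampling_rate) {
  stopifnot(length(matrices) == nrow(events))
  arr <- array(NA_real_, c(length(matrices), length(channels),
                           length(times)))
  for (i in seq_along(matrices)) arr[i, , ] <- matrices[[i]]
  epochs(arr, channels, times, sampling_rate, events)
}
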