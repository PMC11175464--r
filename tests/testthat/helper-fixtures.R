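# small fixtures built in code

default_params <- c(alpha = 0.4, beta = 4, rho = 0.3, epsilon = 0.4)

make_task <- function(seed = 1, n_blocks = 2, n_trials = 40) {
  generate_task(task_config(n_blocks = n_blocks,
                            n_trials_per_block = n_trials), seed = seed)
}

make_sim <- function(seed = 1, spec = model_spec(), params = default_params,
                     ...) {
  task <- make_task(seed, ...)
  simulate_agent(task, spec, params, seed = seed + 1000)
}

# multi-participant cohort of simulated agents with fixed parameters
make_cohort <- function(n = 6, seed = 1, spec = model_spec(),
                        params = default_params, n_blocks = 2,
                        n_trials = 40) {
  purrr::map_dfr(seq_len(n), function(i) {
    sim <- make_sim(seed + i, spec, params, n_blocks = n_blocks,
                    n_trials = n_trials)
    dplyr::mutate(sim$trials, participant = i, .before = 1)
  })
}

# minimal 4-channel chain adjacency for EEG toys
chain_adjacency <- function(channels) {
  n <- length(channels)
  nb <- lapply(seq_len(n), function(i)
    channels[setdiff(c(i - 1, i + 1), c(0, n + 1))])
  setNames(nb, channels)
}

make_toy_epochs <- function(n_events = 60, n_ch = 4, n_t = 20, seed = 2,
                            srate = 100) {
  set.seed(seed)
  arr <- array(rnorm(n_events * n_ch * n_t), c(n_events, n_ch, n_t))
  epochs(arr, paste0("ch", seq_len(n_ch)),
         seq(0, by = 1 / srate, length.out = n_t), srate,
         tibble::tibble(event = seq_len(n_events)))
}
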