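#' Specify a candidate model
#'
#' Five candidate accounts of choice in the multiple-bandits task:
#'
#' * `"surprise_min"` — two policies (one per candidate decision-outcome
#'   mapping) learn action values in parallel; the difference of their
#'   surprise signals (absolute prediction errors) is accumulated into an
#'   arbitration weight that mixes the policies' values for action selection.
#'   Free parameters: learning rate `alpha`, inverse temperature `beta`,
#'   perseveration `rho`, assignment rate `epsilon`.
#' * `"correct_policy"`, `"incorrect_policy"`, `"random_policy"` — nested
#'   variants with the assignment rate preset to 0 and the arbitration
#'   weight fixed (defaults 0.9 / 0.1 / 0.5; override `fixed_weight`, e.g.
#'   1 or 0, for single-policy validation simulations). Free parameters:
#'   `alpha`, `beta`, `rho`.
#' * `"joint_action"` — a flat temporal-difference learner over the four
#'   joint actions, with the summed centered outcome as its reward. Free
#'   parameters: `alpha`, `beta`, `rho`.
#'
#' @param model Model id.
#' @param fixed_weight Arbitration weight for the fixed-weight variants;
#'   must be `NULL` for `"surprise_min"` and `"joint_action"`.
#' @param counterfactual_mode How the unchosen option of each
#'   policy/decision is updated: `"counterfactual"` subtracts the scaled
#'   prediction error (motivated by the anti-correlated payoffs),
#'   `"lr_decay"` shrinks it by `1 - alpha`, `"free_decay"` shrinks it by
#'   `1 - decay` with `decay` as an extra free parameter. Ignored by
#'   `"joint_action"`.
#' @return A `bandit_model_spec`.
#' @export
model_spec <- function(model = c("surprise_min", "correct_policy",
                                 "incorrect_policy", "random_policy",
                                 "joint_action"),
                       fixed_weight = NULL,
                       counterfactual_mode = c("counterfactual", "lr_decay",
                                               "free_decay")) {
  model <- match.arg(model)
  counterfactual_mode <- match.arg(counterfactual_mode)
  fixed_models <- c(correct_policy = 0.9, incorrect_policy = 0.1,
                    random_policy = 0.5)
  if (model %in% names(fixed_models)) {
    fixed_weight <- fixed_weight %||% unname(fixed_models[model])
    if (fixed_weight < 0 || fixed_weight > 1)
      stop("`fixed_weight` must lie in [0, 1]", call. = FALSE)
    code <- 1L
  } else {
    if (!is.null(fixed_weight))
      stop("`fixed_weight` applies only to the fixed-weight variants",
           call. = FALSE)
    code <- if (model == "surprise_min") 0L else 2L
  }
  pars <- c("alpha", "beta", "rho")
  if (model == "surprise_min") pars <- c(pars, "epsilon")
  if (model != "joint_action" && counterfactual_mode == "free_decay")
    pars <- c(pars, "decay")
  structure(
    list(model = model, code = code, fixed_weight = fixed_weight,
         counterfactual_mode = counterfactual_mode,
         cf_code = match(counterfactual_mode,
                         c("counterfactual", "lr_decay", "free_decay")) - 1L,
         params = pars, k = length(pars)),
    class = "bandit_model_spec")
}

#' @export
print.bandit_model_spec <- function(x, ...) {
  cat(sprintf("<model: %s>", x$model))
  if (!is.null(x$fixed_weight)) cat(sprintf(" fixed weight %g", x$fixed_weight))
  if (x$code != 2L) cat(sprintf(", %s updating", x$counterfactual_mode))
  cat(sprintf("\n  free parameters: %s\n", paste(x$params, collapse = ", ")))
  invisible(x)
}

#' Parameter bounds
#'
#' @param spec A [model_spec()].
#' @return Tibble with `param`, `lower`, `upper`.
#' @export
param_bounds <- function(spec) {
  all <- tibble::tibble(
    param = c("alpha", "beta", "rho", "epsilon", "decay"),
    lower = c(0, 0, -5, 0, 0),
    upper = c(1, 20, 5, 1, 1))
  all[all$param %in% spec$params, ]
}

check_params <- function(spec, params) {
  params <- unlist(params)
  if (!setequal(names(params), spec$params))
    stop(sprintf("model '%s' needs exactly parameters {%s}, got {%s}",
                 spec$model, paste(spec$params, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  b <- param_bounds(spec)
  v <- params[b$param]
  if (any(v < b$lower | v > b$upper))
    stop("parameter(s) outside bounds: ",
         paste(b$param[v < b$lower | v > b$upper], collapse = ", "),
         call. = FALSE)
  as.list(v)
}

run_engine <- function(spec, params, block, o1 = NULL, o2 = NULL,
                       a1 = NULL, a2 = NULL, p = NULL, q = NULL,
                       simulate = FALSE) {
  pr <- check_params(spec, params)
  n <- length(block)
  engine_run(spec$code, spec$fixed_weight %||% 0.5, spec$cf_code,
             pr$alpha, pr$beta, pr$rho, pr$epsilon %||% 0, pr$decay %||% 0,
             as.integer(block),
             as.numeric(o1 %||% rep(NA_real_, n)),
             as.numeric(o2 %||% rep(NA_real_, n)),
             as.integer(a1 %||% rep(NA_integer_, n)),
             as.integer(a2 %||% rep(NA_integer_, n)),
             as.numeric(p %||% rep(NA_real_, n)),
             as.numeric(q %||% rep(NA_real_, n)),
             simulate)
}

# long latent-trace tibble (one row per trial x decision) for the two-policy
# models; the joint-action model keeps a one-row-per-trial trace
build_latents <- function(res, block, trial, spec) {
  if (spec$code == 2L) {
    j <- res$joint
    return(tibble::tibble(
      block = block, trial = trial, joint_action = j$j,
      v_chosen = j$v_chosen, delta = j$delta, p_chosen = j$p_chosen))
  }
  l <- res$latents
  n <- length(block)
  two <- function(x1, x2) c(rbind(x1, x2))
  tibble::tibble(
    block = rep(block, each = 2),
    trial = rep(trial, each = 2),
    decision = rep(1:2, n),
    action = two(res$a1, res$a2),
    p_a1 = two(l$p1_d1, l$p1_d2),
    p_chosen = two(ifelse(res$a1 == 1, l$p1_d1, 1 - l$p1_d1),
                   ifelse(res$a2 == 1, l$p1_d2, 1 - l$p1_d2)),
    v_correct_a1 = two(l$vc_d1_a1, l$vc_d2_a1),
    v_correct_a2 = two(l$vc_d1_a2, l$vc_d2_a2),
    v_incorrect_a1 = two(l$vi_d1_a1, l$vi_d2_a1),
    v_incorrect_a2 = two(l$vi_d1_a2, l$vi_d2_a2),
    d_correct = two(l$vc_d1_a1 - l$vc_d1_a2, l$vc_d2_a1 - l$vc_d2_a2),
    d_incorrect = two(l$vi_d1_a1 - l$vi_d1_a2, l$vi_d2_a1 - l$vi_d2_a2),
    delta_correct = two(l$dc1, l$dc2),
    delta_incorrect = two(l$di1, l$di2),
    surprise_correct = two(l$sc1, l$sc2),
    surprise_incorrect = two(l$si1, l$si2),
    evidence_o1 = rep(l$ev1, each = 2),
    evidence_o2 = rep(l$ev2, each = 2),
    # the evidence attributed to this decision's own outcome color
    evidence = two(l$ev1, l$ev2),
    omega = rep(l$omega, each = 2),
    weight = rep(l$weight, each = 2))
}

#' Simulate an agent on a task
#'
#' Runs the model generatively on the given task blocks: on each trial the
#' choice probabilities are computed from the current values and arbitration
#' weight, both actions are sampled, both outcomes realized from the walks,
#' prediction errors taken against the pre-update values, values updated,
#' and (for the surprise-minimization model) the evidence accumulated into
#' the arbitration weight for the next trial. All state resets at block
#' boundaries.
#'
#' @param task Task tibble from [generate_task()] (columns `block`, `trial`,
#'   `p`, `q`).
#' @param spec A [model_spec()].
#' @param params Named parameter vector or list, see [param_bounds()].
#' @param seed Optional integer seed.
#' @return A `bandit_sim` list with `trials` (block, trial, actions,
#'   outcomes), `latents` (long trace, one row per trial and decision), and
#'   `final_weight` (inverse-logit of the evidence after the last trial).
#' @export
simulate_agent <- function(task, spec, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- run_engine(spec, params, task$block, p = task$p, q = task$q,
                    simulate = TRUE)
  trials <- tibble::tibble(
    block = task$block, trial = task$trial,
    action_d1 = res$a1, action_d2 = res$a2,
    outcome_o1 = res$o1, outcome_o2 = res$o2,
    p = task$p, q = task$q)
  structure(
    list(trials = trials,
         latents = build_latents(res, task$block, task$trial, spec),
         nll = res$nll,
         final_weight = inv_logit(res$omega_final),
         spec = spec, params = check_params(spec, params)),
    class = "bandit_sim")
}

#' @export
print.bandit_sim <- function(x, ...) {
  cat(sprintf("<simulated agent: %s, %d trials in %d block(s)>\n",
              x$spec$model, nrow(x$trials), length(unique(x$trials$block))))
  cat(sprintf("  final arbitration weight %.3f\n", x$final_weight))
  invisible(x)
}

#' Negative log-likelihood of observed choices
#'
#' Replays the model deterministically on observed trial records (both
#' actions and both outcomes per trial) and accumulates
#' `-log P(chosen action)` over trials and decisions, propagating all
#' latents exactly as in [simulate_agent()].
#'
#' @param trials Trial tibble with columns `block`, `trial`, `action_d1`,
#'   `action_d2`, `outcome_o1`, `outcome_o2`.
#' @param spec A [model_spec()].
#' @param params Named parameters.
#' @param latents If `TRUE`, also return the latent trace.
#' @return If `latents = FALSE`, the scalar NLL; otherwise a list with
#'   `nll`, `latents`, and `final_weight`.
#' @export
model_nll <- function(trials, spec, params, latents = FALSE) {
  need <- c("block", "trial", "action_d1", "action_d2",
            "outcome_o1", "outcome_o2")
  if (!all(need %in% names(trials)))
    stop("`trials` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  res <- run_engine(spec, params, trials$block,
                    o1 = trials$outcome_o1, o2 = trials$outcome_o2,
                    a1 = trials$action_d1, a2 = trials$action_d2,
                    simulate = FALSE)
  if (!latents) return(res$nll)
  list(nll = res$nll,
       latents = build_latents(res, trials$block, trials$trial, spec),
       final_weight = inv_logit(res$omega_final))
}

# ---------------------------------------------------------------------------
# single-step reference operations (the model's arithmetic, exposed)

#' Prediction errors of both policies for one trial
#'
#' The correct policy pairs decision 1 with outcome o1 and decision 2 with
#' o2; the incorrect policy pairs them the other way around. Each policy's
#' prediction error is the centered reward of its assigned outcome minus the
#' value of the action actually chosen at that decision.
#'
#' @param values List with 2x2 matrices `correct` and `incorrect`
#'   (rows = decisions, columns = actions).
#' @param outcomes Centered rewards `c(o1, o2)`.
#' @param actions Chosen actions `c(d1, d2)`.
#' @return List with `delta_correct` and `delta_incorrect`, each `c(d1, d2)`.
#' @export
prediction_errors <- function(values, outcomes, actions) {
  ch <- cbind(1:2, actions)
  list(delta_correct = outcomes - values$correct[ch],
       delta_incorrect = rev(outcomes) - values$incorrect[ch])
}

#' Update policy values after one trial
#'
#' The chosen option moves toward the outcome by `alpha * delta`; the
#' unchosen option is updated per the counterfactual mode (see
#' [model_spec()]).
#'
#' @param values List of 2x2 value matrices, as in [prediction_errors()].
#' @param deltas List from [prediction_errors()].
#' @param actions Chosen actions `c(d1, d2)`.
#' @param alpha Learning rate in \[0, 1\].
#' @param counterfactual_mode One of `"counterfactual"`, `"lr_decay"`,
#'   `"free_decay"`.
#' @param decay Decay parameter for `"free_decay"`.
#' @return Updated `values` list.
#' @export
update_values <- function(values, deltas, actions, alpha,
                          counterfactual_mode = "counterfactual",
                          decay = NULL) {
  d_by_policy <- list(correct = deltas$delta_correct,
                      incorrect = deltas$delta_incorrect)
  for (pol in c("correct", "incorrect")) {
    for (d in 1:2) {
      ch <- actions[d]; un <- 3 - ch
      values[[pol]][d, ch] <- values[[pol]][d, ch] + alpha * d_by_policy[[pol]][d]
      values[[pol]][d, un] <- switch(
        counterfactual_mode,
        counterfactual = values[[pol]][d, un] - alpha * d_by_policy[[pol]][d],
        lr_decay = values[[pol]][d, un] * (1 - alpha),
        free_decay = values[[pol]][d, un] * (1 - decay))
    }
  }
  values
}

#' Surprise signal
#'
#' Absolute prediction error, the policy's negative model evidence.
#'
#' @param delta Prediction error(s).
#' @return Nonnegative magnitude(s).
#' @export
surprise <- function(delta) abs(delta)

#' Evidence signals per outcome
#'
#' Each outcome's evidence compares the surprise the two policies attribute
#' to it, which requires pairing surprise signals across decisions: outcome
#' o1 is produced by decision 1 under the correct mapping but claimed by
#' decision 2 under the incorrect one (and vice versa for o2). Positive
#' evidence favors the correct mapping.
#'
#' @param surprise_correct Surprise `c(d1, d2)` of the correct policy.
#' @param surprise_incorrect Surprise `c(d1, d2)` of the incorrect policy.
#' @return Named vector `c(o1, o2)`.
#' @export
evidence <- function(surprise_correct, surprise_incorrect) {
  c(o1 = surprise_incorrect[[2]] - surprise_correct[[1]],
    o2 = surprise_incorrect[[1]] - surprise_correct[[2]])
}

#' Accumulate evidence into the arbitration weight
#'
#' @param omega Current accumulated evidence (log-odds scale).
#' @param ev Evidence pair from [evidence()].
#' @param epsilon Assignment rate in \[0, 1\].
#' @return Updated omega; its [inv_logit()] is the next trial's weight on
#'   the correct policy.
#' @export
update_arbitration <- function(omega, ev, epsilon) {
  omega + epsilon * sum(ev)
}

#' Weighted net action values
#'
#' @param v_correct,v_incorrect Value matrices or vectors.
#' @param weight Arbitration weight in (0, 1).
#' @return `weight * v_correct + (1 - weight) * v_incorrect`.
#' @export
net_values <- function(v_correct, v_incorrect, weight) {
  weight * v_correct + (1 - weight) * v_incorrect
}

#' Softmax choice probabilities with perseveration
#'
#' @param v_net 2x2 matrix of net values (rows = decisions, cols = actions).
#' @param beta Inverse temperature.
#' @param rho Perseveration bonus for repeating the previous action.
#' @param previous Previous actions `c(d1, d2)`; `NA` (first trial of a
#'   block) gives a zero repetition indicator for all actions.
#' @return 2x2 matrix of probabilities, rows summing to 1.
#' @export
choice_probabilities <- function(v_net, beta, rho, previous = c(NA, NA)) {
  out <- matrix(NA_real_, 2, 2)
  for (d in 1:2) {
    rep_ind <- as.numeric(!is.na(previous[d]) & (1:2) == previous[d])
    out[d, ] <- softmax(beta * v_net[d, ] + rho * rep_ind)
  }
  out
}

#' One step of the joint-action model
#'
#' A scalar prediction error over the summed centered outcomes updates the
#' value of the chosen 2x2 joint action; there is no counterfactual
#' updating across joint actions. Joint action `j` encodes
#' `(action_d1 - 1) * 2 + action_d2`.
#'
#' @param values Length-4 value vector over joint actions.
#' @param outcomes Outcomes in points `c(o1, o2)`.
#' @param joint_action Chosen joint action in 1..4.
#' @param params Named list/vector with `alpha`, `beta`, `rho`.
#' @param previous Previously chosen joint action or `NA`.
#' @return List with updated `values`, the choice `probabilities` used for
#'   this trial, and the `delta`.
#' @export
joint_action_step <- function(values, outcomes, joint_action, params,
                              previous = NA) {
  params <- as.list(unlist(params))
  rep_ind <- as.numeric(!is.na(previous) & (1:4) == previous)
  probs <- softmax(params$beta * values + params$rho * rep_ind)
  r <- sum(center_outcome(outcomes))
  delta <- r - values[joint_action]
  values[joint_action] <- values[joint_action] + params$alpha * delta
  list(values = values, probabilities = probs, delta = delta)
}
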