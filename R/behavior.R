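# one-sample t-tests of per-participant coefficients against zero
group_level_ttest <- function(per) {
  per |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_est = mean(.data$estimate),
                     sd_est = sd(.data$estimate),
                     .groups = "drop") |>
    dplyr::transmute(
      term = .data$term, estimate = .data$mean_est,
      statistic = dplyr::if_else(
        .data$n > 1 & !is.na(.data$sd_est) & .data$sd_est > 0,
        .data$mean_est / (.data$sd_est / sqrt(.data$n)), NA_real_),
      df = .data$n - 1L,
      p.value = 2 * pt(-abs(.data$statistic), .data$df),
      n = .data$n)
}

#' Build the stay/switch table
#'
#' Each decision of each trial (from the second trial of a block on)
#' contributes one row: whether the same action was repeated (`stay`), and
#' the previous trial's two outcomes dichotomized to +1 (win) / -1 (loss)
#' and assigned as `relevant` (the outcome produced by this decision under
#' the true mapping) or `irrelevant` (the other decision's outcome). Every
#' outcome therefore appears exactly once as relevant and once as
#' irrelevant across the two rows of a trial.
#'
#' @param trials Trial tibble (optionally with a `participant` column)
#'   containing `block`, `trial`, `action_d1`, `action_d2`, `outcome_o1`,
#'   `outcome_o2`.
#' @param threshold Win threshold (default 50).
#' @return A tibble with columns `participant` (if present), `block`,
#'   `trial`, `decision`, `stay`, `relevant`, `irrelevant`. The number of
#'   first-trial rows dropped is stored in attribute `"n_dropped"`.
#' @export
build_stay_table <- function(trials, threshold = 50) {
  grp <- intersect(c("participant", "block"), names(trials))
  long <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      stay_d1 = as.integer(.data$action_d1 == dplyr::lag(.data$action_d1)),
      stay_d2 = as.integer(.data$action_d2 == dplyr::lag(.data$action_d2)),
      prev_o1 = dplyr::lag(.data$outcome_o1),
      prev_o2 = dplyr::lag(.data$outcome_o2)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$stay_d1))
  n_dropped <- 2L * (nrow(trials) - nrow(long))
  out <- dplyr::bind_rows(
    dplyr::transmute(long, dplyr::across(dplyr::all_of(grp)),
                     trial = .data$trial, decision = 1L,
                     stay = .data$stay_d1,
                     relevant = outcome_sign(.data$prev_o1, threshold),
                     irrelevant = outcome_sign(.data$prev_o2, threshold)),
    dplyr::transmute(long, dplyr::across(dplyr::all_of(grp)),
                     trial = .data$trial, decision = 2L,
                     stay = .data$stay_d2,
                     relevant = outcome_sign(.data$prev_o2, threshold),
                     irrelevant = outcome_sign(.data$prev_o1, threshold))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "trial", "decision"))))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Win-stay/lose-shift logistic regression
#'
#' Per participant, a logistic regression of staying on the previous
#' trial's relevant outcome, irrelevant outcome, and their interaction
#' (`stay ~ relevant * irrelevant`); the per-participant coefficients are
#' then tested against zero with one-sample t-tests at the group level.
#' Participants whose fit separates (deterministic agents) fall back to a
#' weakly penalized fit and are flagged; participants with only one
#' outcome condition are dropped with a warning.
#'
#' With `mode = "mixed"` a single pooled logistic mixed model
#' (`lme4::glmer`, random intercept per participant) is estimated instead;
#' the two-stage summary-statistics approach is the primary mode.
#'
#' @param stay_table Output of [build_stay_table()] with a `participant`
#'   column (added as 1 if absent).
#' @param mode `"two_stage"` (default) or `"mixed"`.
#' @return A `bandit_stay_fit` with `participants` (per-participant
#'   coefficients, `penalized` flag) and `group` (term, mean estimate,
#'   t, df, p). In mixed mode, the `glmer` summary terms.
#' @export
stay_regression <- function(stay_table, mode = c("two_stage", "mixed")) {
  mode <- match.arg(mode)
  if (!"participant" %in% names(stay_table)) stay_table$participant <- 1L
  if (mode == "mixed") {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("mixed mode requires lme4", call. = FALSE)
    fit <- lme4::glmer(stay ~ relevant * irrelevant + (1 | participant),
                       data = stay_table, family = binomial())
    sm <- summary(fit)$coefficients
    group <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                            statistic = sm[, 3],
                            p.value = 2 * pnorm(-abs(sm[, 3])))
    return(structure(list(participants = NULL, group = group, mode = mode,
                          fit = fit),
                     class = "bandit_stay_fit"))
  }
  per <- stay_table |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$relevant)) < 2 || length(unique(d$irrelevant)) < 2) {
        warning("participant dropped: an outcome condition is missing",
                call. = FALSE)
        return(tibble::tibble())
      }
      b <- fit_logistic(stay ~ relevant * irrelevant, d)
      tibble::tibble(term = c("(Intercept)", "relevant", "irrelevant",
                              "relevant:irrelevant"),
                     estimate = unname(b),
                     penalized = attr(b, "penalized"))
    }) |>
    dplyr::ungroup()
  group <- group_level_ttest(per)
  structure(list(participants = per, group = group, mode = mode),
            class = "bandit_stay_fit")
}

#' @export
print.bandit_stay_fit <- function(x, ...) {
  cat(sprintf("<stay regression (%s)>\n", x$mode))
  print(x$group)
  invisible(x)
}

#' Mixed-outcome planned contrast
#'
#' Implicit credit assignment: per participant, the stay probability after
#' a relevant win paired with an irrelevant loss minus the stay
#' probability after a relevant loss paired with an irrelevant win,
#' compared across participants with a Wilcoxon signed-rank test.
#' Unitary outcomes (double win / double loss) are excluded since they do
#' not discriminate the mappings.
#'
#' @param stay_table Output of [build_stay_table()].
#' @return A `bandit_contrast` with per-participant cell probabilities and
#'   differences plus the group test (`z`, `p`).
#' @export
mixed_outcome_contrast <- function(stay_table) {
  if (!"participant" %in% names(stay_table)) stay_table$participant <- 1L
  cells <- stay_table |>
    dplyr::filter(.data$relevant != .data$irrelevant) |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      stay_relwin = mean(.data$stay[.data$relevant == 1]),
      stay_relloss = mean(.data$stay[.data$relevant == -1]),
      .groups = "drop")
  dropped <- cells$participant[!complete.cases(cells)]
  if (length(dropped) > 0)
    warning("participant(s) dropped (empty mixed-outcome cell): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  cells <- cells[complete.cases(cells), ]
  cells$difference <- cells$stay_relwin - cells$stay_relloss
  test <- wilcoxon_z(cells$difference)
  structure(list(participants = cells, test = test),
            class = "bandit_contrast")
}

#' @export
print.bandit_contrast <- function(x, ...) {
  cat("<mixed-outcome contrast (implicit credit assignment)>\n")
  cat(sprintf("  mean stay difference %.3f; Wilcoxon Z = %.2f, p = %.3g (n = %d)\n",
              mean(x$participants$difference), x$test$z, x$test$p, x$test$n))
  invisible(x)
}

#' Per-participant behavioral measures
#'
#' Proportion of wins over all delivered outcomes, the implicit
#' credit-assignment score (mixed-outcome stay-probability difference), and
#' optionally a transfer-task accuracy supplied as data.
#'
#' @param trials Multi-participant trial tibble.
#' @param transfer Optional tibble with `participant` and
#'   `transfer_accuracy` in \[0, 1\].
#' @param threshold Win threshold.
#' @return Tibble with one row per participant.
#' @export
behavioral_measures <- function(trials, transfer = NULL, threshold = 50) {
  if (!"participant" %in% names(trials)) trials$participant <- 1L
  perf <- trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      prop_wins = mean(c(.data$outcome_o1 > threshold,
                         .data$outcome_o2 > threshold)),
      .groups = "drop")
  ica <- mixed_outcome_contrast(build_stay_table(trials, threshold))
  out <- dplyr::left_join(
    perf,
    dplyr::select(ica$participants, "participant",
                  implicit_ca = "difference"),
    by = "participant")
  if (!is.null(transfer))
    out <- dplyr::left_join(out, transfer, by = "participant")
  out
}

#' Chance-level tests of performance measures
#'
#' Wilcoxon signed-rank tests of the proportion of wins (and, if present,
#' transfer accuracy) against the 0.5 chance level. Degenerate inputs
#' (all participants exactly at chance) are reported as such with an `NA`
#' statistic.
#'
#' @param measures Output of [behavioral_measures()].
#' @return Tibble with one row per tested measure.
#' @export
chance_tests <- function(measures) {
  cols <- intersect(c("prop_wins", "transfer_accuracy"), names(measures))
  purrr::map_dfr(cols, function(cl) {
    x <- measures[[cl]]
    x <- x[!is.na(x)]
    res <- wilcoxon_z(x, mu = 0.5)
    dplyr::mutate(res, measure = cl, mean = mean(x),
                  degenerate = res$n == 0, .before = 1)
  })
}

#' Correlations among credit-assignment measures
#'
#' Pairwise Pearson correlations among the behavioral measures; columns
#' with zero variance are reported with `NA` and flagged rather than
#' silently dropped.
#'
#' @param measures Output of [behavioral_measures()].
#' @return Tibble with `measure_1`, `measure_2`, `r`, `statistic`, `df`,
#'   `p.value`, `zero_variance`.
#' @export
measure_correlations <- function(measures) {
  cols <- setdiff(names(measures), "participant")
  cols <- cols[vapply(measures[cols], is.numeric, logical(1))]
  pairs <- utils::combn(cols, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- measures[[pr[1]]]; y <- measures[[pr[2]]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    zv <- sd(x) == 0 || sd(y) == 0
    if (zv || length(x) < 3) {
      return(tibble::tibble(measure_1 = pr[1], measure_2 = pr[2],
                            r = NA_real_, statistic = NA_real_,
                            df = length(x) - 2, p.value = NA_real_,
                            zero_variance = zv))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(measure_1 = pr[1], measure_2 = pr[2],
                   r = unname(ct$estimate), statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p.value = ct$p.value,
                   zero_variance = FALSE)
  })
}

# assemble the per-decision design for the choice-prediction regression:
# pre-choice decision values and weight at trial t, evidence for this
# decision's outcome from trial t - 1
choice_prediction_data <- function(latents) {
  if (!"participant" %in% names(latents)) latents$participant <- 1L
  latents |>
    dplyr::group_by(.data$participant, .data$block, .data$decision) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(evidence_prev = dplyr::lag(.data$evidence)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$evidence_prev)) |>
    dplyr::transmute(.data$participant, .data$block, .data$trial,
                     .data$decision,
                     choice = as.integer(.data$action == 1),
                     d_correct = .data$d_correct,
                     d_incorrect = .data$d_incorrect,
                     evidence = .data$evidence_prev,
                     weight = .data$weight)
}

#' Choice prediction from model latents
#'
#' Per participant, a logistic regression of the chosen action on the
#' decision values of both policies (`D = V(a1) - V(a2)`), the evidence
#' signal, the arbitration weight, and the decision-value interactions
#' with both; coefficients are then tested against zero at the group
#' level. A follow-up splits each participant's observations into weight
#' tertiles (ties to the lower tertile) and re-estimates the two
#' decision-value effects per tertile: under surprise-minimization
#' arbitration the correct-policy effect grows and the incorrect-policy
#' effect shrinks from low to high weights.
#'
#' Constant columns (e.g. the weight in fixed-weight agents) are dropped
#' from the design and listed in `dropped_terms`.
#'
#' @param latents Latent trace(s) from [model_nll()] or [simulate_agent()],
#'   optionally with a `participant` column.
#' @return A `bandit_choice_pred` with `participants`, `group`,
#'   `tertiles` (group-level effects per weight tertile), and
#'   `dropped_terms`.
#' @export
choice_prediction_regression <- function(latents) {
  dat <- choice_prediction_data(latents)
  base_terms <- c("d_correct", "d_incorrect", "evidence", "weight")
  constant <- base_terms[vapply(dat[base_terms],
                                function(x) sd(x) == 0, logical(1))]
  if (length(constant) > 0)
    warning("constant regressor(s) dropped from the choice model: ",
            paste(constant, collapse = ", "), call. = FALSE)
  keep <- setdiff(base_terms, constant)
  inter <- c()
  if ("evidence" %in% keep)
    inter <- c(inter, intersect(c("d_correct", "d_incorrect"), keep) |>
                 paste0(":evidence"))
  if ("weight" %in% keep)
    inter <- c(inter, intersect(c("d_correct", "d_incorrect"), keep) |>
                 paste0(":weight"))
  rhs <- paste(c(keep, inter), collapse = " + ")
  form <- stats::as.formula(paste("choice ~", rhs))
  per <- dat |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      b <- fit_logistic(form, d)
      tibble::tibble(term = names(b), estimate = unname(b),
                     penalized = attr(b, "penalized"))
    }) |>
    dplyr::ungroup()
  group <- group_level_ttest(per)
  # tertile follow-up on the decision-value effects
  tert <- dat |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(tertile = tertile_of(.data$weight)) |>
    dplyr::group_by(.data$participant, .data$tertile) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 8 || sd(d$d_correct) == 0 || sd(d$d_incorrect) == 0)
        return(tibble::tibble())
      b <- fit_logistic(choice ~ d_correct + d_incorrect, d)
      tibble::tibble(term = names(b), estimate = unname(b))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$term %in% c("d_correct", "d_incorrect")) |>
    dplyr::group_by(.data$tertile, .data$term) |>
    dplyr::summarise(estimate = mean(.data$estimate), n = dplyr::n(),
                     .groups = "drop")
  structure(list(participants = per, group = group, tertiles = tert,
                 dropped_terms = constant),
            class = "bandit_choice_pred")
}

#' @export
print.bandit_choice_pred <- function(x, ...) {
  cat("<choice-prediction regression>\n")
  print(x$group)
  if (length(x$dropped_terms) > 0)
    cat("dropped constant terms:", paste(x$dropped_terms, collapse = ", "),
        "\n")
  invisible(x)
}

#' Regress behavioral measures on fitted parameters
#'
#' Ordinary least squares of each behavioral measure on the four fitted
#' parameters (`measure ~ alpha + beta + rho + epsilon`), with coefficient
#' t-statistics. A high design condition number (collinear parameters)
#' triggers a warning.
#'
#' @param params Tibble with `participant` and parameter columns.
#' @param measures Output of [behavioral_measures()].
#' @param measure_cols Measures to model; defaults to every numeric
#'   measure column.
#' @return Tibble of per-measure coefficient tests.
#' @export
parameter_behavior_regression <- function(params, measures,
                                          measure_cols = NULL) {
  dat <- dplyr::inner_join(params, measures, by = "participant")
  pcols <- intersect(c("alpha", "beta", "rho", "epsilon"), names(params))
  measure_cols <- measure_cols %||%
    setdiff(names(measures)[vapply(measures, is.numeric, logical(1))],
            c("participant"))
  if (nrow(dat) < length(pcols) + 2)
    stop("need more participants than coefficients", call. = FALSE)
  x <- as.matrix(dat[, pcols])
  kp <- kappa(cbind(1, scale(x)), exact = TRUE)
  if (kp > 100)
    warning(sprintf("parameter design is ill-conditioned (kappa = %.1f)", kp),
            call. = FALSE)
  purrr::map_dfr(measure_cols, function(m) {
    form <- stats::as.formula(paste(m, "~", paste(pcols, collapse = " + ")))
    fit <- lm(form, data = dat)
    sm <- summary(fit)$coefficients
    tibble::tibble(measure = m, term = rownames(sm), estimate = sm[, 1],
                   std.error = sm[, 2], statistic = sm[, 3],
                   p.value = sm[, 4])
  })
}
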