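#' Tidy a MAP fit
#'
#' @param x A `bandit_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @export
tidy.bandit_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' Glance at a MAP fit
#'
#' @param x A `bandit_fit`.
#' @param ... Unused.
#' @return One-row tibble with model id, NLL, information criteria, and
#'   fit diagnostics.
#' @export
glance.bandit_fit <- function(x, ...) {
  tibble::tibble(model = x$model, k = x$k, nll = x$nll,
                 aic = x$aic, bic = x$bic, n_obs = x$n_obs,
                 converged = x$converged)
}

#' Tidy a model-selection result
#'
#' @param x A `bandit_bms`.
#' @param ... Unused.
#' @return Tibble with Dirichlet concentration, expected frequency, and
#'   exceedance probability per model.
#' @export
tidy.bandit_bms <- function(x, ...) {
  tibble::tibble(model = x$models, alpha = unname(x$alpha),
                 expected_freq = unname(x$expected_freq),
                 xp = unname(x$xp))
}

#' Tidy a stay regression
#'
#' @param x A `bandit_stay_fit`.
#' @param ... Unused.
#' @return The group-level coefficient table.
#' @export
tidy.bandit_stay_fit <- function(x, ...) x$group

#' Tidy a choice-prediction regression
#'
#' @param x A `bandit_choice_pred`.
#' @param ... Unused.
#' @return The group-level coefficient table.
#' @export
tidy.bandit_choice_pred <- function(x, ...) x$group

#' Tidy a cluster-permutation result
#'
#' @param x A `bandit_clusters`.
#' @param ... Unused.
#' @return The cluster table (id, sign, extent, mass, p-value).
#' @export
tidy.bandit_clusters <- function(x, ...) x$clusters

#' Glance at a cluster-permutation result
#'
#' @param x A `bandit_clusters`.
#' @param ... Unused.
#' @return One-row tibble with permutation settings and the number of
#'   clusters below the family-wise threshold.
#' @export
glance.bandit_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$p.value <= 0.05),
                 n_perm = x$n_perm, exact = x$exact,
                 threshold = x$threshold)
}

#' Tidy a parameter-recovery result
#'
#' @param x A `bandit_recovery`.
#' @param ... Unused.
#' @return The generating-versus-recovered correlation table.
#' @export
tidy.bandit_recovery <- function(x, ...) x$correlations
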