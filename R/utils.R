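#' Inverse logit
#'
#' Logistic squashing of the accumulated evidence onto the (0, 1) arbitration
#' scale. Clamped at |x| = 700 so that an unbounded evidence sum never
#' overflows the exponential.
#'
#' @param x Numeric vector on the log-odds scale.
#' @return Numeric vector in (0, 1).
#' @export
inv_logit <- function(x) {
  x <- pmin(pmax(x, -700), 700)
  1 / (1 + exp(-x))
}

#' Numerically stable softmax
#'
#' @param u Numeric vector of utilities.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

#' Paired Wilcoxon signed-rank test with normal approximation
#'
#' Computes the signed-rank statistic for paired differences, dropping exact
#' zeros and averaging tied ranks, and reports the Z statistic of the normal
#' approximation (with tie correction, no continuity correction). At complete
#' separation of n pairs the statistic attains its maximum
#' (n(n+1)/4) / sqrt(n(n+1)(2n+1)/24).
#'
#' @param x Numeric vector (first condition, or differences if `y` is NULL).
#' @param y Optional numeric vector paired with `x`.
#' @param mu Null value for the location of `x - y` (default 0).
#' @return A tibble with columns `n` (non-zero pairs), `v` (sum of positive
#'   ranks), `z`, and `p` (two-sided normal approximation).
#' @export
wilcoxon_z <- function(x, y = NULL, mu = 0) {
  d <- if (is.null(y)) x - mu else x - y - mu
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(n = 0L, v = NA_real_, z = NA_real_, p = NA_real_))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu_v <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu_v) / sqrt(sigma2)
  tibble::tibble(n = n, v = v, z = z, p = 2 * pnorm(-abs(z)))
}

#' MAP logistic regression with a Gaussian coefficient prior
#'
#' Weakly penalized logistic fit used as a deterministic fallback when a
#' per-participant maximum-likelihood fit separates (coefficients diverge).
#' The Gaussian prior (sd `prior_sd` on all coefficients except the
#' intercept, which gets a wide prior) keeps estimates finite while leaving
#' the sign and ordering of effects intact.
#'
#' @param x Model matrix including the intercept column.
#' @param y 0/1 response vector.
#' @param prior_sd Prior standard deviation for non-intercept coefficients.
#' @return Named coefficient vector.
#' @export
penalized_logistic <- function(x, y, prior_sd = 2.5) {
  stopifnot(nrow(x) == length(y))
  sds <- c(10, rep(prior_sd, ncol(x) - 1))
  obj <- function(b) {
    eta <- drop(x %*% b)
    # -log lik + Gaussian penalty
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + sum(b^2 / (2 * sds^2))
  }
  grad <- function(b) {
    p <- inv_logit(drop(x %*% b))
    drop(crossprod(x, p - y)) + b / sds^2
  }
  fit <- optim(rep(0, ncol(x)), obj, grad, method = "BFGS",
               control = list(maxit = 500))
  setNames(fit$par, colnames(x))
}

# glm wrapper that detects separation / non-convergence and falls back to the
# penalized MAP fit; returns coefficients plus a `penalized` flag
fit_logistic <- function(formula, data, prior_sd = 2.5, coef_limit = 15) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(formula, mf)
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  b <- coef(fit)
  bad <- !fit$converged || anyNA(b) || any(abs(b) > coef_limit)
  if (bad) {
    b <- penalized_logistic(x, as.numeric(y), prior_sd = prior_sd)
    attr(b, "penalized") <- TRUE
  } else {
    attr(b, "penalized") <- FALSE
  }
  b
}

# deterministic tertile assignment: breaks are the 1/3 and 2/3 empirical
# quantiles (type 1); values equal to a break fall in the lower tertile
tertile_of <- function(x) {
  q <- quantile(x, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  1L + (x > q[1]) + (x > q[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
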