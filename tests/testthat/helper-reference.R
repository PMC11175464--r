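# Independent slow reference implementations used as oracles. These are
# written trial-by-trial from the model equations, deliberately sharing no
# code with the package's engine.

# two-policy model NLL via an explicit R loop over trials and decisions
reference_nll <- function(trials, alpha, beta, rho, epsilon,
                          fixed_weight = NULL,
                          cf_mode = c("counterfactual", "lr_decay",
                                      "free_decay"),
                          decay = 0) {
  cf_mode <- match.arg(cf_mode)
  nll <- 0
  for (b in unique(trials$block)) {
    tb <- trials[trials$block == b, ]
    Vc <- matrix(0, 2, 2); Vi <- matrix(0, 2, 2)
    om <- 0
    prev <- c(NA, NA)
    for (i in seq_len(nrow(tb))) {
      w <- if (is.null(fixed_weight)) stats::plogis(om) else fixed_weight
      acts <- c(tb$action_d1[i], tb$action_d2[i])
      for (d in 1:2) {
        vnet <- w * Vc[d, ] + (1 - w) * Vi[d, ]
        u <- beta * vnet + rho * as.numeric(!is.na(prev[d]) & 1:2 == prev[d])
        pr <- exp(u) / sum(exp(u))
        nll <- nll - log(pr[acts[d]])
      }
      r <- c(tb$outcome_o1[i], tb$outcome_o2[i]) / 50 - 1
      dc <- c(r[1] - Vc[1, acts[1]], r[2] - Vc[2, acts[2]])
      di <- c(r[2] - Vi[1, acts[1]], r[1] - Vi[2, acts[2]])
      for (d in 1:2) {
        ch <- acts[d]; un <- 3 - ch
        Vc[d, ch] <- Vc[d, ch] + alpha * dc[d]
        Vi[d, ch] <- Vi[d, ch] + alpha * di[d]
        if (cf_mode == "counterfactual") {
          Vc[d, un] <- Vc[d, un] - alpha * dc[d]
          Vi[d, un] <- Vi[d, un] - alpha * di[d]
        } else if (cf_mode == "lr_decay") {
          Vc[d, un] <- Vc[d, un] * (1 - alpha)
          Vi[d, un] <- Vi[d, un] * (1 - alpha)
        } else {
          Vc[d, un] <- Vc[d, un] * (1 - decay)
          Vi[d, un] <- Vi[d, un] * (1 - decay)
        }
      }
      ev <- c(abs(di[2]) - abs(dc[1]), abs(di[1]) - abs(dc[2]))
      if (is.null(fixed_weight)) om <- om + epsilon * sum(ev)
      prev <- acts
    }
  }
  nll
}

# single-policy temporal-difference learner with counterfactual updating;
# `mapping = "relevant"` learns each decision from its own outcome,
# `"irrelevant"` from the other decision's outcome
td_learner_nll <- function(trials, alpha, beta, rho,
                           mapping = c("relevant", "irrelevant")) {
  mapping <- match.arg(mapping)
  nll <- 0
  for (b in unique(trials$block)) {
    tb <- trials[trials$block == b, ]
    V <- matrix(0, 2, 2)
    prev <- c(NA, NA)
    for (i in seq_len(nrow(tb))) {
      acts <- c(tb$action_d1[i], tb$action_d2[i])
      for (d in 1:2) {
        u <- beta * V[d, ] + rho * as.numeric(!is.na(prev[d]) & 1:2 == prev[d])
        pr <- exp(u - max(u)) / sum(exp(u - max(u)))
        nll <- nll - log(pr[acts[d]])
      }
      r <- c(tb$outcome_o1[i], tb$outcome_o2[i]) / 50 - 1
      if (mapping == "irrelevant") r <- rev(r)
      for (d in 1:2) {
        ch <- acts[d]; un <- 3 - ch
        del <- r[d] - V[d, ch]
        V[d, ch] <- V[d, ch] + alpha * del
        V[d, un] <- V[d, un] - alpha * del
      }
      prev <- acts
    }
  }
  nll
}

# joint-action model NLL by explicit loop
reference_joint_nll <- function(trials, alpha, beta, rho) {
  nll <- 0
  for (b in unique(trials$block)) {
    tb <- trials[trials$block == b, ]
    V <- rep(0, 4)
    prev <- NA
    for (i in seq_len(nrow(tb))) {
      j <- (tb$action_d1[i] - 1) * 2 + tb$action_d2[i]
      u <- beta * V + rho * as.numeric(!is.na(prev) & 1:4 == prev)
      pr <- exp(u - max(u)) / sum(exp(u - max(u)))
      nll <- nll - log(pr[j])
      r <- sum(c(tb$outcome_o1[i], tb$outcome_o2[i]) / 50 - 1)
      V[j] <- V[j] + alpha * (r - V[j])
      prev <- j
    }
  }
  nll
}

# normal-approximation signed-rank Z, coded independently of wilcoxon_z
reference_signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  ew <- n * (n + 1) / 4
  tie_tab <- table(rk)
  varw <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  (w_pos - ew) / sqrt(varw)
}

# per-point OLS via lm(), the brute-force check for the mass GLM
reference_mass_glm <- function(ep, design) {
  regs <- attr(design, "regressors")
  X <- as.data.frame(design[, regs])
  out <- array(NA_real_, c(length(regs) + 1, dim(ep$data)[2], dim(ep$data)[3]))
  for (ch in seq_len(dim(ep$data)[2])) {
    for (s in seq_len(dim(ep$data)[3])) {
      df <- cbind(y = ep$data[, ch, s], X)
      fit <- lm(y ~ ., data = df)
      out[, ch, s] <- coef(fit)
    }
  }
  out
}
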