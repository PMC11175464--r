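#' Construct an epochs object
#'
#' A light container for epoched EEG: an events x channels x time numeric
#' array (microvolts) plus channel labels, a uniformly spaced time vector
#' (seconds relative to the lock event), the sampling rate, and one row of
#' event metadata per epoch.
#'
#' @param data Numeric array, events x channels x time.
#' @param channels Channel labels.
#' @param times Time vector (seconds); must be strictly increasing with
#'   spacing `1/sampling_rate`.
#' @param sampling_rate Sampling rate in Hz.
#' @param events Tibble with one row per event (trial metadata, event kind).
#' @return A `bandit_epochs`.
#' @export
epochs <- function(data, channels, times, sampling_rate, events) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != nrow(events))
    stop("`events` must have one row per epoch", call. = FALSE)
  if (dim(data)[2] != length(channels) || dim(data)[3] != length(times))
    stop("array dimensions must match `channels` and `times`", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1 / sampling_rate)) > 1e-6)
    stop("`times` must increase uniformly at 1/sampling_rate", call. = FALSE)
  structure(list(data = data, channels = channels, times = times,
                 sampling_rate = sampling_rate,
                 events = tibble::as_tibble(events)),
            class = "bandit_epochs")
}

#' @export
print.bandit_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs: %d events x %d channels x %d samples @ %g Hz, %.0f-%.0f ms>\n",
              d[1], d[2], d[3], x$sampling_rate,
              1000 * min(x$times), 1000 * max(x$times)))
  invisible(x)
}

#' A small default montage
#'
#' 16 channels from the 10-20 system on a schematic 2-D head layout, read
#' from the montage table shipped with the package. Used as the default
#' spatial layout for synthetic epochs and for the channel adjacency of the
#' cluster tests.
#'
#' @return Tibble with `channel`, `x`, `y`.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage16.tsv", package = "surprisemin")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Channel adjacency from a montage
#'
#' Two channels are neighbors when their planar distance is at most
#' `max_dist`. The result is a named list of neighbor labels, symmetric by
#' construction.
#'
#' @param montage Tibble with `channel`, `x`, `y` (default
#'   [default_montage()]).
#' @param max_dist Neighbor distance threshold in montage units.
#' @return Named list, channel -> character vector of neighbors.
#' @export
montage_adjacency <- function(montage = default_montage(), max_dist = 1.1) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  nb <- lapply(seq_len(nrow(montage)), function(i) {
    montage$channel[d[i, ] > 0 & d[i, ] <= max_dist]
  })
  setNames(nb, montage$channel)
}

check_adjacency <- function(adjacency, channels) {
  if (!all(channels %in% names(adjacency)))
    stop("adjacency must cover all channels", call. = FALSE)
  for (ch in channels) {
    for (nb in adjacency[[ch]]) {
      if (nb %in% channels && !(ch %in% adjacency[[nb]]))
        stop("adjacency is not symmetric at ", ch, " / ", nb, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# 0-based integer neighbor list restricted to the used channels
adjacency_index <- function(adjacency, channels) {
  lapply(channels, function(ch) {
    idx <- match(intersect(adjacency[[ch]], channels), channels) - 1L
    as.integer(idx)
  })
}

#' Event table for model-based EEG designs
#'
#' Expands a latent trace into per-event rows: two feedback-locked events
#' per trial (one per outcome color) or two response-locked events per
#' trial (one per decision).
#'
#' @param latents Latent trace from [simulate_agent()] or [model_nll()].
#' @param lock `"feedback"` or `"response"`.
#' @return Tibble with `block`, `trial`, `event` (`o1`/`o2` or `d1`/`d2`)
#'   and, if present in `latents`, `participant`.
#' @export
build_events <- function(latents, lock = c("feedback", "response")) {
  lock <- match.arg(lock)
  keep <- intersect(c("participant", "block", "trial", "decision"),
                    names(latents))
  ev <- dplyr::distinct(latents[, keep])
  ev$event <- paste0(if (lock == "feedback") "o" else "d", ev$decision)
  dplyr::select(ev, -"decision")
}

#' Build a model-based design matrix
#'
#' One row per event-locked epoch with the latent-variable regressors of
#' the single-trial EEG model: the prediction errors each policy attributes
#' to the event, the evidence signal, and the arbitration weight.
#'
#' For a feedback event showing outcome `o_i`: the correct policy assigns
#' `o_i` to decision `i`, the incorrect policy to the other decision, so
#' `pe_correct = delta_correct(d_i)`, `pe_incorrect = delta_incorrect(d_j)`
#' (j != i), and `evidence = surprise_incorrect(d_j) -
#' surprise_correct(d_i)`. For a response event of decision `d_i` all
#' quantities are taken within that decision, with the response-locked
#' evidence recombined as `surprise_incorrect(d_i) -
#' surprise_correct(d_i)`.
#'
#' All regressors are z-scored per participant; a constant column is
#' dropped and recorded in attribute `"dropped"`.
#'
#' @param latents Latent trace.
#' @param lock `"feedback"` or `"response"`.
#' @return Tibble of event metadata plus z-scored regressors
#'   `pe_correct`, `pe_incorrect`, `evidence`, `weight`.
#' @export
build_design <- function(latents, lock = c("feedback", "response")) {
  lock <- match.arg(lock)
  if (!"participant" %in% names(latents)) latents$participant <- 1L
  wide <- latents |>
    dplyr::select("participant", "block", "trial", "decision",
                  "delta_correct", "delta_incorrect",
                  "surprise_correct", "surprise_incorrect",
                  "evidence_o1", "evidence_o2", "weight") |>
    tidyr::pivot_wider(names_from = "decision",
                       values_from = c("delta_correct", "delta_incorrect",
                                       "surprise_correct",
                                       "surprise_incorrect"),
                       names_sep = "_d")
  per_event <- function(i) {
    j <- 3 - i
    if (lock == "feedback") {
      tibble::tibble(
        participant = wide$participant, block = wide$block,
        trial = wide$trial, event = paste0("o", i),
        pe_correct = wide[[paste0("delta_correct_d", i)]],
        pe_incorrect = wide[[paste0("delta_incorrect_d", j)]],
        evidence = wide[[paste0("surprise_incorrect_d", j)]] -
          wide[[paste0("surprise_correct_d", i)]],
        weight = wide$weight)
    } else {
      tibble::tibble(
        participant = wide$participant, block = wide$block,
        trial = wide$trial, event = paste0("d", i),
        pe_correct = wide[[paste0("delta_correct_d", i)]],
        pe_incorrect = wide[[paste0("delta_incorrect_d", i)]],
        evidence = wide[[paste0("surprise_incorrect_d", i)]] -
          wide[[paste0("surprise_correct_d", i)]],
        weight = wide$weight)
    }
  }
  out <- dplyr::bind_rows(per_event(1), per_event(2)) |>
    dplyr::arrange(.data$participant, .data$block, .data$trial, .data$event)
  regs <- c("pe_correct", "pe_incorrect", "evidence", "weight")
  dropped <- character(0)
  for (r in regs) {
    out <- out |>
      dplyr::group_by(.data$participant) |>
      dplyr::mutate(!!r := if (sd(.data[[r]]) == 0) .data[[r]] else
        as.numeric(scale(.data[[r]]))) |>
      dplyr::ungroup()
    if (any(tapply(out[[r]], out$participant, sd) == 0)) {
      dropped <- c(dropped, r)
    }
  }
  if (length(dropped) > 0) {
    warning("constant regressor(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    out <- out[, setdiff(names(out), dropped)]
  }
  attr(out, "regressors") <- setdiff(regs, dropped)
  attr(out, "lock") <- lock
  out
}

design_regressors <- function(design) {
  attr(design, "regressors") %||%
    intersect(c("pe_correct", "pe_incorrect", "evidence", "weight"),
              names(design))
}

#' Simulate epoched EEG with planted latent-variable effects
#'
#' Each epoch is a weighted sum of planted effects — a regression
#' coefficient times a channel profile times a time profile times the
#' event's (z-scored) regressor value — plus temporally autocorrelated,
#' spatially smoothed Gaussian noise. Ground-truth effects are stored in
#' attribute `"effects"` for recovery checks.
#'
#' @param design Design tibble from [build_design()] (one participant).
#' @param effects List of planted effects; each element is a list with
#'   `regressor`, `beta`, `channels` (named numeric profile over a subset
#'   of channels), and `window` (`c(start, end)` seconds, realized as a
#'   raised-cosine time profile).
#' @param montage Montage tibble; its channels define the array.
#' @param times Time vector in seconds.
#' @param noise List with `sd` (noise scale), `ar` (lag-one
#'   autocorrelation), and `spatial` (0-1 neighbor mixing).
#' @param seed Optional integer seed.
#' @return A `bandit_epochs`.
#' @export
simulate_epochs <- function(design, effects = list(),
                            montage = default_montage(),
                            times = seq(0, 0.996, by = 1 / 250),
                            noise = list(sd = 1, ar = 0.6, spatial = 0.3),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ev <- nrow(design)
  chs <- montage$channel
  n_ch <- length(chs)
  n_t <- length(times)
  srate <- round(1 / diff(times)[1])
  dat <- array(rnorm(n_ev * n_ch * n_t, sd = noise$sd %||% 1),
               dim = c(n_ev, n_ch, n_t))
  ar <- noise$ar %||% 0
  if (ar > 0) { # lag-one recursive filter along time, per event x channel
    sc <- sqrt(1 - ar^2) # keep the marginal variance at sd^2
    for (s in 2:n_t) dat[, , s] <- ar * dat[, , s - 1] + sc * dat[, , s]
  }
  sp <- noise$spatial %||% 0
  if (sp > 0) {
    adj <- montage_adjacency(montage)
    mix <- diag(n_ch)
    for (i in seq_len(n_ch)) {
      nb <- match(adj[[chs[i]]], chs)
      if (length(nb) > 0) mix[i, nb] <- sp / length(nb)
    }
    mix <- mix / rowSums(mix)
    for (s in seq_len(n_t)) dat[, , s] <- dat[, , s] %*% t(mix)
  }
  for (ef in effects) {
    if (!ef$regressor %in% names(design))
      stop("unknown regressor in effect: ", ef$regressor, call. = FALSE)
    chan_prof <- rep(0, n_ch)
    idx <- match(names(ef$channels), chs)
    if (anyNA(idx)) stop("effect channels not in montage", call. = FALSE)
    chan_prof[idx] <- as.numeric(ef$channels)
    tp <- rep(0, n_t)
    inw <- times >= ef$window[1] & times <= ef$window[2]
    if (!any(inw)) stop("effect window outside `times`", call. = FALSE)
    ph <- (times[inw] - ef$window[1]) / diff(ef$window)
    tp[inw] <- 0.5 - 0.5 * cos(2 * pi * ph) # raised cosine bump
    x <- design[[ef$regressor]]
    map <- outer(chan_prof, tp) # channels x time
    for (e in seq_len(n_ev)) {
      dat[e, , ] <- dat[e, , ] + ef$beta * x[e] * map
    }
  }
  ep <- epochs(dat, chs, times, srate,
               design[, setdiff(names(design), design_regressors(design))])
  attr(ep, "effects") <- effects
  ep
}

#' Mass-univariate single-trial GLM
#'
#' Ordinary least squares of the single-trial EEG signal at every channel
#' and time point on the design's regressors (plus intercept), for one
#' participant. Beta weights are standardized by their standard deviation
#' — by default the standard error of the per-point OLS estimate, which
#' also penalizes multicollinearity; residual-SD scaling is available as
#' an alternative.
#'
#' @param ep A `bandit_epochs`.
#' @param design Design tibble from [build_design()]; row order must match
#'   the epochs.
#' @param standardize `"se"` (default), `"resid"`, or `"none"`.
#' @return A `mass_glm` with arrays `beta` and `beta_std` (regressors x
#'   channels x time, intercept included), channels, times, regressors.
#' @export
mass_glm <- function(ep, design, standardize = c("se", "resid", "none")) {
  standardize <- match.arg(standardize)
  regs <- design_regressors(design)
  n_ev <- dim(ep$data)[1]
  if (nrow(design) != n_ev)
    stop("design rows must match epochs", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(design[, regs]))
  p <- ncol(X)
  if (n_ev <= p) stop("need more events than regressors", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_ch <- dim(ep$data)[2]; n_t <- dim(ep$data)[3]
  Y <- matrix(ep$data, n_ev, n_ch * n_t)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y) # p x (ch*time)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n_ev - p)
  Bstd <- switch(standardize,
                 none = B,
                 resid = sweep(B, 2, sqrt(sigma2), "/"),
                 se = B / sqrt(outer(diag(XtXinv), sigma2)))
  shape <- c(p, n_ch, n_t)
  dn <- list(colnames(X), ep$channels, NULL)
  structure(
    list(beta = array(B, shape, dimnames = dn),
         beta_std = array(Bstd, shape, dimnames = dn),
         regressors = colnames(X), channels = ep$channels,
         times = ep$times, standardize = standardize, n_events = n_ev),
    class = "mass_glm")
}

#' @export
print.mass_glm <- function(x, ...) {
  cat(sprintf("<mass-univariate GLM: %d regressors x %d channels x %d samples (%d events, %s-standardized)>\n",
              length(x$regressors), length(x$channels), length(x$times),
              x$n_events, x$standardize))
  invisible(x)
}

#' Stack one regressor's standardized betas across participants
#'
#' @param glms List of `mass_glm` objects (one per participant).
#' @param regressor Regressor name.
#' @return Participants x channels x time array.
#' @export
stack_betas <- function(glms, regressor) {
  mats <- lapply(glms, function(g) g$beta_std[regressor, , ])
  arr <- array(NA_real_, c(length(glms), dim(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  dimnames(arr) <- list(NULL, glms[[1]]$channels, NULL)
  arr
}

#' Two-tailed cluster-based permutation test
#'
#' One-sample t-tests of per-participant beta maps against zero at every
#' channel x time point; points with uncorrected two-tailed p below
#' `cluster_alpha` are grouped into signed clusters under channel
#' adjacency plus consecutive-sample time adjacency, each cluster scored
#' by its mass (sum of t). The family-wise null distribution of the
#' maximal absolute cluster mass is built by randomly sign-flipping
#' participants; when the requested permutations exceed the number of
#' unique sign assignments, all flips are enumerated exactly.
#'
#' @param betas Participants x channels x time array (see
#'   [stack_betas()]).
#' @param adjacency Named neighbor list over the channels (see
#'   [montage_adjacency()]).
#' @param channels Channel labels; defaults to `dimnames(betas)[[2]]`.
#' @param times Optional time vector for reporting.
#' @param cluster_alpha Uncorrected threshold for cluster formation.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A `bandit_clusters` with a tidy cluster table (mass, sign,
#'   extent, permutation p), the observed t-map, cluster labels, and the
#'   null distribution.
#' @export
cluster_permutation <- function(betas, adjacency, channels = NULL,
                                times = NULL, cluster_alpha = 0.05,
                                n_perm = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(dim(betas)) == 3)
  n <- dim(betas)[1]
  if (n < 2) stop("need at least two participants", call. = FALSE)
  channels <- channels %||% dimnames(betas)[[2]] %||%
    paste0("ch", seq_len(dim(betas)[2]))
  check_adjacency(adjacency, channels)
  adj_idx <- adjacency_index(adjacency, channels)
  n_ch <- dim(betas)[2]; n_t <- dim(betas)[3]
  thresh <- qt(1 - cluster_alpha / 2, df = n - 1)
  X <- matrix(betas, n, n_ch * n_t)
  ssq <- colSums(X^2) # invariant under sign flips
  tmap_from_signs <- function(s) {
    m <- drop(s %*% X) / n
    v <- (ssq - n * m^2) / (n - 1)
    matrix(m / sqrt(v / n), n_ch, n_t)
  }
  tobs <- tmap_from_signs(matrix(1, 1, n))
  lab <- cluster_label_cpp(tobs, thresh, adj_idx)
  exact <- 2^n <= n_perm
  signs <- if (exact) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  null_max <- apply(signs, 1, function(s)
    cluster_max_mass_cpp(tmap_from_signs(matrix(s, 1, n)), thresh, adj_idx))
  masses <- lab$mass
  p <- vapply(masses, function(m) {
    (1 + sum(null_max >= abs(m))) / (length(null_max) + 1)
  }, numeric(1))
  tab <- if (length(masses) == 0) {
    tibble::tibble(cluster = integer(0), sign = integer(0),
                   n_points = integer(0), channels = character(0),
                   t_start = numeric(0), t_end = numeric(0),
                   mass = numeric(0), p.value = numeric(0))
  } else {
    purrr::map_dfr(seq_along(masses), function(k) {
      pts <- which(lab$labels == k, arr.ind = TRUE)
      tibble::tibble(
        cluster = k, sign = lab$sign[k], n_points = nrow(pts),
        channels = paste(sort(unique(channels[pts[, 1]])), collapse = ","),
        t_start = if (is.null(times)) min(pts[, 2]) else min(times[pts[, 2]]),
        t_end = if (is.null(times)) max(pts[, 2]) else max(times[pts[, 2]]),
        mass = masses[k], p.value = p[k])
    }) |> dplyr::arrange(.data$p.value, dplyr::desc(abs(.data$mass)))
  }
  structure(
    list(clusters = tab, tmap = tobs, labels = lab$labels,
         channels = channels, times = times, threshold = thresh,
         null_max = null_max, n_perm = length(null_max), exact = exact),
    class = "bandit_clusters")
}

#' @export
print.bandit_clusters <- function(x, ...) {
  cat(sprintf("<cluster permutation: %d cluster(s), %d permutations%s>\n",
              nrow(x$clusters), x$n_perm,
              if (x$exact) " (exact enumeration)" else ""))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Downsample epochs by an integer factor
#'
#' Anti-alias FIR low-pass filtering (zero-phase, order-30 Hamming window
#' at the new Nyquist) followed by decimation. The target rate must divide
#' the original sampling rate.
#'
#' @param ep A `bandit_epochs`.
#' @param target_rate Target sampling rate in Hz.
#' @return Downsampled `bandit_epochs`; event metadata preserved.
#' @export
downsample_epochs <- function(ep, target_rate) {
  q <- ep$sampling_rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("`target_rate` must divide the sampling rate", call. = FALSE)
  q <- as.integer(round(q))
  if (q == 1L) return(ep)
  h <- signal::fir1(30, 1 / q)
  h <- h / sum(h) # unit DC gain so constant signals pass through exactly
  n_ev <- dim(ep$data)[1]; n_ch <- dim(ep$data)[2]; n_t <- dim(ep$data)[3]
  # filter along time for all event x channel traces at once; symmetric FIR
  # with centered convolution gives zero phase, edges padded by replication
  pad <- 15
  tr <- matrix(aperm(ep$data, c(3, 1, 2)), n_t, n_ev * n_ch)
  trp <- rbind(tr[rep(1, pad), , drop = FALSE], tr,
               tr[rep(n_t, pad), , drop = FALSE])
  f <- stats::filter(trp, h, method = "convolution", sides = 2)
  f <- f[(pad + 1):(pad + n_t), , drop = FALSE]
  keep <- seq(1, n_t, by = q)
  arr <- aperm(array(f[keep, ], c(length(keep), n_ev, n_ch)), c(2, 3, 1))
  epochs(arr, ep$channels, ep$times[keep], target_rate, ep$events)
}
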