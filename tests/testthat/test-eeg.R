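test_that("epochs constructor validates its geometry", {
  ep <- make_toy_epochs()
  expect_s3_class(ep, "bandit_epochs")
  expect_error(epochs(array(0, c(2, 3, 4)), paste0("c", 1:3),
                      c(0, 0.01, 0.03, 0.04), 100,
                      tibble::tibble(e = 1:2)), "uniformly")
  expect_error(epochs(array(0, c(2, 3, 4)), paste0("c", 1:2),
                      seq(0, 0.03, 0.01), 100, tibble::tibble(e = 1:2)),
               "dimensions")
  expect_error(epochs(array(0, c(2, 3, 4)), paste0("c", 1:3),
                      seq(0, 0.03, 0.01), 100, tibble::tibble(e = 1:3)),
               "one row per epoch")
})

test_that("the default montage yields a symmetric, full-cover adjacency", {
  mon <- default_montage()
  expect_equal(nrow(mon), 16)
  adj <- montage_adjacency(mon)
  expect_setequal(names(adj), mon$channel)
  check <- vapply(names(adj), function(ch)
    all(vapply(adj[[ch]], function(nb) ch %in% adj[[nb]], logical(1))),
    logical(1))
  expect_true(all(check))
  # interior channels of the 4x4 grid have 4 neighbors, corners 2
  expect_length(adj[["FC1"]], 4)
  expect_length(adj[["F7"]], 2)
})

test_that("design matrices assign latents per event and z-score them", {
  sim <- make_sim(400, n_blocks = 2, n_trials = 30)
  lat <- sim$latents
  for (lock in c("feedback", "response")) {
    des <- build_design(lat, lock)
    expect_equal(nrow(des), 2 * nrow(sim$trials)) # two events per trial
    regs <- attr(des, "regressors")
    expect_setequal(regs, c("pe_correct", "pe_incorrect", "evidence",
                            "weight"))
    for (r in regs) {
      expect_equal(mean(des[[r]]), 0, tolerance = 1e-12)
      expect_equal(sd(des[[r]]), 1, tolerance = 1e-12)
    }
  }
  # feedback lock: o1 takes the correct policy's d1 PE and the incorrect
  # policy's d2 PE (cross-decision assignment); z-scoring pools both events
  des <- build_design(lat, "feedback")
  o1 <- des[des$event == "o1", ]
  d1 <- lat[lat$decision == 1, ]; d2 <- lat[lat$decision == 2, ]
  scale_by <- function(x, pool) (x - mean(pool)) / sd(pool)
  pool_pec <- c(d1$delta_correct, d2$delta_correct)
  expect_equal(o1$pe_correct, scale_by(d1$delta_correct, pool_pec),
               tolerance = 1e-12)
  pool_pei <- c(d2$delta_incorrect, d1$delta_incorrect)
  expect_equal(o1$pe_incorrect, scale_by(d2$delta_incorrect, pool_pei),
               tolerance = 1e-12)
  ev1 <- d2$surprise_incorrect - d1$surprise_correct
  ev2 <- d1$surprise_incorrect - d2$surprise_correct
  expect_equal(o1$evidence, scale_by(ev1, c(ev1, ev2)), tolerance = 1e-12)
  # response lock recombines surprise within the decision
  desr <- build_design(lat, "response")
  r1 <- desr[desr$event == "d1", ]
  evr1 <- d1$surprise_incorrect - d1$surprise_correct
  evr2 <- d2$surprise_incorrect - d2$surprise_correct
  expect_equal(r1$evidence, scale_by(evr1, c(evr1, evr2)),
               tolerance = 1e-12)
  # constant latent (fixed weight) is dropped with a warning
  simfix <- make_sim(401, spec = model_spec("correct_policy"),
                     params = c(alpha = 0.4, beta = 4, rho = 0.2))
  expect_warning(desf <- build_design(simfix$latents, "feedback"),
                 "constant")
  expect_false("weight" %in% names(desf))
})

test_that("the mass GLM equals per-point lm() and scales linearly", {
  set.seed(410)
  sim <- make_sim(402, n_blocks = 1, n_trials = 40)
  des <- build_design(sim$latents, "feedback")
  n_ev <- nrow(des)
  chans <- paste0("ch", 1:4)
  arr <- array(rnorm(n_ev * 4 * 6, sd = 0.5), c(n_ev, 4, 6))
  # plant pe_correct at channel 2, samples 3:4
  arr[, 2, 3] <- arr[, 2, 3] + 0.8 * des$pe_correct
  arr[, 2, 4] <- arr[, 2, 4] + 0.8 * des$pe_correct
  ep <- epochs(arr, chans, seq(0, 0.05, 0.01), 100,
               tibble::tibble(e = seq_len(n_ev)))
  fit <- mass_glm(ep, des, standardize = "none")
  ref <- reference_mass_glm(ep, des)
  expect_equal(max(abs(fit$beta - ref)), 0, tolerance = 1e-8)
  expect_equal(fit$beta["pe_correct", 2, 3], 0.8, tolerance = 0.15)
  # noiseless signal equal to one regressor: unstandardized beta exactly 1
  arr0 <- array(0, c(n_ev, 4, 6))
  for (ch in 1:4) for (s in 1:6) arr0[, ch, s] <- des$evidence
  ep0 <- epochs(arr0, chans, seq(0, 0.05, 0.01), 100,
                tibble::tibble(e = seq_len(n_ev)))
  fit0 <- mass_glm(ep0, des, standardize = "none")
  expect_equal(as.vector(fit0$beta["evidence", , ]), rep(1, 24),
               tolerance = 1e-8)
  # doubling the planted effect doubles the recovered beta
  arr2 <- arr; arr2[, 2, 3] <- arr[, 2, 3] + 0.8 * des$pe_correct
  ep2 <- epochs(arr2, chans, seq(0, 0.05, 0.01), 100,
                tibble::tibble(e = seq_len(n_ev)))
  fit2 <- mass_glm(ep2, des, standardize = "none")
  expect_equal(fit2$beta["pe_correct", 2, 3],
               fit$beta["pe_correct", 2, 3] + 0.8, tolerance = 1e-8)
  # rank-deficient design names the collinear column
  des_bad <- des
  des_bad$pe_incorrect <- des_bad$pe_correct
  expect_error(mass_glm(ep, des_bad), "collinear")
})

test_that("orthogonal regressors match single-regressor fits", {
  set.seed(420)
  n_ev <- 64
  x1 <- rep(c(-1, 1), 32); x2 <- rep(c(-1, -1, 1, 1), 16)
  des <- tibble::tibble(pe_correct = x1, pe_incorrect = x2)
  attr(des, "regressors") <- c("pe_correct", "pe_incorrect")
  arr <- array(rnorm(n_ev * 2 * 3), c(n_ev, 2, 3))
  ep <- epochs(arr, c("a", "b"), c(0, 0.01, 0.02), 100,
               tibble::tibble(e = 1:n_ev))
  both <- mass_glm(ep, des, standardize = "none")
  des1 <- des[, 1]; attr(des1, "regressors") <- "pe_correct"
  one <- mass_glm(ep, des1, standardize = "none")
  expect_equal(both$beta["pe_correct", , ], one$beta["pe_correct", , ],
               tolerance = 1e-10)
})

test_that("planted effects are recovered through the full epochs pipeline", {
  set.seed(430)
  mon <- default_montage()
  adj <- montage_adjacency(mon)
  times <- seq(0, 0.996, by = 1 / 250)
  post <- setNames(rep(1, 4), c("P7", "P3", "P4", "P8"))
  effects <- list(list(regressor = "pe_correct", beta = 1.2,
                       channels = post, window = c(0.49, 0.77)))
  glms <- lapply(1:8, function(i) {
    sim <- make_sim(430 + i, n_blocks = 1, n_trials = 60)
    des <- build_design(sim$latents, "feedback")
    ep <- simulate_epochs(des, effects, mon, times,
                          noise = list(sd = 1, ar = 0.5, spatial = 0.3))
    ep <- downsample_epochs(ep, 125)
    mass_glm(ep, des)
  })
  betas <- stack_betas(glms, "pe_correct")
  res <- cluster_permutation(betas, adj, times = glms[[1]]$times,
                             n_perm = 400, seed = 1)
  tab <- tidy(res)
  expect_gt(nrow(tab), 0)
  top <- tab[1, ]
  expect_lt(top$p.value, 0.05)
  expect_gt(top$sign, 0)
  # the detected cluster overlaps the planted window and channels
  expect_lt(top$t_start, 0.77)
  expect_gt(top$t_end, 0.49)
  expect_true(any(c("P3", "P4", "P7", "P8") %in%
                    strsplit(top$channels, ",")[[1]]))
  # zero planted effects: betas hover near zero
  glms0 <- lapply(1:4, function(i) {
    sim <- make_sim(460 + i, n_blocks = 1, n_trials = 40)
    des <- build_design(sim$latents, "feedback")
    ep <- simulate_epochs(des, list(), mon, times[1:50])
    mass_glm(ep, des, standardize = "none")
  })
  b0 <- stack_betas(glms0, "pe_correct")
  expect_lt(max(abs(apply(b0, c(2, 3), mean))), 0.5)
})

test_that("sign-flipping all participants mirrors clusters, p unchanged", {
  set.seed(440)
  arr <- array(rnorm(8 * 4 * 10), c(8, 4, 10))
  arr[, 2, 4:6] <- arr[, 2, 4:6] + 1.2
  adj <- chain_adjacency(paste0("ch", 1:4))
  r1 <- cluster_permutation(arr, adj, channels = paste0("ch", 1:4),
                            n_perm = 300, seed = 7)
  r2 <- cluster_permutation(-arr, adj, channels = paste0("ch", 1:4),
                            n_perm = 300, seed = 7)
  expect_equal(r1$clusters$p.value, r2$clusters$p.value)
  expect_equal(r1$clusters$mass, -r2$clusters$mass)
  expect_equal(r1$clusters$sign, -r2$clusters$sign)
})

test_that("few participants trigger exact enumeration of sign flips", {
  set.seed(450)
  arr <- array(rnorm(5 * 3 * 8), c(5, 3, 8))
  adj <- chain_adjacency(paste0("ch", 1:3))
  r <- cluster_permutation(arr, adj, channels = paste0("ch", 1:3),
                           n_perm = 1000, seed = 1)
  expect_true(r$exact)
  expect_equal(r$n_perm, 2^5)
})

test_that("downsampling decimates cleanly and is idempotent in cascade", {
  set.seed(460)
  n_t <- 200
  arr <- array(rnorm(10 * 3 * n_t), c(10, 3, n_t))
  # add a slow component that must survive the anti-alias filter
  slow <- sin(2 * pi * 5 * seq(0, (n_t - 1) / 500, 1 / 500))
  for (e in 1:10) for (ch in 1:3) arr[e, ch, ] <- arr[e, ch, ] + 3 * slow
  ep <- epochs(arr, paste0("c", 1:3), seq(0, (n_t - 1) / 500, 1 / 500), 500,
               tibble::tibble(e = 1:10))
  d1 <- downsample_epochs(ep, 125)
  expect_equal(dim(d1$data)[3], 50)
  expect_equal(d1$sampling_rate, 125)
  expect_equal(nrow(d1$events), 10)
  expect_error(downsample_epochs(ep, 333), "divide")
  # constant signal is unchanged in value
  cst <- epochs(array(2.5, c(2, 2, 40)), c("a", "b"),
                seq(0, 39 / 500, 1 / 500), 500, tibble::tibble(e = 1:2))
  dc <- downsample_epochs(cst, 125)
  expect_equal(as.vector(dc$data), rep(2.5, 2 * 2 * 10), tolerance = 1e-9)
  # 500 -> 250 -> 125 approximately equals 500 -> 125 away from edges
  d2 <- downsample_epochs(downsample_epochs(ep, 250), 125)
  mid <- 10:40
  expect_equal(d1$data[, , mid], d2$data[, , mid], tolerance = 0.2)
})
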