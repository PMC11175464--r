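zero_values <- function() list(correct = matrix(0, 2, 2),
                               incorrect = matrix(0, 2, 2))

test_that("single-step operations reproduce hand-computed cases", {
  # prediction errors
  pe <- prediction_errors(zero_values(), outcomes = c(0.5, 0.5),
                          actions = c(1, 1))
  expect_equal(pe$delta_correct, c(0.5, 0.5))
  v <- zero_values(); v$correct[] <- 0.2
  pe <- prediction_errors(v, outcomes = c(-0.2, 0.1), actions = c(1, 2))
  expect_equal(pe$delta_correct[1], -0.4)
  v <- zero_values(); v$correct[1, 1] <- 0.5; v$incorrect[1, 2] <- -0.3
  pe <- prediction_errors(v, outcomes = c(0.5, -0.3), actions = c(1, 2))
  expect_equal(pe$delta_correct[1], 0) # perfect prediction
  expect_equal(pe$delta_incorrect[1], -0.3) # o2 minus the (zero) chosen value

  # value updates
  v0 <- zero_values()
  upd <- update_values(v0, list(delta_correct = c(0.5, 0),
                                delta_incorrect = c(0, 0)),
                       actions = c(1, 1), alpha = 0.5)
  expect_equal(upd$correct[1, ], c(0.25, -0.25))
  upd0 <- update_values(v0, list(delta_correct = c(0.7, -0.2),
                                 delta_incorrect = c(0.1, 0.3)),
                        actions = c(2, 1), alpha = 0)
  expect_equal(upd0, v0)

  # surprise and evidence
  expect_equal(surprise(-0.4), 0.4)
  expect_equal(surprise(0), 0)
  ev <- evidence(surprise_correct = c(0.2, 0.2),
                 surprise_incorrect = c(0.2, 0.2))
  expect_equal(unname(ev), c(0, 0))
  ev <- evidence(surprise_correct = c(0.2, 0.5),
                 surprise_incorrect = c(0.1, 0.6))
  expect_equal(unname(ev), c(0.6 - 0.2, 0.1 - 0.5)) # cross-decision pairing
  ev_swap <- evidence(surprise_correct = c(0.1, 0.6),
                      surprise_incorrect = c(0.2, 0.5))
  expect_equal(unname(ev_swap), -rev(unname(ev))) # policy swap antisymmetry

  # arbitration update
  expect_equal(update_arbitration(0.7, c(o1 = 0.4, o2 = 0.2), 0), 0.7)
  om <- update_arbitration(0, c(o1 = 0.4, o2 = 0.2), 0.5)
  expect_equal(om, 0.3)
  expect_equal(inv_logit(om), 1 / (1 + exp(-0.3)))

  # net values
  expect_equal(net_values(0.4, -0.2, 0.75), 0.25)
  expect_equal(net_values(0.4, -0.2, 0.5), 0.1)
  expect_equal(net_values(0.4, -0.2, 1), 0.4)

  # choice probabilities
  p <- choice_probabilities(matrix(0.3, 2, 2), beta = 0, rho = 0)
  expect_equal(as.vector(p), rep(0.5, 4))
  p <- choice_probabilities(matrix(c(0.98, 0.98, -0.98, -0.98), 2, 2),
                            beta = 20, rho = 0)
  expect_equal(p[1, 1], 1 / (1 + exp(-39.2)))
  p <- choice_probabilities(matrix(0.2, 2, 2), beta = 0, rho = 1,
                            previous = c(1, NA))
  expect_equal(p[1, 1], 1 / (1 + exp(-1)))
  expect_equal(p[2, 1], 0.5)
  expect_equal(rowSums(p), c(1, 1))
})

test_that("joint-action step follows the scalar TD rule over four actions", {
  st <- joint_action_step(rep(0, 4), outcomes = c(75, 25), joint_action = 2,
                          params = c(alpha = 0.3, beta = 0, rho = 0))
  expect_equal(st$delta, 0)
  expect_equal(st$probabilities, rep(0.25, 4))
  st <- joint_action_step(rep(0, 4), outcomes = c(75, 99), joint_action = 1,
                          params = c(alpha = 0.3, beta = 2, rho = 0.5),
                          previous = 3)
  expect_equal(st$delta, 1.48)
  expect_equal(st$values[1], 0.444)
  expect_equal(sum(st$probabilities), 1)
})

test_that("model_spec validates parameter sets and weight usage", {
  expect_error(model_spec("surprise_min", fixed_weight = 0.9), "fixed-weight")
  expect_equal(model_spec("correct_policy")$fixed_weight, 0.9)
  expect_equal(model_spec("incorrect_policy")$fixed_weight, 0.1)
  expect_equal(model_spec("random_policy")$fixed_weight, 0.5)
  expect_equal(model_spec("surprise_min",
                          counterfactual_mode = "free_decay")$k, 5)
  task <- make_task(20, n_blocks = 1, n_trials = 5)
  expect_error(simulate_agent(task, model_spec(), c(alpha = 0.5, beta = 1)),
               "exactly parameters")
  expect_error(simulate_agent(task, model_spec("random_policy"),
                              default_params), "exactly parameters")
  expect_error(simulate_agent(task, model_spec(),
                              c(alpha = 2, beta = 1, rho = 0, epsilon = 0.1)),
               "outside bounds")
})

test_that("latent traces satisfy the structural invariants", {
  sim <- make_sim(31)
  l <- sim$latents
  expect_true(all(l$surprise_correct >= 0 & l$surprise_incorrect >= 0))
  expect_true(all(l$weight > 0 & l$weight < 1))
  first <- dplyr::filter(l, trial == 1)
  expect_true(all(first$omega == 0 & first$weight == 0.5))
  # value antisymmetry under counterfactual updating from zero init
  expect_equal(l$v_correct_a1, -l$v_correct_a2, tolerance = 1e-12)
  expect_equal(l$v_incorrect_a1, -l$v_incorrect_a2, tolerance = 1e-12)
  expect_equal(l$p_chosen,
               ifelse(l$action == 1, l$p_a1, 1 - l$p_a1), tolerance = 1e-12)
})

test_that("uniform-policy likelihood equals 2T log 2 exactly", {
  sim <- make_sim(32)
  pars <- c(alpha = 0.5, beta = 0, rho = 0, epsilon = 0.3)
  nll <- model_nll(sim$trials, model_spec(), pars)
  expect_equal(nll, 2 * nrow(sim$trials) * log(2), tolerance = 1e-12)
})

test_that("engine likelihood matches the slow reference loop to 1e-10", {
  set.seed(33)
  for (i in 1:3) {
    sim <- make_sim(40 + i, n_blocks = 2, n_trials = 25)
    pars <- unlist(draw_params(model_spec(), 1))
    expect_equal(model_nll(sim$trials, model_spec(), pars),
                 reference_nll(sim$trials, pars["alpha"], pars["beta"],
                               pars["rho"], pars["epsilon"]),
                 tolerance = 1e-10)
    # fixed-weight variant
    expect_equal(
      model_nll(sim$trials, model_spec("correct_policy"),
                pars[c("alpha", "beta", "rho")]),
      reference_nll(sim$trials, pars["alpha"], pars["beta"], pars["rho"],
                    0, fixed_weight = 0.9),
      tolerance = 1e-10)
    # joint-action model
    expect_equal(
      model_nll(sim$trials, model_spec("joint_action"),
                pars[c("alpha", "beta", "rho")]),
      reference_joint_nll(sim$trials, pars["alpha"], pars["beta"],
                          pars["rho"]),
      tolerance = 1e-10)
    # decay variants
    expect_equal(
      model_nll(sim$trials, model_spec(counterfactual_mode = "lr_decay"),
                pars),
      reference_nll(sim$trials, pars["alpha"], pars["beta"], pars["rho"],
                    pars["epsilon"], cf_mode = "lr_decay"),
      tolerance = 1e-10)
    pars5 <- c(pars, decay = 0.25)
    expect_equal(
      model_nll(sim$trials, model_spec(counterfactual_mode = "free_decay"),
                pars5),
      reference_nll(sim$trials, pars["alpha"], pars["beta"], pars["rho"],
                    pars["epsilon"], cf_mode = "free_decay", decay = 0.25),
      tolerance = 1e-10)
  }
})

test_that("epsilon = 0 reduces exactly to the random-policy model", {
  for (i in 1:3) {
    sim <- make_sim(50 + i)
    nll_sm <- model_nll(sim$trials, model_spec(),
                        c(alpha = 0.35, beta = 3, rho = -0.4, epsilon = 0))
    nll_rand <- model_nll(sim$trials, model_spec("random_policy"),
                          c(alpha = 0.35, beta = 3, rho = -0.4))
    expect_equal(nll_sm, nll_rand, tolerance = 1e-12)
  }
})

test_that("fixed weight 1 and 0 equal single-policy TD learners exactly", {
  for (i in 1:3) {
    sim <- make_sim(60 + i)
    a <- 0.45; b <- 2.5; r <- 0.6
    nll_w1 <- model_nll(sim$trials,
                        model_spec("correct_policy", fixed_weight = 1),
                        c(alpha = a, beta = b, rho = r))
    expect_equal(nll_w1, td_learner_nll(sim$trials, a, b, r, "relevant"),
                 tolerance = 1e-12)
    nll_w0 <- model_nll(sim$trials,
                        model_spec("incorrect_policy", fixed_weight = 0),
                        c(alpha = a, beta = b, rho = r))
    expect_equal(nll_w0, td_learner_nll(sim$trials, a, b, r, "irrelevant"),
                 tolerance = 1e-12)
  }
})

test_that("replayed latents equal the generative latents exactly", {
  for (spec in list(model_spec(), model_spec("correct_policy"),
                    model_spec("joint_action"))) {
    pars <- default_params[seq_len(spec$k)]
    names(pars) <- spec$params
    sim <- make_sim(70, spec = spec, params = pars)
    rep <- model_nll(sim$trials, spec, pars, latents = TRUE)
    expect_equal(rep$nll, sim$nll, tolerance = 1e-12)
    expect_equal(rep$latents, sim$latents, tolerance = 1e-12)
  }
})

test_that("generating parameters beat far-perturbed ones on average", {
  set.seed(80)
  gen <- c(alpha = 0.4, beta = 5, rho = 0, epsilon = 0.5)
  far <- c(alpha = 0.95, beta = 0.3, rho = 2, epsilon = 0.02)
  diffs <- replicate(8, {
    sim <- make_sim(sample.int(1e6, 1), params = gen)
    model_nll(sim$trials, model_spec(), gen) -
      model_nll(sim$trials, model_spec(), far)
  })
  expect_lt(mean(diffs), 0)
})

test_that("surprise separates the policies in parameterized simulations", {
  set.seed(90)
  runs <- simulate_study(40)
  expect_true(all(runs$mean_surprise_correct < runs$mean_surprise_incorrect))
})
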