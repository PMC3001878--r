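# Posterior risk, optimal actions, softmax policies and response likelihoods.

test_that("posterior risk: closed form and quadrature agree", {
  bel <- gaussian_belief(1.5, 0.7)
  sq <- squared_error_loss()
  expect_equal(posterior_risk(sq, bel, action = 2), (2 - 1.5)^2 + 0.7)
  expect_equal(posterior_risk(sq, bel, action = 1.5), 0.7)

  # same loss without the closed form goes through Gauss-Hermite
  sq_num <- loss_spec(function(a, x, phi) sum((a - x)^2),
                      action_space_continuous(-10, 10))
  set.seed(9)
  for (rep in 1:10) {
    bel <- gaussian_belief(rnorm(1), exp(rnorm(1)))
    a <- rnorm(1)
    expect_equal(posterior_risk(sq_num, bel, a),
                 posterior_risk(sq, bel, a), tolerance = 1e-10)
  }

  # the toy composite risk: offset 0, n = 9, beta = 1, k = 0.01 -> 0.19
  bel9 <- gaussian_belief(0.5, 1 / (1 + 9))
  expect_equal(posterior_risk(toy_loss(), bel9, action = c(0.5, 9), phi = 0.01),
               0.19)
  tl_num <- loss_spec(toy_loss()$evaluate, action_space_continuous())
  expect_equal(posterior_risk(tl_num, bel9, c(0.5, 9), 0.01), 0.19,
               tolerance = 1e-10)

  # documented dimension limit for quadrature
  bel5 <- structure(list(trial = 1L, mode = rep(0, 5), covariance = diag(5),
                         perceptual_free_energy = 0, converged = TRUE),
                    class = "belief")
  expect_error(posterior_risk(sq_num, bel5, rep(0, 5)),
               class = "ibdt_unsupported_dimension")
})

test_that("the optimal action minimizes posterior risk", {
  # squared error: optimal action is the posterior mean
  bel <- gaussian_belief(0.42, 0.3)
  expect_equal(as.numeric(optimal_action(squared_error_loss(), bel)), 0.42)

  # finite action set with exact ties: lowest index wins and the tie is flagged
  sym <- loss_spec(function(a, x, phi) (a - x)^2, action_space_finite(c(-1, 1)))
  bel0 <- gaussian_belief(0, 1)
  a <- optimal_action(sym, bel0)
  expect_equal(as.numeric(a), -1)
  expect_true(attr(a, "tie"))

  # toy sampling problem via the generic integer-action path
  prior_bel <- gaussian_belief(0, 1, 0L)
  n_star <- optimal_action(toy_sampling_loss(upper = 2000), prior_bel, phi = 0.01)
  expect_equal(as.numeric(n_star), 9)
  brute <- which.min(toy_risk(toy_observer_config(beta = 1, k = 0.01), 0:1000)) - 1
  expect_equal(as.numeric(n_star), brute)

  # unbounded continuous space without a closed form is rejected
  bad <- loss_spec(function(a, x, phi) a, action_space_continuous())
  expect_error(optimal_action(bad, bel), class = "ibdt_invalid_loss")
})

test_that("softmax policies behave like a logit in negative risk", {
  expect_equal(softmax_policy(c(3, 3, 3), 0.7), rep(1 / 3, 3))
  expect_equal(softmax_policy(c(0, 1), 1), c(0.7311, 0.2689), tolerance = 1e-4)
  # zero-temperature limit degenerates on the argmin
  p <- softmax_policy(c(0, 1), 1e-6)
  expect_gt(p[1], 1 - 1e-9)
  # invariance to a common shift in the risks
  set.seed(4)
  r <- rnorm(5)
  expect_equal(softmax_policy(r, 0.5), softmax_policy(r + 17.3, 0.5),
               tolerance = 1e-12)
  expect_equal(sum(softmax_policy(r, 2)), 1, tolerance = 1e-12)
  expect_error(softmax_policy(c(Inf, Inf), 1), class = "ibdt_invalid_input")
  expect_error(softmax_policy(c(0, 1), 0), class = "ibdt_invalid_input")
})

test_that("response log-likelihoods match their Gaussian / softmax forms", {
  resp <- response_model(
    observation_map = function(trajectory, phi) trajectory[[1L]]$mode[1],
    response_dim = 1L, sigma2 = 1)
  traj <- structure(list(gaussian_belief(0.3, 1, 0L)), class = "belief_trajectory")
  expect_equal(response_loglik(resp, traj, numeric(0), observed = 0.3),
               -0.5 * log(2 * pi))
  expect_equal(response_loglik(resp, traj, numeric(0), observed = 1.3),
               -0.5 * log(2 * pi) - 0.5)
  expect_identical(response_loglik(resp, traj, numeric(0), observed = NA_real_), 0)

  # categorical channel: the riskier of two actions under temperature 1
  cat_resp <- response_model(
    observation_map = function(trajectory, phi) stop("unused"),
    response_dim = 1L, sigma2 = 1, type = "categorical",
    risks_map = function(trajectory, phi) c(0, 1),
    temperature = function(phi) 1)
  expect_equal(response_loglik(cat_resp, traj, numeric(0), observed = 2),
               log(0.2689), tolerance = 1e-3)

  # conditional independence: the trajectory log-likelihood is a sum of
  # per-trial terms
  dat <- make_toy_data(n_trials = 12, seed = 2)
  perc <- toy_perceptual_model()
  resp2 <- toy_response_spec(sigma2 = 0.0025)
  per_trial <- vapply(seq_along(dat$inputs), function(t) {
    traj <- recognise_sequence(perc, dat$inputs[[t]], theta = 2)
    response_loglik(resp2, traj, phi = 0.01, observed = dat$responses[t, ])
  }, numeric(1))
  Y <- resp2$predict_all(2, 0.01, dat)
  total <- sum(dnorm(dat$responses, Y, sqrt(0.0025), log = TRUE))
  expect_equal(sum(per_trial), total, tolerance = 1e-10)
})
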