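# Experimenter-level inversion: recovery, evidence, comparison, belief
# reconstruction and identifiability.

test_that("the inversion recovers the generating toy parameters", {
  dat <- make_toy_data(beta = 1, k = 0.01, sigma2 = 1e-4, n_trials = 100,
                       seed = 42)
  post <- invert_observer(toy_perceptual_model(), toy_response_spec(sigma2 = 1e-4),
                          dat, toy_default_prior(),
                          options = list(multistart = 2, seed = 43))
  truth <- c(log(1), log(0.01))
  err <- as.numeric(post$mode) - truth
  sds <- sqrt(diag(post$covariance))
  expect_true(all(abs(err) <= 3 * sds))
  expect_lt(abs(err[1]), 0.1)
  expect_lt(abs(err[2]), 0.1 * abs(truth[2]))
  expect_true(post$converged)
  expect_equal(dim(post$residuals), c(100L, 2L))
})

test_that("with no informative responses the posterior is the prior", {
  dat <- make_toy_data(n_trials = 10, seed = 5)
  dat$responses[] <- NA_real_
  prior <- toy_default_prior()
  post <- invert_observer(toy_perceptual_model(), toy_response_spec(sigma2 = 0.01),
                          dat, prior)
  expect_equal(as.numeric(post$mode), unname(prior$mean), tolerance = 1e-8)
  expect_equal(post$covariance, prior$covariance, tolerance = 1e-8)
})

test_that("the free energy matches the exact evidence in the linear-Gaussian case", {
  set.seed(12)
  cand <- linear_gaussian_candidate(sigma2 = 0.5, prior_mean = 0.2, prior_sd = 1.5)
  y <- 1 + rnorm(30, sd = sqrt(0.5))
  dat <- trial_data(as.list(rep(0, 30)), matrix(y, ncol = 1))
  post <- invert_observer(cand$perceptual, cand$response, dat, cand$prior,
                          options = list(multistart = 1))
  exact <- linear_gaussian_evidence(y, 0.2, 1.5^2, 0.5)
  expect_equal(post$free_energy, exact, tolerance = 1e-6)
  # the accuracy-minus-complexity decomposition reproduces the same number
  expect_equal(response_free_energy(post), post$free_energy, tolerance = 1e-6)
  # information is only gained: posterior covariance below prior covariance
  gap <- eigen(post$prior$covariance - post$covariance,
               symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(gap), -1e-6)

  # a delta prior pinned at the truth: F tends to the log-likelihood at
  # that value (complexity term vanishes)
  cand0 <- linear_gaussian_candidate(sigma2 = 0.5, prior_mean = 1.1,
                                     prior_sd = 1e-5)
  post0 <- invert_observer(cand0$perceptual, cand0$response, dat, cand0$prior,
                           options = list(multistart = 1))
  expect_equal(post0$free_energy, sum(dnorm(y, 1.1, sqrt(0.5), log = TRUE)),
               tolerance = 1e-3)
})

test_that("free energy is invariant to trial order for exchangeable data", {
  dat <- make_toy_data(n_trials = 30, seed = 9)
  perm <- sample(30)
  dat_p <- trial_data(dat$inputs[perm], dat$responses[perm, , drop = FALSE])
  perc <- toy_perceptual_model()
  resp <- toy_response_spec(sigma2 = 0.0025)
  prior <- toy_default_prior()
  f1 <- invert_observer(perc, resp, dat, prior, options = list(multistart = 1))
  f2 <- invert_observer(perc, resp, dat_p, prior, options = list(multistart = 1))
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-8)
})

test_that("model comparison is symmetric for duplicated candidates", {
  dat <- make_toy_data(n_trials = 25, seed = 11)
  cand <- list(perceptual = toy_perceptual_model(),
               response = toy_response_spec(sigma2 = 0.0025),
               prior = toy_default_prior())
  cmp <- compare_models(list(cand, cand), dat, options = list(multistart = 1))
  expect_equal(cmp$posterior_model_probabilities, c(0.5, 0.5), tolerance = 1e-6)

  other <- toy_fixed_beta_candidate(beta = 0.01, sigma2 = 0.0025)
  cmp3 <- compare_models(list(cand, cand, other), dat,
                         options = list(multistart = 1))
  p <- cmp3$posterior_model_probabilities
  expect_equal(p[1], p[2], tolerance = 1e-6)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("a redundant response parameter lowers the free energy", {
  dat <- make_toy_data(n_trials = 60, seed = 21)
  base <- invert_observer(toy_perceptual_model(), toy_response_spec(sigma2 = 0.0025),
                          dat, toy_default_prior(), options = list(multistart = 1))
  aug <- invert_observer(toy_perceptual_model(), toy_gain_response_spec(sigma2 = 0.0025),
                         dat, parameter_prior(
                           mean = c(log_beta = 0, log_k = 0, log_gain = 0),
                           sd = c(10, 10, 10)),
                         options = list(multistart = 1))
  expect_lt(aug$free_energy, base$free_energy)
})

test_that("reconstructed subject beliefs are inflated, never deflated", {
  dat <- make_toy_data(n_trials = 40, seed = 14)
  post <- invert_observer(toy_perceptual_model(), toy_response_spec(sigma2 = 0.0025),
                          dat, toy_default_prior(), options = list(multistart = 1))
  for (tr in c(0L, 7L, 39L)) {
    rec <- reconstruct_subject_belief(post, trial = tr)
    expect_gte(rec$variance[1, 1], rec$subject_variance[1, 1])
    z <- qnorm(0.95)
    subj_ci <- rec$mean + c(-1, 1) * z * sqrt(rec$subject_variance[1, 1])
    expect_lte(rec$credible_interval[1, "lower"], subj_ci[1])
    expect_gte(rec$credible_interval[1, "upper"], subj_ci[2])
  }
  expect_error(reconstruct_subject_belief(post, trial = 40L),
               class = "ibdt_index_error")
  expect_error(reconstruct_subject_belief(post, trial = -1L),
               class = "ibdt_index_error")
})

test_that("identifiability reporting flags confounded parameters", {
  # diagonal covariance: no flags
  fake <- list(mode = c(a = 0, b = 0), covariance = diag(c(1, 2)))
  rep0 <- identifiability_report(fake)
  expect_identical(nrow(rep0$flagged), 0L)
  expect_equal(rep0$correlation[1, 2], 0)

  # a deliberately confounded observer: the response depends only on
  # theta + phi, so the two parameters cannot be separated
  perc <- perceptual_model(
    log_prior = function(x, theta) dnorm(x, 0, 1, log = TRUE),
    log_likelihood = function(u, x, theta) 0,
    theta_names = "a", theta_transform = "identity",
    prior_moments = function(theta) list(mode = 0, covariance = matrix(1, 1, 1)),
    update = function(mode, covariance, u, theta)
      list(mode = mode, covariance = covariance, log_evidence = 0))
  resp <- response_model(
    observation_map = function(trajectory, phi) 0,
    response_dim = 1L, sigma2 = 0.01,
    phi_names = "b", phi_transform = "identity",
    predict_all = function(theta, phi, data)
      matrix(theta[1] + phi[1], length(data$inputs), 1))
  set.seed(2)
  dat <- trial_data(as.list(rep(0, 40)),
                    matrix(1 + 0.1 * rnorm(40), ncol = 1))
  post <- invert_observer(perc, resp, dat,
                          parameter_prior(mean = c(a = 0, b = 0), sd = c(2, 2)),
                          options = list(multistart = 1))
  repc <- identifiability_report(post)
  expect_gte(nrow(repc$flagged), 1L)
  expect_gt(abs(repc$correlation[1, 2]), 0.95)

  # zero-variance parameters are reported as degenerate, not divided by zero
  degen <- list(mode = c(a = 0, b = 0), covariance = diag(c(1, 0)))
  repd <- identifiability_report(degen)
  expect_identical(repd$degenerate, 2L)
})

test_that("posterior uncertainty shrinks with more trials", {
  sds <- sapply(c(25, 50, 100), function(tt) {
    s <- sapply(1:5, function(i) {
      dat <- make_toy_data(n_trials = tt, seed = 100 + i)
      post <- invert_observer(toy_perceptual_model(),
                              toy_response_spec(sigma2 = 0.0025), dat,
                              toy_default_prior(), options = list(multistart = 1))
      sqrt(diag(post$covariance))
    })
    rowMeans(s)
  })
  expect_true(all(diff(sds[1, ]) < 0))
  expect_true(all(diff(sds[2, ]) < 0))
})

test_that("an ill-posed problem is refused with actionable advice", {
  dat <- make_toy_data(n_trials = 1, seed = 1)
  dat$responses[1, 2] <- NA  # one informative number, two parameters
  wide <- parameter_prior(mean = c(log_beta = 0, log_k = 0), sd = c(1e5, 1e5))
  expect_error(invert_observer(toy_perceptual_model(),
                               toy_response_spec(sigma2 = 0.0025), dat, wide),
               "priors", class = "ibdt_ill_posed")
})
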