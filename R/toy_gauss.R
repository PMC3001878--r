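# Worked example with closed forms: a subject estimates the mean of a unit-
# variance Gaussian signal under a loss that trades squared estimation error
# against a linear per-sample cost k*n. The conjugate algebra makes every
# quantity exact, so this model doubles as the oracle for the generic
# recognition / decision / inversion machinery.

#' Configuration of the toy Gaussian-mean observer
#'
#' @param beta positive prior precision of the signal mean (the perceptual
#'   parameter `theta`).
#' @param k positive per-sample cost weight (response parameter `phi`).
#' @param sigma2 positive response residual variance, shared by both response
#'   channels (reported estimate and reported sample size).
#' @param prior_mean prior mean of the signal mean.
#' @param signal_variance sampling variance of the signal, fixed at 1 (the
#'   subject is assumed to know it).
#' @return object of class `toy_observer_config`.
#' @export
toy_observer_config <- function(beta = 2, k = 0.01, sigma2 = 0.0025,
                                prior_mean = 0, signal_variance = 1) {
  if (!all(is.finite(c(beta, k, sigma2, prior_mean, signal_variance))) ||
      beta <= 0 || k <= 0 || sigma2 < 0 || signal_variance <= 0)
    ibdt_stop("invalid toy observer configuration", "ibdt_invalid_input")
  structure(list(beta = beta, k = k, sigma2 = sigma2, prior_mean = prior_mean,
                 signal_variance = signal_variance),
            class = "toy_observer_config")
}

#' Conjugate posterior for the toy model
#'
#' With prior `N(prior_mean, 1/beta)` and unit-variance samples, the posterior
#' precision is `beta + n` and the posterior mean is the precision-weighted
#' average. The free energy returned is the exact Gaussian log marginal
#' likelihood of the samples (accumulated predictive densities).
#'
#' @param beta positive prior precision.
#' @param prior_mean prior mean.
#' @param samples numeric vector of observed samples (may be empty).
#' @param signal_variance sampling variance of the signal.
#' @return list with `mean`, `precision`, `free_energy`.
#' @export
toy_posterior <- function(beta, prior_mean = 0, samples = numeric(),
                          signal_variance = 1) {
  stopifnot(beta > 0, signal_variance > 0)
  m <- prior_mean
  prec <- beta
  fe <- 0
  for (u in samples) {
    fe <- fe + stats::dnorm(u, m, sqrt(1 / prec + signal_variance), log = TRUE)
    m <- (prec * m + u / signal_variance) / (prec + 1 / signal_variance)
    prec <- prec + 1 / signal_variance
  }
  list(mean = m, precision = prec, free_energy = fe)
}

#' Posterior risk in the toy task
#'
#' Expected loss of reporting the posterior mean plus `estimator_offset`
#' after observing `n` samples: `offset^2 + 1/(beta + n) + k * n`.
#'
#' @param config a [toy_observer_config()].
#' @param n nonnegative sample size(s); vectorized.
#' @param estimator_offset deviation of the reported estimator from the
#'   posterior mean.
#' @return numeric risk, same length as `n`.
#' @export
toy_risk <- function(config, n, estimator_offset = 0) {
  stopifnot(all(n >= 0))
  estimator_offset^2 + 1 / (config$beta + n) + config$k * n
}

#' Continuous-relaxation optimal sample size
#'
#' Stationary point of the toy risk in `n` treated as real:
#' `max(0, 1/sqrt(k) - beta)`. This is the mean of the real-valued
#' sample-size response channel.
#'
#' @param beta,k positive toy parameters; vectorized.
#' @return nonnegative numeric.
#' @export
toy_continuous_n <- function(beta, k) {
  pmax(0, 1 / sqrt(k) - beta)
}

#' Optimal integer sample size
#'
#' Integer minimizer of the toy posterior risk at zero estimator offset,
#' found by comparing the floor/ceiling neighbours of the continuous
#' stationary point (and 0); ties resolve to the smaller `n`.
#'
#' @param beta,k positive toy parameters.
#' @return nonnegative integer.
#' @export
toy_optimal_n <- function(beta, k) {
  stopifnot(beta > 0, k > 0)
  nc <- toy_continuous_n(beta, k)
  cand <- sort(unique(pmax(0, c(0, floor(nc), ceiling(nc)))))
  cfg <- toy_observer_config(beta = beta, k = k)
  risks <- toy_risk(cfg, cand)
  as.integer(cand[which.min(risks)])
}

#' Deterministic toy response map
#'
#' The noise-free response of the toy observer: the reported estimate is the
#' posterior mean of the supplied samples and the chosen sample size is the
#' Bayes-optimal integer `n*`. The simulator adds Gaussian response noise on
#' top of this map (and uses the continuous policy value as the mean of the
#' sample-size channel, which coincides with `n*` whenever
#' `1/sqrt(k) - beta` is an integer).
#'
#' @param config a [toy_observer_config()].
#' @param samples numeric vector of the samples the subject drew.
#' @return named numeric `c(estimate, n)`.
#' @export
toy_response_map <- function(config, samples) {
  post <- toy_posterior(config$beta, config$prior_mean, samples,
                        config$signal_variance)
  c(estimate = post$mean, n = as.numeric(toy_optimal_n(config$beta, config$k)))
}

#' Toy perceptual model for the generic machinery
#'
#' Builds a [perceptual_model()] for the toy task with `theta = beta` (log
#' transform to the unconstrained scale). Analytic Gaussian derivatives are
#' always supplied; with `analytic = TRUE` the exact conjugate update is also
#' attached, so recognition bypasses the numeric Laplace fit (the two paths
#' agree to numerical precision; the numeric path is the one exercised when
#' validating the generic engine).
#'
#' @param analytic attach the exact conjugate update rule.
#' @param prior_mean prior mean of the signal mean.
#' @param signal_variance sampling variance of the signal.
#' @return a `perceptual_model`.
#' @export
toy_perceptual_model <- function(analytic = TRUE, prior_mean = 0,
                                 signal_variance = 1) {
  sv <- signal_variance
  m0 <- prior_mean
  perceptual_model(
    log_prior = function(x, theta)
      stats::dnorm(x, m0, sqrt(1 / theta[1]), log = TRUE),
    log_likelihood = function(u, x, theta)
      sum(stats::dnorm(u, x, sqrt(sv), log = TRUE)),
    state_dim = 1L,
    theta_names = "beta",
    theta_transform = "log",
    prior_grad = function(x, theta) -theta[1] * (x - m0),
    prior_hess = function(x, theta) matrix(-theta[1], 1, 1),
    lik_grad = function(u, x, theta) sum(u - x) / sv,
    lik_hess = function(u, x, theta) matrix(-length(u) / sv, 1, 1),
    prior_moments = function(theta)
      list(mode = m0, covariance = matrix(1 / theta[1], 1, 1)),
    update = if (analytic) function(mode, covariance, u, theta) {
      post <- toy_posterior(1 / covariance[1, 1], mode, u, sv)
      list(mode = post$mean, covariance = matrix(1 / post$precision, 1, 1),
           log_evidence = post$free_energy)
    })
}

#' Toy loss over (estimator, sample size) actions
#'
#' `(a - x)^2 + k * n` for the composite action `c(a, n)`; the closed-form
#' posterior risk is `(a - mu)^2 + var + k * n`.
#'
#' @return a `loss_spec` with `phi = k`.
#' @export
toy_loss <- function() {
  loss_spec(
    evaluate = function(action, x, phi) (action[1] - x)^2 + phi[1] * action[2],
    action_space = action_space_continuous(),
    phi_names = "k",
    closed_form_risk = function(action, belief, phi)
      (action[1] - belief$mode[1])^2 + belief$covariance[1, 1] +
        phi[1] * action[2])
}

#' Toy sample-size decision as an integer-action loss
#'
#' Risk of committing to `n` samples before seeing them, at the prior belief:
#' `1/(prior precision + n) + k * n`. Used to pose the optimal-sample-size
#' decision through the generic [optimal_action()] path.
#'
#' @param upper upper bound of the integer action space.
#' @return a `loss_spec` whose closed-form risk reads the prior precision off
#'   the supplied belief.
#' @export
toy_sampling_loss <- function(upper = 1e6) {
  loss_spec(
    evaluate = function(action, x, phi) NA_real_,  # risk is given in closed form
    action_space = action_space_integer(0, upper),
    phi_names = "k",
    closed_form_risk = function(action, belief, phi)
      1 / (1 / belief$covariance[1, 1] + action) + phi[1] * action)
}

#' Toy response model (two Gaussian channels)
#'
#' Channel 1 is the reported estimate (posterior mean of the trial's samples);
#' channel 2 is the reported sample size, whose mean is the continuous policy
#' value `max(0, 1/sqrt(k) - beta)` with `beta` read off the prior belief's
#' precision. A vectorized `predict_all` is attached for fast inversion.
#'
#' @param sigma2 residual variance (scalar, per-channel vector, or
#'   `"estimated"`).
#' @param prior_mean prior mean used by the vectorized predictor (must match
#'   the perceptual model's).
#' @return a `response_model` with `phi = k` (log transform).
#' @export
toy_response_spec <- function(sigma2 = "estimated", prior_mean = 0) {
  m0 <- prior_mean
  response_model(
    observation_map = function(trajectory, phi) {
      prior_prec <- 1 / trajectory[[1L]]$covariance[1, 1]
      last <- trajectory[[length(trajectory)]]
      c(last$mode[1], max(0, 1 / sqrt(phi[1]) - prior_prec))
    },
    response_dim = 2L,
    sigma2 = sigma2,
    phi_names = "k",
    phi_transform = "log",
    loss = toy_loss(),
    predict_all = function(theta, phi, data) {
      beta <- theta[1]; k <- phi[1]
      sums <- vapply(data$inputs, function(u) sum(u), numeric(1))
      ns <- lengths(data$inputs)
      cbind((beta * m0 + sums) / (beta + ns),
            rep(max(0, 1 / sqrt(k) - beta), length(ns)))
    })
}

#' Toy observer with the prior precision fixed
#'
#' Builds the perceptual/response pair of a toy observer whose prior
#' precision `beta` is frozen at a given value (no free perceptual
#' parameter), e.g. a near-flat-prior observer with tiny `beta`. Useful as a
#' comparison candidate against the free-`beta` observer.
#'
#' @param beta fixed prior precision.
#' @param sigma2 residual variance for the response model.
#' @param prior_mean prior mean of the signal mean.
#' @param prior_sd prior standard deviation over `log k`.
#' @return list with elements `perceptual`, `response` and a suitable
#'   one-parameter `prior` over `log k`.
#' @export
toy_fixed_beta_candidate <- function(beta, sigma2, prior_mean = 0,
                                     prior_sd = 10) {
  m0 <- prior_mean
  b <- beta
  perc <- perceptual_model(
    log_prior = function(x, theta) stats::dnorm(x, m0, sqrt(1 / b), log = TRUE),
    log_likelihood = function(u, x, theta)
      sum(stats::dnorm(u, x, 1, log = TRUE)),
    prior_moments = function(theta) list(mode = m0, covariance = matrix(1 / b, 1, 1)),
    update = function(mode, covariance, u, theta) {
      p <- toy_posterior(1 / covariance[1, 1], mode, u)
      list(mode = p$mean, covariance = matrix(1 / p$precision, 1, 1),
           log_evidence = p$free_energy)
    })
  resp <- toy_response_spec(sigma2 = sigma2, prior_mean = m0)
  resp$predict_all <- function(theta, phi, data) {
    sums <- vapply(data$inputs, function(u) sum(u), numeric(1))
    ns <- lengths(data$inputs)
    cbind((b * m0 + sums) / (b + ns),
          rep(max(0, 1 / sqrt(phi[1]) - b), length(ns)))
  }
  resp$observation_map <- function(trajectory, phi) {
    last <- trajectory[[length(trajectory)]]
    c(last$mode[1], max(0, 1 / sqrt(phi[1]) - b))
  }
  list(perceptual = perc, response = resp,
       prior = parameter_prior(mean = c(log_k = 0), sd = prior_sd))
}

#' Toy response model with a redundant gain parameter
#'
#' Variant of [toy_response_spec()] whose estimate channel is multiplied by a
#' gain `exp(log_gain)`; the generating observer has gain 1, so the extra
#' parameter is redundant and the model should lose a free-energy comparison
#' against the true model through the Occam (complexity) term.
#'
#' @inheritParams toy_response_spec
#' @return a `response_model` with `phi = (k, gain)`.
#' @export
toy_gain_response_spec <- function(sigma2 = "estimated", prior_mean = 0) {
  m0 <- prior_mean
  response_model(
    observation_map = function(trajectory, phi) {
      prior_prec <- 1 / trajectory[[1L]]$covariance[1, 1]
      last <- trajectory[[length(trajectory)]]
      c(phi[2] * last$mode[1], max(0, 1 / sqrt(phi[1]) - prior_prec))
    },
    response_dim = 2L,
    sigma2 = sigma2,
    phi_names = c("k", "gain"),
    phi_transform = c("log", "log"),
    predict_all = function(theta, phi, data) {
      beta <- theta[1]
      sums <- vapply(data$inputs, function(u) sum(u), numeric(1))
      ns <- lengths(data$inputs)
      cbind(phi[2] * (beta * m0 + sums) / (beta + ns),
            rep(max(0, 1 / sqrt(phi[1]) - beta), length(ns)))
    })
}
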