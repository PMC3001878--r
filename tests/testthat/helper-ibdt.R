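# Shared fixtures, all generated in code.

# toy dataset under given observer parameters
make_toy_data <- function(beta = 2, k = 0.01, sigma2 = 0.0025, n_trials = 50,
                          seed = 1, input_sd = 1) {
  cfg <- simulation_config(
    observer = toy_observer_config(beta = beta, k = k, sigma2 = sigma2),
    n_trials = n_trials, input_sd = input_sd, seed = seed)
  simulate_observer(cfg)
}

# shifted/scaled gamma-kernel log densities: skewed, log-concave targets with
# a known normalizer log(b) + lgamma(a); orientation optionally flipped
gamma_kernel_target <- function(a, b, shift = 0, flip = FALSE) {
  stopifnot(a > 1)
  f <- function(x) {
    z <- if (flip) (shift - x) / b else (x - shift) / b
    if (z <= 0) return(-Inf)
    (a - 1) * log(z) - z
  }
  mode <- if (flip) shift - b * (a - 1) else shift + b * (a - 1)
  list(target = log_joint_spec(f, 1), log_z = log(b) + lgamma(a), mode = mode)
}

# trapezoid quadrature oracle for a 1-D log density
grid_log_z <- function(f, lower, upper, n = 40001) {
  x <- seq(lower, upper, length.out = n)
  lf <- vapply(x, f, numeric(1))
  mx <- max(lf)
  w <- exp(lf - mx)
  h <- x[2] - x[1]
  mx + log(h * (sum(w) - (w[1] + w[n]) / 2))
}

# belief construction shortcut
gaussian_belief <- function(mean, variance, trial = 1L) {
  structure(list(trial = as.integer(trial), mode = mean,
                 covariance = matrix(variance, 1, 1),
                 perceptual_free_energy = 0, converged = TRUE),
            class = "belief")
}

# linear-Gaussian observer pair: one location parameter theta (identity
# transform), responses y_t = theta + noise; exact evidence available in
# closed form, so this is the conjugate oracle for the inversion layer
linear_gaussian_candidate <- function(sigma2, prior_mean = 0, prior_sd = 1) {
  perc <- perceptual_model(
    log_prior = function(x, theta) stats::dnorm(x, theta[1], 1, log = TRUE),
    log_likelihood = function(u, x, theta) 0,
    theta_names = "mu", theta_transform = "identity",
    prior_moments = function(theta) list(mode = theta[1], covariance = matrix(1, 1, 1)),
    update = function(mode, covariance, u, theta)
      list(mode = mode, covariance = covariance, log_evidence = 0))
  resp <- response_model(
    observation_map = function(trajectory, phi) trajectory[[1L]]$mode[1],
    response_dim = 1L, sigma2 = sigma2,
    predict_all = function(theta, phi, data)
      matrix(theta[1], length(data$inputs), 1))
  prior <- parameter_prior(mean = c(mu = prior_mean), sd = prior_sd)
  list(perceptual = perc, response = resp, prior = prior)
}

# exact log evidence of y_t = theta + e_t, theta ~ N(m0, s0^2), e ~ N(0, s2)
linear_gaussian_evidence <- function(y, m0, s02, s2) {
  tt <- length(y)
  post_prec <- 1 / s02 + tt / s2
  m_post <- (m0 / s02 + sum(y) / s2) / post_prec
  sum(stats::dnorm(y, m_post, sqrt(s2), log = TRUE)) +
    stats::dnorm(m_post, m0, sqrt(s02), log = TRUE) -
    stats::dnorm(m_post, m_post, sqrt(1 / post_prec), log = TRUE)
}
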