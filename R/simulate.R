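# Synthetic-observer simulator and the trial-data container. The simulator
# realizes the generative direction of the framework: draw a hidden state,
# draw sensory samples, run recognition, act optimally, add response noise.

#' Trial data container
#'
#' Aligned sequences of per-trial sensory inputs and observed responses.
#' Trials are indexed 0-based in files and metadata.
#'
#' @param inputs list of numeric vectors (one per trial; may have different
#'   lengths, may be empty).
#' @param responses numeric matrix, trials by response channels (`NA` codes a
#'   missing response).
#' @param labels optional character vector naming the response channels.
#' @param meta free-form provenance list (seed, generator settings, truth).
#' @return object of class `trial_data`.
#' @export
trial_data <- function(inputs, responses, labels = NULL, meta = list()) {
  if (is.atomic(inputs)) inputs <- as.list(inputs)
  responses <- as.matrix(responses)
  if (length(inputs) != nrow(responses) || length(inputs) < 1)
    ibdt_stop("inputs and responses must have equal length T >= 1",
              "ibdt_invalid_input")
  if (is.null(labels)) labels <- paste0("response_", seq_len(ncol(responses)))
  structure(list(inputs = lapply(inputs, as.numeric), responses = responses,
                 labels = labels, meta = meta),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Trial data: %d trials, %d response channel(s) [%s]\n",
              length(x$inputs), ncol(x$responses),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Simulation configuration
#'
#' The study conditions of the synthetic observer: the observer itself, the
#' number of trials, the distribution of the true (hidden) signal means, and
#' the master seed that fully determines all randomness.
#'
#' @param observer a [toy_observer_config()], or a list with elements
#'   `perceptual`, `response`, `theta`, `phi`, `sigma2`, `n_inputs` for a
#'   generic observer.
#' @param n_trials positive number of trials.
#' @param input_mean,input_sd mean and standard deviation of the Gaussian
#'   from which the true per-trial signal means are drawn.
#' @param seed integer seed; equal configs give bit-identical data.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(observer = toy_observer_config(), n_trials = 100L,
                              input_mean = 0, input_sd = 1, seed = 1L) {
  if (!is.finite(n_trials) || n_trials < 1 || !is.finite(input_sd) || input_sd < 0)
    ibdt_stop("invalid simulation configuration", "ibdt_config_error")
  structure(list(observer = observer, n_trials = as.integer(n_trials),
                 input_mean = input_mean, input_sd = input_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a synthetic observer
#'
#' For each trial: draw the hidden signal mean, draw the observer's samples
#' around it, run recognition, map the belief to the deterministic response,
#' and add zero-mean Gaussian response noise. Response noise deviates are
#' drawn even when `sigma2 = 0` so that configurations differing only in
#' noise level share all other random draws (paired comparisons).
#'
#' For the toy observer the number of samples per trial is the Bayes-optimal
#' `n*` and the sample-size channel mean is the continuous policy value
#' `max(0, 1/sqrt(k) - beta)`.
#'
#' @param config a [simulation_config()].
#' @return a [trial_data()] with full provenance in `meta`.
#' @export
simulate_observer <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tt <- config$n_trials
  x <- config$input_mean + config$input_sd * stats::rnorm(tt)
  obs <- config$observer
  if (inherits(obs, "toy_observer_config")) {
    n_star <- toy_optimal_n(obs$beta, obs$k)
    eps <- matrix(stats::rnorm(tt * max(1, n_star)), tt)
    inputs <- lapply(seq_len(tt), function(t)
      if (n_star == 0) numeric(0) else
        x[t] + sqrt(obs$signal_variance) * eps[t, seq_len(n_star)])
    sums <- vapply(inputs, sum, numeric(1))
    est <- (obs$beta * obs$prior_mean + sums / obs$signal_variance) /
      (obs$beta + n_star / obs$signal_variance)
    n_chan <- rep(toy_continuous_n(obs$beta, obs$k), tt)
    z <- matrix(stats::rnorm(tt * 2L), tt)
    responses <- cbind(est, n_chan) + sqrt(obs$sigma2) * z
    colnames(responses) <- NULL
    truth <- list(beta = obs$beta, k = obs$k, sigma2 = obs$sigma2,
                  prior_mean = obs$prior_mean, n_star = n_star)
    labels <- c("estimate", "sample_size")
  } else {
    perc <- obs$perceptual
    resp <- obs$response
    n_in <- obs$n_inputs
    eps <- matrix(stats::rnorm(tt * max(1, n_in)), tt)
    inputs <- lapply(seq_len(tt), function(t)
      if (n_in == 0) numeric(0) else x[t] + eps[t, seq_len(n_in)])
    Y <- matrix(NA_real_, tt, resp$response_dim)
    for (t in seq_len(tt)) {
      traj <- recognise_sequence_(perc, as.list(inputs[[t]]), obs$theta)
      Y[t, ] <- resp$observation_map(traj, obs$phi)
    }
    z <- matrix(stats::rnorm(tt * resp$response_dim), tt)
    responses <- Y + sqrt(obs$sigma2) * z
    truth <- list(theta = obs$theta, phi = obs$phi, sigma2 = obs$sigma2)
    labels <- paste0("response_", seq_len(resp$response_dim))
  }
  trial_data(inputs, responses, labels = labels,
             meta = list(true = truth, seed = config$seed,
                         input_mean = config$input_mean,
                         input_sd = config$input_sd,
                         n_trials = tt, hidden_states = x))
}

#' Default toy parameter prior
#'
#' Wide Gaussian prior on `(log beta, log k)` (SD 10 on the log scale,
#' centered at zero), with the noise treated as fixed unless requested.
#'
#' @inheritParams parameter_prior
#' @export
toy_default_prior <- function(sd = c(10, 10), noise = "fixed", noise_init = 1) {
  parameter_prior(mean = c(log_beta = 0, log_k = 0), sd = sd, noise = noise,
                  noise_init = noise_init)
}

#' Dense-grid Bayes oracle for the two-parameter toy inversion
#'
#' Exact (to grid resolution) posterior mean of `(log beta, log k)` by direct
#' numerical integration on an `n_grid` x `n_grid` grid spanning
#' `half_width_sd` prior standard deviations around the prior mean, with the
#' residual variance fixed. Serves as an independent check on the variational
#' Laplace inversion.
#'
#' @param data toy [trial_data()].
#' @param prior a [parameter_prior()] with independent components.
#' @param sigma2 fixed residual variance (scalar or per-channel length-2).
#' @param prior_mean_state prior mean of the subject's belief (toy
#'   `prior_mean`).
#' @param n_grid grid points per dimension.
#' @param half_width_sd half-width of the grid in prior SDs.
#' @return list with `mean` (posterior mean of `c(log_beta, log_k)`),
#'   `log_evidence`, grid marginals.
#' @export
toy_grid_posterior <- function(data, prior, sigma2, prior_mean_state = 0,
                               n_grid = 201L, half_width_sd = 4) {
  sds <- sqrt(diag(prior$covariance))
  g1 <- prior$mean[1] + seq(-half_width_sd, half_width_sd,
                            length.out = n_grid) * sds[1]
  g2 <- prior$mean[2] + seq(-half_width_sd, half_width_sd,
                            length.out = n_grid) * sds[2]
  s2 <- if (length(sigma2) == 1) rep(sigma2, 2) else sigma2
  sums <- vapply(data$inputs, sum, numeric(1))
  ns <- lengths(data$inputs)
  y1 <- data$responses[, 1]
  y2 <- data$responses[, 2]
  tt <- length(ns)
  # estimate channel depends on beta only
  beta <- exp(g1)
  ll1 <- vapply(seq_len(n_grid), function(i) {
    pred <- (beta[i] * prior_mean_state + sums) / (beta[i] + ns)
    -0.5 * sum((y1 - pred)^2) / s2[1] - 0.5 * tt * log(2 * pi * s2[1])
  }, numeric(1))
  # sample-size channel depends on both
  k <- exp(g2)
  npred <- pmax(0, outer(beta, 1 / sqrt(k), function(b, s) -b + s))
  S2y <- sum(y2^2); Sy <- sum(y2)
  ll2 <- -0.5 * (tt * npred^2 - 2 * npred * Sy + S2y) / s2[2] -
    0.5 * tt * log(2 * pi * s2[2])
  lp <- outer(stats::dnorm(g1, prior$mean[1], sds[1], log = TRUE),
              stats::dnorm(g2, prior$mean[2], sds[2], log = TRUE), `+`)
  lpost <- ll1 + ll2 + lp  # ll1 recycles down columns (rows index g1)
  mx <- max(lpost)
  w <- exp(lpost - mx)
  Z <- sum(w)
  d1 <- g1[2] - g1[1]; d2 <- g2[2] - g2[1]
  list(mean = c(log_beta = sum(rowSums(w) * g1) / Z,
                log_k = sum(colSums(w) * g2) / Z),
       log_evidence = mx + log(Z * d1 * d2),
       grid_log_beta = g1, grid_log_k = g2,
       marginal_log_beta = rowSums(w) / Z / d1,
       marginal_log_k = colSums(w) / Z / d2)
}
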