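# Subject-level recognition: sequential variational-Laplace inversion of a
# perceptual model. Each trial's posterior becomes the next trial's prior
# (assumed-density filtering in the Gaussian/Laplace family), so the belief
# trajectory is Markovian: lambda_t = f(lambda_{t-1}, u_t; theta).

#' Specify a subject's perceptual model
#'
#' The perceptual model is the subject's generative model of sensory input: a
#' prior over hidden states and an input likelihood, parameterized by the
#' perceptual parameters `theta` (on their natural, constrained scale).
#' Optional analytic pieces speed up and sharpen recognition: derivatives of
#' the log densities with respect to the hidden state, an exact conjugate
#' `update` rule, and closed-form prior moments.
#'
#' @param log_prior function `(x, theta) -> numeric`, log prior density of the
#'   hidden state vector `x`.
#' @param log_likelihood function `(u, x, theta) -> numeric`, log likelihood of
#'   one input `u` (possibly a vector of exchangeable samples) given `x`.
#' @param state_dim dimension of the hidden state.
#' @param theta_names character vector naming the perceptual parameters.
#' @param theta_transform per-parameter map from the unconstrained estimation
#'   scale to the natural scale: `"identity"` or `"log"` (natural = exp).
#' @param prior_grad,prior_hess optional derivatives of `log_prior` in `x`.
#' @param lik_grad,lik_hess optional derivatives of `log_likelihood` in `x`.
#' @param update optional exact update `(mode, covariance, u, theta) -> list`
#'   with elements `mode`, `covariance`, `log_evidence` (the log predictive
#'   density of `u`); used instead of the numeric Laplace fit when present.
#' @param prior_moments optional `(theta) -> list(mode, covariance)`.
#' @param init_state optional numeric start for the prior Laplace fit.
#' @return object of class `perceptual_model`.
#' @export
perceptual_model <- function(log_prior, log_likelihood, state_dim = 1L,
                             theta_names = character(),
                             theta_transform = rep("log", length(theta_names)),
                             prior_grad = NULL, prior_hess = NULL,
                             lik_grad = NULL, lik_hess = NULL,
                             update = NULL, prior_moments = NULL,
                             init_state = NULL) {
  stopifnot(is.function(log_prior), is.function(log_likelihood), state_dim >= 1)
  stopifnot(length(theta_transform) == length(theta_names),
            all(theta_transform %in% c("identity", "log")))
  structure(list(log_prior = log_prior, log_likelihood = log_likelihood,
                 state_dim = as.integer(state_dim), theta_names = theta_names,
                 theta_transform = theta_transform,
                 prior_grad = prior_grad, prior_hess = prior_hess,
                 lik_grad = lik_grad, lik_hess = lik_hess,
                 update = update, prior_moments = prior_moments,
                 init_state = init_state),
            class = "perceptual_model")
}

# map an unconstrained parameter subvector to the natural scale
to_natural <- function(par, transform) {
  out <- par
  out[transform == "log"] <- exp(par[transform == "log"])
  out
}

from_natural <- function(par, transform) {
  out <- par
  out[transform == "log"] <- log(par[transform == "log"])
  out
}

check_theta <- function(model, theta) {
  if (length(model$theta_names) > 0 && length(theta) != length(model$theta_names))
    ibdt_stop("theta has wrong length for the perceptual model", "ibdt_invalid_input")
  if (length(theta) > 0 && !all(is.finite(theta)))
    ibdt_stop("theta contains non-finite values", "ibdt_invalid_input")
  invisible(TRUE)
}

new_belief <- function(trial, mode, covariance, free_energy, converged = TRUE) {
  covariance <- symmetrize(as.matrix(covariance))
  asym <- max(abs(covariance - t(covariance))) / max(abs(covariance), 1e-300)
  if (asym > 1e-10) ibdt_stop("belief covariance is asymmetric", "ibdt_invalid_input")
  if (min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    ibdt_stop("belief covariance is not positive-definite", "ibdt_invalid_input")
  structure(list(trial = as.integer(trial), mode = as.numeric(mode),
                 covariance = covariance,
                 perceptual_free_energy = free_energy, converged = converged),
            class = "belief")
}

#' @export
print.belief <- function(x, ...) {
  cat(sprintf("Belief at trial %d: mode = %s, sd = %s, F = %.6g\n", x$trial,
              paste(signif(x$mode, 6), collapse = ", "),
              paste(signif(sqrt(diag(x$covariance)), 6), collapse = ", "),
              x$perceptual_free_energy))
  invisible(x)
}

#' Prior belief of a perceptual model
#'
#' The trial-0 representation: the Laplace fit of the prior alone. Its
#' perceptual free energy is 0 by convention (no data observed yet).
#'
#' @param model a [perceptual_model()].
#' @param theta perceptual parameters on the natural scale.
#' @return a `belief` at trial 0.
#' @export
prior_belief <- function(model, theta) {
  check_theta(model, theta)
  if (!is.null(model$prior_moments)) {
    pm <- model$prior_moments(theta)
    return(new_belief(0L, pm$mode, pm$covariance, 0))
  }
  init <- if (!is.null(model$init_state)) model$init_state else numeric(model$state_dim)
  target <- log_joint_spec(
    evaluate = function(x) model$log_prior(x, theta),
    dimension = model$state_dim,
    gradient = if (!is.null(model$prior_grad)) function(x) model$prior_grad(x, theta),
    hessian = if (!is.null(model$prior_hess))
      function(x) as.matrix(model$prior_hess(x, theta)))
  fit <- laplace_fit(target, init)
  new_belief(0L, fit$mode, fit$covariance, 0, fit$converged)
}

#' One step of recognition
#'
#' Updates the belief given one new input: the previous approximate posterior
#' is propagated as the new prior (Markov property) and the Laplace fit of
#' log-likelihood plus that Gaussian prior yields the new belief. The stored
#' perceptual free energy accumulates the per-step Laplace bound on the log
#' predictive density, so a trajectory's terminal value bounds the total log
#' evidence of the input sequence.
#'
#' @param model a [perceptual_model()].
#' @param prev previous `belief`.
#' @param input one sensory input (numeric scalar or vector).
#' @param theta perceptual parameters on the natural scale.
#' @return the updated `belief` at trial `prev$trial + 1`.
#' @export
recognise_step <- function(model, prev, input, theta) {
  check_theta(model, theta)
  stopifnot(inherits(prev, "belief"))
  if (!is.null(model$update)) {
    up <- model$update(prev$mode, prev$covariance, input, theta)
    return(new_belief(prev$trial + 1L, up$mode, up$covariance,
                      prev$perceptual_free_energy + up$log_evidence))
  }
  ch <- chol(prev$covariance)
  P <- chol2inv(ch)
  m <- prev$mode
  target <- log_joint_spec(
    evaluate = function(x)
      model$log_likelihood(input, x, theta) + lmvn_chol(x, m, ch),
    dimension = model$state_dim,
    gradient = if (!is.null(model$lik_grad))
      function(x) model$lik_grad(input, x, theta) - P %*% (x - m),
    hessian = if (!is.null(model$lik_hess))
      function(x) as.matrix(model$lik_hess(input, x, theta)) - P)
  fit <- tryCatch(laplace_fit(target, init = prev$mode),
                  ibdt_degenerate_curvature = function(e) stop(e))
  if (!fit$converged)
    warning(sprintf("recognition step at trial %d did not converge", prev$trial + 1L))
  new_belief(prev$trial + 1L, fit$mode, fit$covariance,
             prev$perceptual_free_energy + fit$free_energy, fit$converged)
}

#' Recognise a whole input sequence
#'
#' Runs [recognise_step()] over the inputs, returning the Markovian belief
#' trajectory of length `T + 1` (the prior plus one belief per input).
#'
#' @inheritParams recognise_step
#' @param inputs non-empty list of inputs (an atomic vector is treated as a
#'   sequence of scalar inputs).
#' @return object of class `belief_trajectory`: a list of `belief`s.
#' @export
recognise_sequence <- function(model, inputs, theta) {
  if (is.atomic(inputs)) inputs <- as.list(inputs)
  if (length(inputs) == 0)
    ibdt_stop("inputs must be non-empty", "ibdt_invalid_input")
  traj <- recognise_sequence_(model, inputs, theta)
  traj
}

# internal variant that tolerates an empty input list (trajectory = prior
# only); used by the simulator and the inversion when a trial has no samples
recognise_sequence_ <- function(model, inputs, theta) {
  b <- prior_belief(model, theta)
  traj <- vector("list", length(inputs) + 1L)
  traj[[1L]] <- b
  for (t in seq_along(inputs)) {
    b <- tryCatch(recognise_step(model, b, inputs[[t]], theta),
                  error = function(e) {
                    ibdt_stop(sprintf("recognition failed at trial %d: %s",
                                      t, conditionMessage(e)),
                              "ibdt_recognition_failure")
                  })
    traj[[t + 1L]] <- b
  }
  structure(traj, class = "belief_trajectory", theta = theta)
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat(sprintf("Belief trajectory over %d trials (plus prior)\n", length(x) - 1L))
  last <- x[[length(x)]]
  print(last)
  invisible(x)
}

#' Jacobian of the recognition step with respect to the previous mode
#'
#' Central finite-difference derivative of the updated posterior mode with
#' respect to the previous belief's mode. For conjugate-Gaussian models this
#' equals prior precision times posterior variance, i.e. learning effects are
#' linearly proportional to posterior uncertainty.
#'
#' @inheritParams recognise_step
#' @param rel_step relative finite-difference step.
#' @return a `state_dim` by `state_dim` matrix.
#' @export
evolution_jacobian <- function(model, prev, input, theta, rel_step = 1e-6) {
  d <- model$state_dim
  J <- matrix(0, d, d)
  for (i in seq_len(d)) {
    h <- rel_step * max(1, abs(prev$mode[i]))
    if (h == 0 || !is.finite(h))
      ibdt_stop("finite-difference step underflow", "ibdt_numerical_precision")
    bp <- prev; bp$mode[i] <- prev$mode[i] + h
    bm <- prev; bm$mode[i] <- prev$mode[i] - h
    mp <- recognise_step(model, bp, input, theta)$mode
    mm <- recognise_step(model, bm, input, theta)$mode
    J[, i] <- (mp - mm) / (2 * h)
  }
  J
}
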