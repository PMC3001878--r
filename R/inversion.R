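# Experimenter-level inversion: fit the response model (which embeds the
# subject's recognition process) to observed behaviour. The posterior over
# (theta, phi) is a Laplace fit of the penalized likelihood; its free energy
# is the model-comparison bound; its covariance is the identifiability
# diagnostic; and propagating it through recognition yields the experimenter's
# (inflated) reconstruction of the subject's belief.

#' Prior over the unconstrained (theta, phi) parameters
#'
#' Gaussian prior on the concatenated unconstrained parameter vector (log
#' scale for positive parameters). "Non-informative" priors are realized as
#' proper wide Gaussians: improper flats would break the free-energy
#' complexity term.
#'
#' @param mean named numeric vector of prior means.
#' @param sd numeric vector of prior standard deviations (used when
#'   `covariance` is not given; default 10, wide on the log scale).
#' @param covariance optional full prior covariance matrix.
#' @param noise `"fixed"` (residual variance taken from the response model)
#'   or `"estimated"` (optimized by the hyperparameter loop).
#' @param noise_init,noise_bounds starting value and search bounds for the
#'   residual variance when estimated.
#' @return object of class `parameter_prior`.
#' @export
parameter_prior <- function(mean, sd = rep(10, length(mean)), covariance = NULL,
                            noise = c("fixed", "estimated"), noise_init = 1,
                            noise_bounds = c(1e-8, 1e8)) {
  noise <- match.arg(noise)
  mean <- unlist(mean)
  if (is.null(covariance)) {
    stopifnot(length(sd) == length(mean), all(sd > 0))
    covariance <- diag(sd^2, length(mean))
  }
  covariance <- symmetrize(as.matrix(covariance))
  if (length(mean) > 0 &&
      min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    ibdt_stop("prior covariance must be positive-definite", "ibdt_invalid_input")
  structure(list(mean = mean, covariance = covariance, noise = noise,
                 noise_init = noise_init, noise_bounds = noise_bounds),
            class = "parameter_prior")
}

# build the per-trial predicted-response matrix for a packed parameter vector;
# returns NULL when recognition fails at the candidate (the caller penalizes
# the candidate with -Inf)
predicted_responses <- function(perc, resp, data, theta, phi) {
  if (!is.null(resp$predict_all))
    return(resp$predict_all(theta, phi, data))
  tt <- length(data$inputs)
  Y <- matrix(NA_real_, tt, resp$response_dim)
  for (t in seq_len(tt)) {
    traj <- recognise_sequence_(perc, as.list(data$inputs[[t]]), theta)
    Y[t, ] <- resp$observation_map(traj, phi)
  }
  Y
}

trajectories_at <- function(perc, data, theta) {
  lapply(data$inputs, function(u) recognise_sequence_(perc, as.list(u), theta))
}

#' Invert a response model given trial data
#'
#' Maximizes the Laplace free energy of the experimenter's generative model of
#' responses -- a penalized (regularized sum-of-squared-error) objective:
#' Gaussian response log-likelihood of the predicted responses, obtained by
#' running recognition at candidate `theta` and mapping beliefs through the
#' observation model at candidate `phi`, plus the Gaussian log-prior on the
#' unconstrained parameters. Candidates where recognition fails are penalized
#' with `-Inf`. If the prior requests it, the residual variance is optimized
#' by alternating with the parameter fit. Multistart (first start at the
#' prior mean, remaining starts jittered) guards against local optima.
#'
#' @param perc a [perceptual_model()].
#' @param resp a [response_model()].
#' @param data a [trial_data()] object.
#' @param prior a [parameter_prior()] over the concatenated unconstrained
#'   `(theta, phi)` vector (perceptual parameters first).
#' @param options list: `multistart` (default 5), `tol`, `max_iter`,
#'   `seed` (fixed sub-seeds for the start jitter), `start_sd_cap` (jitter
#'   standard deviation is `min(prior sd, start_sd_cap)`).
#' @return object of class `experimenter_posterior`: `mode` (named,
#'   unconstrained), `covariance`, `free_energy`, `loglik_at_mode`,
#'   `residuals` (trials x channels), `noise_variance`, `theta_hat` /
#'   `phi_hat` (natural scale), `belief_trajectories` at the mode, `prior`,
#'   `converged`, `starts` (free energy per start), `meta`.
#' @export
invert_observer <- function(perc, resp, data, prior, options = list()) {
  stopifnot(inherits(perc, "perceptual_model"), inherits(resp, "response_model"),
            inherits(data, "trial_data"), inherits(prior, "parameter_prior"))
  opts <- utils::modifyList(list(multistart = 5L, tol = 1e-8, max_iter = 100L,
                                 seed = 1L, start_sd_cap = 2), options)
  nt <- length(perc$theta_names)
  np <- length(resp$phi_names)
  p <- nt + np
  if (length(prior$mean) != p)
    ibdt_stop("prior dimension does not match theta/phi names", "ibdt_invalid_input")
  par_names <- c(if (nt) paste0("theta.", perc$theta_names),
                 if (np) paste0("phi.", resp$phi_names))

  Yobs <- data$responses
  n_inform <- sum(!is.na(Yobs))
  if (n_inform == 0) {
    # no-data identity: the posterior is the prior
    theta <- to_natural(prior$mean[seq_len(nt)], perc$theta_transform)
    phi <- to_natural(prior$mean[nt + seq_len(np)], resp$phi_transform)
    post <- structure(list(
      mode = stats::setNames(prior$mean, par_names),
      covariance = prior$covariance, free_energy = 0, loglik_at_mode = 0,
      residuals = matrix(NA_real_, nrow(Yobs), ncol(Yobs)),
      noise_variance = if (is.numeric(resp$sigma2)) resp$sigma2 else prior$noise_init,
      theta_hat = theta, phi_hat = phi,
      belief_trajectories = trajectories_at(perc, data, theta),
      prior = prior, data = data, perceptual = perc, response = resp,
      converged = TRUE, starts = numeric(0),
      meta = list(note = "no informative responses: posterior equals prior")),
      class = "experimenter_posterior")
    return(post)
  }
  if (n_inform < p && max(diag(prior$covariance)) > 1e8)
    ibdt_stop(paste("fewer informative data points than parameters under a",
                    "near-improper prior: the problem is ill-posed (complete-class",
                    "indeterminacy); supply proper priors"), "ibdt_ill_posed")

  ch0 <- chol(prior$covariance)
  log_prior_dens <- function(par) lmvn_chol(par, prior$mean, ch0)
  keep <- !is.na(Yobs)

  loglik <- function(par, s2) {
    theta <- to_natural(par[seq_len(nt)], perc$theta_transform)
    phi <- to_natural(par[nt + seq_len(np)], resp$phi_transform)
    Y <- tryCatch(predicted_responses(perc, resp, data, theta, phi),
                  error = function(e) NULL)
    if (is.null(Y) || any(!is.finite(Y[keep]))) return(-Inf)
    s2v <- channel_variances(resp, s2)
    S2 <- matrix(s2v, nrow(Yobs), ncol(Yobs), byrow = TRUE)
    sum(stats::dnorm(Yobs[keep], Y[keep], sqrt(S2[keep]), log = TRUE))
  }
  builder <- function(s2) log_joint_spec(function(par) loglik(par, s2) +
                                           log_prior_dens(par), p)

  estimate_noise <- identical(resp$sigma2, "estimated") ||
    prior$noise == "estimated"
  s2_fixed <- if (is.numeric(resp$sigma2)) resp$sigma2 else prior$noise_init

  sds <- sqrt(diag(prior$covariance))
  set.seed(opts$seed)
  starts <- list(prior$mean)
  if (opts$multistart > 1)
    for (i in seq_len(opts$multistart - 1L))
      starts[[i + 1L]] <- prior$mean +
        pmin(sds, opts$start_sd_cap) * stats::rnorm(p)

  best <- NULL
  best_s2 <- s2_fixed
  start_fes <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    res <- tryCatch({
      if (estimate_noise) {
        hf <- laplace_fit_hyper(builder, starts[[i]],
                                hyper_init = prior$noise_init,
                                hyper_bounds = prior$noise_bounds,
                                tol = opts$tol * 100,
                                max_iter = opts$max_iter)
        list(fit = hf$approx, s2 = hf$hyperparameter)
      } else {
        list(fit = laplace_fit(builder(s2_fixed), starts[[i]], tol = opts$tol,
                               max_iter = opts$max_iter),
             s2 = s2_fixed)
      }
    }, error = function(e) NULL)
    if (is.null(res)) next
    start_fes[i] <- res$fit$free_energy
    if (is.null(best) || res$fit$free_energy > best$free_energy) {
      best <- res$fit
      best_s2 <- res$s2
    }
  }
  if (is.null(best))
    ibdt_stop("all starts failed during inversion", "ibdt_convergence_failure")

  mode <- stats::setNames(best$mode, par_names)
  theta <- to_natural(best$mode[seq_len(nt)], perc$theta_transform)
  phi <- to_natural(best$mode[nt + seq_len(np)], resp$phi_transform)
  Yhat <- predicted_responses(perc, resp, data, theta, phi)
  residuals <- Yobs - Yhat
  structure(list(
    mode = mode, covariance = best$covariance, free_energy = best$free_energy,
    loglik_at_mode = loglik(best$mode, best_s2),
    residuals = residuals, noise_variance = best_s2,
    theta_hat = stats::setNames(theta, perc$theta_names),
    phi_hat = stats::setNames(phi, resp$phi_names),
    belief_trajectories = trajectories_at(perc, data, theta),
    prior = prior, data = data, perceptual = perc, response = resp,
    converged = best$converged, starts = start_fes,
    meta = list(noise_estimated = estimate_noise,
                note = if (estimate_noise)
                  "noise hyperparameter point-optimized; excluded from covariance")),
    class = "experimenter_posterior")
}

#' @export
print.experimenter_posterior <- function(x, ...) {
  cat("Experimenter posterior over (theta, phi)\n")
  cat("  mode (unconstrained):\n")
  print(signif(x$mode, 6))
  cat("  posterior sd:", signif(sqrt(diag(x$covariance)), 6), "\n")
  cat("  free energy:", signif(x$free_energy, 8), "nats;",
      "residual variance:", signif(x$noise_variance, 6), "\n")
  invisible(x)
}

#' Response free energy (log-evidence bound)
#'
#' Recomputes the Laplace free energy of an inverted response model from its
#' stored pieces: log-likelihood at the mode, minus half the prior-deviation
#' quadratic, plus half the log-determinant of posterior covariance times
#' prior precision (accuracy minus complexity). Deterministic given the
#' posterior; equals `post$free_energy` up to the optimizer tolerance.
#'
#' @param post an `experimenter_posterior`.
#' @param prior the [parameter_prior()] it was fitted under.
#' @return the free energy in nats.
#' @export
response_free_energy <- function(post, prior = post$prior) {
  if (length(post$mode) != length(prior$mean))
    ibdt_stop("posterior/prior dimension mismatch", "ibdt_invalid_input")
  dev <- as.numeric(post$mode) - prior$mean
  P0 <- chol2inv(chol(prior$covariance))
  ld <- as.numeric(determinant(post$covariance %*% P0, logarithm = TRUE)$modulus)
  post$loglik_at_mode - 0.5 * sum(dev * (P0 %*% dev)) + 0.5 * ld
}

#' Compare candidate observer models by free energy
#'
#' Fits each candidate (a perceptual model, response model, prior triple) via
#' [invert_observer()] and converts the free energies to posterior model
#' probabilities under uniform model priors (with max-subtraction). A
#' candidate whose fit fails receives probability zero.
#'
#' @param candidates list of lists with elements `perceptual`, `response`,
#'   `prior` and optionally `id`.
#' @param data a [trial_data()] object.
#' @param options passed to [invert_observer()].
#' @return object of class `comparison_result` with `model_ids`,
#'   `free_energies`, `posterior_model_probabilities`, `fits`.
#' @export
compare_models <- function(candidates, data, options = list()) {
  stopifnot(length(candidates) >= 2)
  ids <- vapply(seq_along(candidates), function(i) {
    if (!is.null(candidates[[i]]$id)) candidates[[i]]$id else paste0("model_", i)
  }, character(1))
  fits <- lapply(candidates, function(cand)
    tryCatch(invert_observer(cand$perceptual, cand$response, data,
                             cand$prior, options),
             error = function(e) {
               message("candidate fit failed: ", conditionMessage(e))
               NULL
             }))
  fes <- vapply(fits, function(f) if (is.null(f)) -Inf else f$free_energy,
                numeric(1))
  probs <- softmax_policy(-fes, temperature = 1)  # exp(F) normalized
  structure(list(model_ids = ids, free_energies = fes,
                 posterior_model_probabilities = probs, fits = fits),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  print(data.frame(model = x$model_ids, free_energy = x$free_energies,
                   probability = x$posterior_model_probabilities))
  invisible(x)
}

#' Reconstruct the subject's belief under experimental uncertainty
#'
#' First-order propagation of the experimenter's parameter uncertainty into
#' the subject's belief at a given trial: the reconstructed variance is the
#' subject's own posterior variance at the parameter mode plus
#' `J' Sigma_(theta,phi) J`, where `J` is the finite-difference sensitivity of
#' the subject's belief mode to the unconstrained parameters. The credible
#' interval is mean +/- z * sqrt(variance); the inflation is nonnegative, so
#' the experimenter's interval always contains the subject's own.
#'
#' @param post an `experimenter_posterior`.
#' @param trial 0-based trial index (trial indexing is 0-based throughout the
#'   package and its files).
#' @param level two-sided credible level (default 0.90).
#' @param rel_step relative finite-difference step for the sensitivities.
#' @return list with `mean`, `variance`, `subject_variance`,
#'   `credible_interval` (matrix, one row per state dimension).
#' @export
reconstruct_subject_belief <- function(post, trial, level = 0.90,
                                       rel_step = 1e-4) {
  tt <- length(post$belief_trajectories)
  if (trial < 0 || trial >= tt)
    ibdt_stop(sprintf("trial %d out of range [0, %d]", trial, tt - 1L),
              "ibdt_index_error")
  perc <- post$perceptual
  nt <- length(perc$theta_names)
  inputs <- as.list(post$data$inputs[[trial + 1L]])
  traj <- post$belief_trajectories[[trial + 1L]]
  bel <- traj[[length(traj)]]
  d <- length(bel$mode)
  p <- length(post$mode)
  belief_mode_at <- function(par) {
    theta <- to_natural(par[seq_len(nt)], perc$theta_transform)
    tr <- recognise_sequence_(perc, inputs, theta)
    tr[[length(tr)]]$mode
  }
  J <- matrix(0, p, d)
  for (j in seq_len(nt)) {  # the belief depends on theta only
    h <- rel_step * (1 + abs(post$mode[j]))
    pp <- as.numeric(post$mode); pp[j] <- pp[j] + h
    pm <- as.numeric(post$mode); pm[j] <- pm[j] - h
    J[j, ] <- (belief_mode_at(pp) - belief_mode_at(pm)) / (2 * h)
  }
  v_subj <- bel$covariance
  v_total <- v_subj + t(J) %*% post$covariance %*% J
  z <- stats::qnorm((1 + level) / 2)
  sdv <- sqrt(diag(as.matrix(v_total)))
  ci <- cbind(lower = bel$mode - z * sdv, upper = bel$mode + z * sdv)
  list(mean = bel$mode, variance = as.matrix(v_total),
       subject_variance = as.matrix(v_subj), credible_interval = ci,
       level = level)
}

#' Identifiability report from the posterior covariance
#'
#' Normalizes the posterior covariance to correlations and flags parameter
#' pairs whose absolute correlation exceeds the threshold: strong off-diagonal
#' structure signals near-non-identifiability. Parameters with (numerically)
#' zero variance are reported as degenerate rather than divided by zero.
#'
#' @param post an `experimenter_posterior` (or any list with a `covariance`
#'   and `mode`).
#' @param threshold absolute correlation above which a pair is flagged.
#' @return list with `correlation`, `flagged` (data frame of pairs),
#'   `degenerate` (indices with zero variance).
#' @export
identifiability_report <- function(post, threshold = 0.95) {
  V <- as.matrix(post$covariance)
  nm <- names(post$mode)
  if (is.null(nm)) nm <- paste0("p", seq_len(nrow(V)))
  v <- diag(V)
  degen <- which(v <= 1e-300)
  C <- matrix(NA_real_, nrow(V), ncol(V), dimnames = list(nm, nm))
  ok <- setdiff(seq_len(nrow(V)), degen)
  if (length(ok) > 0)
    C[ok, ok] <- V[ok, ok] / sqrt(tcrossprod(v[ok]))
  flagged <- data.frame(i = integer(), j = integer(), parameter_i = character(),
                        parameter_j = character(), correlation = numeric())
  for (i in seq_len(nrow(V) - 1L)) for (j in seq.int(i + 1L, nrow(V))) {
    if (i %in% degen || j %in% degen) next
    if (abs(C[i, j]) > threshold)
      flagged <- rbind(flagged, data.frame(
        i = i, j = j, parameter_i = nm[i], parameter_j = nm[j],
        correlation = C[i, j]))
  }
  list(correlation = C, flagged = flagged, degenerate = degen)
}
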