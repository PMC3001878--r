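# Simulation studies: parameter recovery (bias, RMSE, coverage), model
# recovery (free-energy ranking), response-noise scaling of the reconstructed
# subject belief, and the signal-power identifiability property. A master
# seed spawns per-replicate seeds by fixed arithmetic (master + index) so the
# studies are reproducible and trivially parallelizable.

#' Parameter-recovery study for the toy observer
#'
#' Repeatedly simulates the toy observer and re-estimates `(log beta, log k)`
#' by [invert_observer()] with the residual variance fixed at its true value,
#' collecting bias, RMSE and credible-interval coverage.
#'
#' @param n_replicates number of simulated datasets.
#' @param config a [simulation_config()] with a toy observer; replicate `i`
#'   uses seed `master_seed + i - 1`.
#' @param prior a [parameter_prior()]; default [toy_default_prior()].
#' @param level credible level for coverage.
#' @param master_seed integer master seed.
#' @param invert_options options for [invert_observer()] (default
#'   `multistart = 2` here: the study posterior is unimodal and truth-centred).
#' @return object of class `recovery_study`: per-replicate estimates and a
#'   `summary` data frame (truth, mean estimate, bias, rmse, coverage).
#' @export
recovery_study <- function(n_replicates = 20L, config = simulation_config(),
                           prior = toy_default_prior(), level = 0.90,
                           master_seed = 0L,
                           invert_options = list(multistart = 2L)) {
  obs <- config$observer
  stopifnot(inherits(obs, "toy_observer_config"))
  truth <- c(log_beta = log(obs$beta), log_k = log(obs$k))
  perc <- toy_perceptual_model(prior_mean = obs$prior_mean)
  resp <- toy_response_spec(sigma2 = obs$sigma2, prior_mean = obs$prior_mean)
  z <- stats::qnorm((1 + level) / 2)
  est <- sd <- cover <- matrix(NA_real_, n_replicates, 2L,
                               dimnames = list(NULL, names(truth)))
  fe <- rep(NA_real_, n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- master_seed + i - 1L
    dat <- simulate_observer(cfg)
    opts <- utils::modifyList(invert_options, list(seed = cfg$seed + 1L))
    post <- invert_observer(perc, resp, dat, prior, opts)
    est[i, ] <- as.numeric(post$mode)
    sd[i, ] <- sqrt(diag(post$covariance))
    cover[i, ] <- abs(est[i, ] - truth) <= z * sd[i, ]
    fe[i] <- post$free_energy
  }
  summary <- data.frame(
    parameter = names(truth), truth = truth,
    mean_estimate = colMeans(est), bias = colMeans(est) - truth,
    rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
    mean_posterior_sd = colMeans(sd), coverage = colMeans(cover),
    row.names = NULL)
  structure(list(estimates = est, posterior_sd = sd, coverage = cover,
                 free_energies = fe, truth = truth, level = level,
                 summary = summary, master_seed = master_seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%.0f%% intervals)\n",
              nrow(x$estimates), 100 * x$level))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Model-recovery study
#'
#' Simulates datasets under a generating toy observer and counts how often
#' each candidate model attains the highest response free energy.
#'
#' @param n_datasets number of simulated datasets.
#' @param config generating [simulation_config()] (toy observer).
#' @param candidates candidate list as for [compare_models()].
#' @param master_seed integer master seed.
#' @param invert_options options for [invert_observer()].
#' @return list with `wins` (named counts), `free_energies` (datasets x
#'   candidates matrix), `n_datasets`.
#' @export
model_recovery_study <- function(n_datasets, config, candidates,
                                 master_seed = 0L,
                                 invert_options = list(multistart = 2L)) {
  ids <- vapply(seq_along(candidates), function(i)
    if (!is.null(candidates[[i]]$id)) candidates[[i]]$id else paste0("model_", i),
    character(1))
  fes <- matrix(NA_real_, n_datasets, length(candidates),
                dimnames = list(NULL, ids))
  for (i in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- master_seed + i - 1L
    dat <- simulate_observer(cfg)
    opts <- utils::modifyList(invert_options, list(seed = cfg$seed + 1L))
    cmp <- compare_models(candidates, dat, opts)
    fes[i, ] <- cmp$free_energies
  }
  winner <- apply(fes, 1, which.max)
  wins <- stats::setNames(tabulate(winner, nbins = length(ids)), ids)
  list(wins = wins, free_energies = fes, n_datasets = n_datasets)
}

#' Response-noise scaling of the reconstructed subject belief
#'
#' Simulates one noise-free toy dataset and re-inverts it at each stated
#' response-noise level `sigma2`, reconstructing the subject's belief
#' variance at a chosen trial each time. Holding the realization fixed
#' isolates how the experimenter's parameter uncertainty -- and hence the
#' inflation of the reconstructed belief -- scales with the measurement
#' imprecision: the reconstructed variance is affine in `sigma2` with
#' positive slope. (A realized noise draw would add O(sigma) sampling jitter
#' to the plug-in subject variance on top of this relationship.)
#'
#' @param sigma2_grid positive noise variances.
#' @param config a [simulation_config()] with a toy observer (its own
#'   `sigma2` is ignored).
#' @param prior a [parameter_prior()].
#' @param trial 0-based trial at which to reconstruct.
#' @param invert_options options for [invert_observer()].
#' @return list with `sigma2`, `reconstructed_variance`,
#'   `subject_variance`, `r_squared`, `slope`, `intercept`.
#' @export
noise_scaling_study <- function(sigma2_grid = c(0.01, 0.02, 0.05, 0.1, 0.2,
                                                0.4, 0.7, 1),
                                config = simulation_config(n_trials = 60L),
                                prior = toy_default_prior(), trial = 0L,
                                invert_options = list(multistart = 1L)) {
  obs <- config$observer
  cfg0 <- config
  cfg0$observer$sigma2 <- 0
  dat0 <- simulate_observer(cfg0)
  perc <- toy_perceptual_model(prior_mean = obs$prior_mean)
  vars <- svars <- numeric(length(sigma2_grid))
  for (i in seq_along(sigma2_grid)) {
    s2 <- sigma2_grid[i]
    dat <- dat0
    resp <- toy_response_spec(sigma2 = s2, prior_mean = obs$prior_mean)
    opts <- utils::modifyList(invert_options, list(seed = config$seed + 1L))
    post <- invert_observer(perc, resp, dat, prior, opts)
    rec <- reconstruct_subject_belief(post, trial = trial)
    vars[i] <- rec$variance[1, 1]
    svars[i] <- rec$subject_variance[1, 1]
  }
  fit <- stats::lm(vars ~ sigma2_grid)
  list(sigma2 = sigma2_grid, reconstructed_variance = vars,
       subject_variance = svars,
       r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Signal-power identifiability study
#'
#' Paired comparison of the experimenter's posterior variances when the
#' magnitude of the hidden signal means is doubled, holding every random draw
#' fixed (same seed): stronger sensory signals should never make any
#' parameter variance larger.
#'
#' @param n_pairs number of paired replicates.
#' @param config base [simulation_config()] (toy observer).
#' @param prior a [parameter_prior()].
#' @param scale factor applied to `input_sd` for the strong-signal arm.
#' @param master_seed integer master seed.
#' @param invert_options options for [invert_observer()].
#' @return list with `variance_base`, `variance_scaled` (pairs x parameters),
#'   `fraction_non_increasing`.
#' @export
signal_power_study <- function(n_pairs = 20L,
                               config = simulation_config(n_trials = 60L),
                               prior = toy_default_prior(), scale = 2,
                               master_seed = 0L,
                               invert_options = list(multistart = 1L)) {
  obs <- config$observer
  perc <- toy_perceptual_model(prior_mean = obs$prior_mean)
  resp <- toy_response_spec(sigma2 = obs$sigma2, prior_mean = obs$prior_mean)
  v1 <- v2 <- matrix(NA_real_, n_pairs, 2L,
                     dimnames = list(NULL, c("log_beta", "log_k")))
  for (i in seq_len(n_pairs)) {
    base <- config
    base$seed <- master_seed + i - 1L
    strong <- base
    strong$input_sd <- base$input_sd * scale
    opts <- utils::modifyList(invert_options, list(seed = base$seed + 1L))
    p1 <- invert_observer(perc, resp, simulate_observer(base), prior, opts)
    p2 <- invert_observer(perc, resp, simulate_observer(strong), prior, opts)
    v1[i, ] <- diag(p1$covariance)
    v2[i, ] <- diag(p2$covariance)
  }
  list(variance_base = v1, variance_scaled = v2,
       fraction_non_increasing = mean(v2 <= v1 * (1 + 1e-6)))
}
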