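# Bayesian-decision-theoretic response layer: posterior risk (expected loss
# under the current belief), optimal actions, softmax policies, and response
# likelihoods.

#' Specify a loss function
#'
#' The loss `evaluate(action, x, phi)` is the cost of taking `action` when the
#' hidden state is `x`, given response parameters `phi` (natural scale).
#' Optional closed forms accelerate and sharpen risk evaluation: for quadratic
#' losses the posterior risk has an exact Gaussian-moment expression.
#'
#' @param evaluate function `(action, x, phi) -> numeric` cost.
#' @param action_space one of [action_space_continuous()],
#'   [action_space_finite()], [action_space_integer()].
#' @param phi_names character names of the response parameters involved.
#' @param closed_form_risk optional `(action, belief, phi) -> numeric`.
#' @param closed_form_argmin optional `(belief, phi) -> action`.
#' @return object of class `loss_spec`.
#' @export
loss_spec <- function(evaluate, action_space, phi_names = character(),
                      closed_form_risk = NULL, closed_form_argmin = NULL) {
  stopifnot(is.function(evaluate), is.list(action_space))
  structure(list(evaluate = evaluate, action_space = action_space,
                 phi_names = phi_names, closed_form_risk = closed_form_risk,
                 closed_form_argmin = closed_form_argmin),
            class = "loss_spec")
}

#' @rdname loss_spec
#' @param lower,upper bounds of the action space.
#' @export
action_space_continuous <- function(lower = -Inf, upper = Inf) {
  list(type = "continuous", lower = lower, upper = upper)
}

#' @rdname loss_spec
#' @param actions vector or list of admissible actions.
#' @export
action_space_finite <- function(actions) {
  list(type = "finite", actions = actions)
}

#' @rdname loss_spec
#' @export
action_space_integer <- function(lower = 0, upper = 1e6) {
  list(type = "integer", lower = lower, upper = upper)
}

#' Squared-error loss
#'
#' `(a - x)^2` (summed over coordinates). Its posterior risk under a Gaussian
#' belief is `(a - mu)^2 + tr(Sigma)` and the optimal action is the posterior
#' mean, both supplied in closed form.
#'
#' @return a `loss_spec`.
#' @export
squared_error_loss <- function() {
  loss_spec(
    evaluate = function(action, x, phi) sum((action - x)^2),
    action_space = action_space_continuous(),
    closed_form_risk = function(action, belief, phi)
      sum((action - belief$mode)^2) + sum(diag(belief$covariance)),
    closed_form_argmin = function(belief, phi) belief$mode)
}

gauss_hermite_grid <- function(order, d) {
  gh <- pracma::gaussHermite(order)
  if (d == 1) return(list(z = matrix(gh$x, ncol = 1), w = gh$w / sqrt(pi)))
  idx <- do.call(expand.grid, rep(list(seq_len(order)), d))
  z <- matrix(gh$x[as.matrix(idx)], ncol = d)
  w <- apply(matrix(gh$w[as.matrix(idx)], ncol = d), 1, prod) / pi^(d / 2)
  list(z = z, w = w)
}

quadrature_risk <- function(loss, belief, action, phi, order) {
  d <- length(belief$mode)
  grid <- gauss_hermite_grid(order, d)
  L <- chol(belief$covariance)
  pts <- sweep(sqrt(2) * grid$z %*% L, 2, belief$mode, `+`)
  vals <- vapply(seq_len(nrow(pts)), function(i)
    loss$evaluate(action, pts[i, ], phi), numeric(1))
  sum(grid$w * vals)
}

#' Posterior risk of an action
#'
#' Expected loss under the Gaussian belief: closed form when the loss supplies
#' one, otherwise Gauss-Hermite quadrature (default order 21 per state
#' dimension, doubled automatically if refinement changes the value by more
#' than 1e-8; state dimension at most 4).
#'
#' @param loss a [loss_spec()].
#' @param belief a `belief`.
#' @param action admissible action.
#' @param phi response parameters on the natural scale.
#' @param order Gauss-Hermite order per dimension.
#' @return the expected loss (numeric scalar).
#' @export
posterior_risk <- function(loss, belief, action, phi = numeric(), order = 21) {
  stopifnot(inherits(loss, "loss_spec"), inherits(belief, "belief"))
  if (!is.null(loss$closed_form_risk))
    return(loss$closed_form_risk(action, belief, phi))
  d <- length(belief$mode)
  if (d > 4)
    ibdt_stop("quadrature risk supports state dimension <= 4", "ibdt_unsupported_dimension")
  r1 <- quadrature_risk(loss, belief, action, phi, order)
  for (rep in 1:2) {
    order2 <- 2L * order + 1L
    r2 <- quadrature_risk(loss, belief, action, phi, order2)
    if (abs(r2 - r1) <= 1e-8) return(r2)
    r1 <- r2; order <- order2
  }
  r1
}

#' Optimal (risk-minimizing) action
#'
#' Argmin of [posterior_risk()] over the action space: finite sets by
#' enumeration (ties broken toward the lowest index and flagged in attribute
#' `"tie"`), continuous spaces by bounded minimization with three starts,
#' integer spaces by continuous relaxation followed by comparison of the
#' floor/ceiling neighbours (and the lower bound).
#'
#' @inheritParams posterior_risk
#' @return the optimal action; attribute `"risk"` carries its posterior risk.
#' @export
optimal_action <- function(loss, belief, phi = numeric()) {
  if (!is.null(loss$closed_form_argmin)) {
    a <- loss$closed_form_argmin(belief, phi)
    attr(a, "risk") <- posterior_risk(loss, belief, a, phi)
    return(a)
  }
  sp <- loss$action_space
  risk <- function(a) posterior_risk(loss, belief, a, phi)
  if (sp$type == "finite") {
    acts <- sp$actions
    risks <- vapply(seq_along(acts), function(i) risk(acts[[i]]), numeric(1))
    if (all(!is.finite(risks)))
      ibdt_stop("all actions have infinite risk", "ibdt_invalid_loss")
    near <- which(risks <= min(risks) + 1e-12 * max(1, abs(min(risks))))
    i <- near[1L]  # ties break toward the lowest index
    tie <- length(near) > 1L
    a <- acts[[i]]
    attr(a, "risk") <- risks[i]
    attr(a, "tie") <- tie
    return(a)
  }
  if (!is.finite(sp$lower) || !is.finite(sp$upper))
    ibdt_stop("continuous/integer action spaces must be bounded (or the loss must supply a closed-form argmin)",
              "ibdt_invalid_loss")
  # scalar bounded minimization with 3 multistarts over subintervals
  cuts <- seq(sp$lower, sp$upper, length.out = 4)
  cands <- lapply(1:3, function(i)
    stats::optimize(risk, interval = c(cuts[i], cuts[i + 1])))
  cands <- c(cands, list(list(minimum = sp$lower, objective = risk(sp$lower)),
                         list(minimum = sp$upper, objective = risk(sp$upper))))
  objs <- vapply(cands, `[[`, numeric(1), "objective")
  a_cont <- cands[[which.min(objs)]]$minimum
  if (sp$type == "integer") {
    cand_n <- unique(pmin(pmax(c(sp$lower, floor(a_cont), ceiling(a_cont)),
                               sp$lower), sp$upper))
    cand_n <- sort(cand_n)
    risks <- vapply(cand_n, risk, numeric(1))
    i <- which.min(risks)  # ties resolve to the smallest n
    a <- cand_n[i]
    attr(a, "risk") <- risks[i]
    return(a)
  }
  attr(a_cont, "risk") <- min(objs)
  a_cont
}

#' Softmax (logit) policy over risks
#'
#' Choice probabilities proportional to `exp(-risk / temperature)`, computed
#' with max-subtraction for overflow safety. As the temperature tends to zero
#' the policy degenerates onto the risk-minimizing action.
#'
#' @param risks finite numeric vector of posterior risks (entries of `Inf`
#'   denote inadmissible actions and receive probability zero).
#' @param temperature positive decision-noise temperature.
#' @return probability vector summing to one.
#' @export
softmax_policy <- function(risks, temperature) {
  if (length(temperature) != 1 || !is.finite(temperature) || temperature <= 0)
    ibdt_stop("temperature must be a positive finite scalar", "ibdt_invalid_input")
  if (any(is.na(risks)))
    ibdt_stop("risks must not contain NA", "ibdt_invalid_input")
  if (all(!is.finite(risks)))
    ibdt_stop("all risks are infinite", "ibdt_invalid_input")
  z <- -risks / temperature
  z <- z - max(z[is.finite(z)])
  p <- exp(z)
  p / sum(p)
}

#' Specify a response model
#'
#' The experimenter's model of observed responses: an observation mapping `g`
#' from the belief trajectory of a trial to a predicted response vector, plus
#' zero-mean Gaussian residuals (variance fixed or estimated) for continuous
#' channels, or a softmax policy for a categorical channel.
#'
#' @param observation_map function `(trajectory, phi) -> numeric` predicted
#'   response of length `response_dim`; the trajectory is the trial's
#'   `belief_trajectory` (its first element is the prior belief).
#' @param response_dim number of response channels.
#' @param sigma2 residual variance: a positive scalar, a length-`response_dim`
#'   vector of per-channel variances, or `"estimated"`.
#' @param phi_names,phi_transform response parameters and their unconstrained
#'   -to-natural transforms (`"identity"` or `"log"`).
#' @param loss optional [loss_spec()] the mapping derives from.
#' @param predict_all optional vectorized predictor
#'   `(theta, phi, data) -> T x response_dim matrix`, used by the inversion
#'   when present (must agree with looping `observation_map` over trials).
#' @param type `"gaussian"` or `"categorical"`.
#' @param risks_map for categorical models: `(trajectory, phi) -> risks`.
#' @param temperature for categorical models: `(phi) -> positive scalar`.
#' @return object of class `response_model`.
#' @export
response_model <- function(observation_map, response_dim, sigma2 = "estimated",
                           phi_names = character(),
                           phi_transform = rep("log", length(phi_names)),
                           loss = NULL, predict_all = NULL,
                           type = c("gaussian", "categorical"),
                           risks_map = NULL, temperature = NULL) {
  type <- match.arg(type)
  if (is.numeric(sigma2)) {
    if (!all(sigma2 > 0)) ibdt_stop("sigma2 must be positive", "ibdt_invalid_input")
  } else if (!identical(sigma2, "estimated")) {
    ibdt_stop("sigma2 must be numeric or \"estimated\"", "ibdt_invalid_input")
  }
  stopifnot(length(phi_transform) == length(phi_names),
            all(phi_transform %in% c("identity", "log")))
  structure(list(observation_map = observation_map,
                 response_dim = as.integer(response_dim), sigma2 = sigma2,
                 phi_names = phi_names, phi_transform = phi_transform,
                 loss = loss, predict_all = predict_all, type = type,
                 risks_map = risks_map, temperature = temperature),
            class = "response_model")
}

# per-channel variance vector from a response model and a scalar estimate
channel_variances <- function(resp, sigma2) {
  s2 <- if (is.numeric(resp$sigma2)) resp$sigma2 else sigma2
  if (length(s2) == 1) rep(s2, resp$response_dim) else s2
}

#' Log-likelihood of one observed response
#'
#' Gaussian log density of the residual `observed - g(trajectory, phi)` for
#' continuous channels (missing channels, coded `NA`, contribute zero); log
#' softmax probability of the observed action index for categorical models.
#'
#' @param resp a [response_model()].
#' @param trajectory the trial's `belief_trajectory`.
#' @param phi response parameters on the natural scale.
#' @param observed numeric response vector, or an action index for
#'   categorical models.
#' @param sigma2 residual variance used when `resp$sigma2 = "estimated"`.
#' @return log-likelihood contribution of the trial.
#' @export
response_loglik <- function(resp, trajectory, phi, observed, sigma2 = NULL) {
  stopifnot(inherits(resp, "response_model"))
  if (resp$type == "categorical") {
    risks <- resp$risks_map(trajectory, phi)
    p <- softmax_policy(risks, resp$temperature(phi))
    return(log(p[[observed]]))
  }
  if (length(observed) != resp$response_dim)
    ibdt_stop("observed response has wrong dimension", "ibdt_invalid_input")
  s2 <- channel_variances(resp, sigma2)
  yhat <- resp$observation_map(trajectory, phi)
  keep <- !is.na(observed)
  if (!any(keep)) return(0)
  sum(stats::dnorm(observed[keep], yhat[keep], sqrt(s2[keep]), log = TRUE))
}
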