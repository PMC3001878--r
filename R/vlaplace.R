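# Variational Bayes under the Laplace approximation: a generic engine used at
# the subject level (recognition of hidden states) and at the experimenter
# level (inversion of the response model).

ibdt_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ibdt_error")))
}

#' Specify a log joint density to be approximated
#'
#' Wraps the log of an unnormalized joint density (e.g. log-likelihood plus
#' log-prior) together with its dimension and optional analytic derivatives.
#' A return value of `-Inf` from `evaluate` signals zero density.
#'
#' @param evaluate function mapping a numeric vector of length `dimension`
#'   to a single finite numeric (or `-Inf`).
#' @param dimension positive integer, length of the argument vector.
#' @param gradient optional function vector -> vector (same length).
#' @param hessian optional function vector -> square matrix.
#' @return an object of class `log_joint_spec`.
#' @seealso [laplace_fit()]
#' @export
log_joint_spec <- function(evaluate, dimension, gradient = NULL, hessian = NULL) {
  stopifnot(is.function(evaluate), length(dimension) == 1L, dimension >= 1)
  structure(list(evaluate = evaluate, dimension = as.integer(dimension),
                 gradient = gradient, hessian = hessian),
            class = "log_joint_spec")
}

# central finite differences; rel_step per spec'd default for gradients
fd_gradient <- function(f, x, rel_step = 1e-5) {
  d <- length(x)
  g <- numeric(d)
  for (i in seq_len(d)) {
    h <- rel_step * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# second differences use a larger step: the cancellation floor for f''
# scales as eps * |f| / h^2
fd_hessian <- function(f, x, rel_step = 1.2e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  h <- rel_step * pmax(1, abs(x))
  f0 <- f(x)
  for (i in seq_len(d)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
  }
  if (d > 1) {
    for (i in seq_len(d - 1)) {
      for (j in seq.int(i + 1, d)) {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

symmetrize <- function(M) (M + t(M)) / 2

target_grad <- function(target, x) {
  if (!is.null(target$gradient)) target$gradient(x) else fd_gradient(target$evaluate, x)
}

target_hess <- function(target, x) {
  if (!is.null(target$hessian)) symmetrize(target$hessian(x)) else
    symmetrize(fd_hessian(target$evaluate, x))
}

#' Laplace fit of an unnormalized log density
#'
#' Finds a local maximizer of the log joint by Newton ascent (analytic
#' derivatives when supplied, central finite differences otherwise) with
#' step-halving, and returns the Gaussian (Laplace) approximation around it:
#' mode, covariance (inverse negative Hessian) and the Laplace free energy
#' \deqn{F = \log p(\hat x) + \tfrac12 \log\det\Sigma + \tfrac d2 \log 2\pi,}
#' a bound approximation to the log normalizer. The sequence of objective
#' values never decreases.
#'
#' @param target a [log_joint_spec()].
#' @param init numeric start vector of length `target$dimension` where
#'   `target$evaluate` is finite.
#' @param tol absolute free-energy change declaring convergence.
#' @param max_iter maximum Newton iterations; exceeded fits are returned with
#'   `converged = FALSE`.
#' @param grad_tol gradient sup-norm declaring convergence.
#' @param max_halvings step halvings allowed per iteration.
#' @return object of class `gaussian_approx` with elements `mode`,
#'   `covariance`, `free_energy`, `converged`, `n_iter`, `objective_trace`.
#' @examples
#' # Laplace is exact for quadratic targets
#' fit <- laplace_fit(log_joint_spec(function(x) -(x - 3)^2 / 8, 1), init = 0)
#' c(fit$mode, fit$covariance)  # 3, 4
#' @export
laplace_fit <- function(target, init, tol = 1e-8, max_iter = 200L,
                        grad_tol = 1e-6, max_halvings = 32L) {
  stopifnot(inherits(target, "log_joint_spec"))
  x <- as.numeric(init)
  if (length(x) != target$dimension)
    ibdt_stop("init has wrong length for target dimension", "ibdt_invalid_input")
  d <- length(x)
  f <- target$evaluate
  f0 <- f(x)
  if (!is.finite(f0))
    ibdt_stop("objective is not finite at the initial point", "ibdt_invalid_input")

  trace <- f0
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    g <- target_grad(target, x)
    if (max(abs(g)) < grad_tol) { converged <- TRUE; n_iter <- iter - 1L; break }
    H <- target_hess(target, x)
    # modified Newton: flip any non-negative curvature directions so the
    # step is always an ascent direction, with sane scaling far from the
    # mode; the terminal curvature check below uses the raw Hessian
    eg <- eigen(-H, symmetric = TRUE)
    dmod <- pmax(abs(eg$values), 1e-8 * max(abs(eg$values), 1))
    step <- eg$vectors %*% ((crossprod(eg$vectors, g)) / dmod)
    step <- as.numeric(step)
    f1 <- f(x + step)
    nh <- 0L
    while ((!is.finite(f1) || f1 < f0) && nh < max_halvings) {
      step <- step / 2
      f1 <- f(x + step)
      nh <- nh + 1L
    }
    if (!is.finite(f1) || f1 < f0) {
      # no improving step found in this direction; treat as converged at x
      converged <- max(abs(g)) < sqrt(grad_tol)
      break
    }
    x <- x + step
    df <- f1 - f0
    f0 <- f1
    trace <- c(trace, f1)
    if (abs(df) < tol) { converged <- TRUE; break }
  }

  H <- target_hess(target, x)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) >= 0)
    ibdt_stop(sprintf(
      "Hessian is not negative-definite at the terminal point (eigenvalue %.3e)",
      max(ev)), "ibdt_degenerate_curvature")
  A <- -H
  if (kappa(A) > 1e12) {
    A <- A + diag(1e-10 * sum(diag(A)) / d, d)
    warning("ill-conditioned curvature: jitter added before inversion")
  }
  Sigma <- symmetrize(chol2inv(chol(A)))
  fe <- f0 + 0.5 * as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
    d / 2 * log(2 * pi)
  structure(list(mode = x, covariance = Sigma, free_energy = fe,
                 converged = converged, n_iter = n_iter,
                 objective_trace = trace),
            class = "gaussian_approx")
}

#' @export
print.gaussian_approx <- function(x, ...) {
  cat("Laplace (Gaussian) approximation\n")
  cat("  mode:", signif(x$mode, 6), "\n")
  cat("  free energy:", signif(x$free_energy, 8), "nats\n")
  cat("  converged:", x$converged, "after", x$n_iter, "iterations\n")
  invisible(x)
}

#' Laplace fit with noise-hyperparameter optimization
#'
#' Alternates a [laplace_fit()] of the parameters with a one-dimensional
#' maximization of the Laplace free energy over the log of a positive noise
#' hyperparameter (e.g. a residual variance), until the free energy changes by
#' less than `tol` between outer iterations.
#'
#' @param target_builder function mapping a positive hyperparameter to a
#'   [log_joint_spec()].
#' @param init numeric start vector for the parameters.
#' @param hyper_init positive starting hyperparameter; also the value used
#'   when `fixed = TRUE`.
#' @param tol free-energy change declaring outer convergence.
#' @param max_outer maximum outer alternations.
#' @param hyper_bounds positive bounds for the hyperparameter search.
#' @param fixed if `TRUE` no hyperparameter update is performed and the result
#'   is identical to `laplace_fit(target_builder(hyper_init), init, ...)`.
#' @param ... passed to [laplace_fit()].
#' @return list with elements `approx` (a `gaussian_approx`),
#'   `hyperparameter`, `converged`, `n_outer`.
#' @export
laplace_fit_hyper <- function(target_builder, init, hyper_init = 1, tol = 1e-6,
                              max_outer = 50L, hyper_bounds = c(1e-6, 1e6),
                              fixed = FALSE, ...) {
  stopifnot(hyper_init > 0, all(hyper_bounds > 0), hyper_bounds[1] < hyper_bounds[2])
  if (fixed) {
    fit <- laplace_fit(target_builder(hyper_init), init, ...)
    return(list(approx = fit, hyperparameter = hyper_init,
                converged = fit$converged, n_outer = 0L))
  }
  h <- min(max(hyper_init, hyper_bounds[1]), hyper_bounds[2])
  x <- as.numeric(init)
  fe_old <- -Inf
  converged <- FALSE
  n_outer <- 0L
  best <- NULL
  for (outer in seq_len(max_outer)) {
    n_outer <- outer
    fit <- laplace_fit(target_builder(h), x, ...)
    x <- fit$mode
    fe_of_logh <- function(lh) {
      laplace_fit(target_builder(exp(lh)), x, ...)$free_energy
    }
    opt <- stats::optimize(fe_of_logh, interval = log(hyper_bounds), maximum = TRUE,
                           tol = 1e-6)
    h <- exp(opt$maximum)
    fit <- laplace_fit(target_builder(h), x, ...)
    x <- fit$mode
    if (is.null(best) || fit$free_energy > best$approx$free_energy)
      best <- list(approx = fit, hyperparameter = h)
    if (abs(fit$free_energy - fe_old) < tol) { converged <- TRUE; break }
    fe_old <- fit$free_energy
  }
  if (!converged)
    warning("hyperparameter alternation did not converge; best iterate returned")
  if (h <= hyper_bounds[1] * 1.01 || h >= hyper_bounds[2] / 1.01)
    warning("hyperparameter is at its search bound")
  list(approx = best$approx, hyperparameter = best$hyperparameter,
       converged = converged, n_outer = n_outer)
}

# log density of a multivariate normal given a precomputed cholesky of the
# covariance; scalar fast path avoids matrix overhead in inner loops
lmvn_chol <- function(x, mean, chol_cov) {
  d <- length(x)
  z <- forwardsolve(t(chol_cov), x - mean)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_cov))) - 0.5 * sum(z^2)
}
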