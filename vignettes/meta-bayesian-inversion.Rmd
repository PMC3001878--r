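---
title: "Meta-Bayesian inversion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-Bayesian inversion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdt)
```

## The two-level model

`ibdt` treats behavioural data as the output of an observer who is
themselves performing Bayesian inference. Two generative models are
therefore in play, and the package keeps them strictly separated.

The **perceptual model** is the subject's: a prior $p(x\mid\theta)$ over
hidden states $x$ and a likelihood $p(u\mid x,\theta)$ for sensory inputs
$u$, with perceptual parameters $\theta$ (e.g. a prior precision). The
subject cannot compute exact posteriors for general models, and neither do
we on their behalf: *recognition* is implemented as variational Bayes under
the Laplace approximation. The belief after each input is a Gaussian with
sufficient statistics $\lambda_t = (\mu_t, \Sigma_t)$ found by maximizing
the log joint; the attained free energy
$F = \log p(u,\hat x) + \tfrac12\log\det\Sigma + \tfrac d2\log 2\pi$
bounds the log evidence. Each posterior is propagated as the next prior
(assumed-density filtering), which makes the belief sequence a Markovian
state-space trajectory $\lambda_t = f(\lambda_{t-1}, u_t;\theta)$. Gaussian
propagation is exact within the Laplace family, which is why it was chosen
over, say, matching a wider exponential family. A consequence worth testing
(and tested): the Jacobian $\partial f/\partial\lambda$ equals prior
precision times posterior covariance in the conjugate case, so learning
effects are linearly proportional to perceptual uncertainty.

The **response model** is the experimenter's: decisions arise from a loss
$\ell(a,x;\varphi)$ via posterior risk (expected loss under the current
belief), and measured responses are the observation map $g(\lambda;\varphi)$
plus zero-mean Gaussian residuals with variance $\sigma^2$ (a softmax
policy is available for categorical channels, with the temperature treated
as one more response parameter on the log scale). Because $g$ consumes the
recognition trajectory, the response model *subsumes* the perceptual model:
fitting it to data simultaneously estimates the subject's prior ($\theta$)
and preferences ($\varphi$).

**Inversion** maximizes the Laplace free energy of the response model over
the unconstrained $(\theta,\varphi)$ vector — a penalized sum of squared
residuals plus the Gaussian log prior — and reports the posterior mode,
covariance (inverse curvature including prior precision), free energy,
residuals, and the belief trajectory at the mode. The free energy is
accuracy minus complexity, so richer models pay an automatic Occam penalty
in `compare_models()`. The posterior covariance doubles as the
identifiability diagnostic: strongly correlated pairs mean the design
cannot separate those parameters.

Finally, `reconstruct_subject_belief()` propagates experimenter uncertainty
into the estimate of the subject's belief to first order:
$\mathrm{var}_{\text{total}} = \Sigma_{\text{subject}} +
J^\top \Sigma_{\theta\varphi} J$ with $J$ the finite-difference sensitivity
of the belief mode to the parameters. The inflation is nonnegative, so the
experimenter's credible interval always contains the plug-in subject
interval — estimated subjective uncertainty is an upper bound that tightens
with better measurements.

## The worked example and its closed forms

The toy task: estimate the mean of a unit-variance Gaussian signal, paying
$k$ per sample. With prior $\mathcal N(m_0, 1/\beta)$, conjugacy gives
posterior precision $\beta + n$ and the familiar shrunken mean; the
posterior risk of reporting the posterior mean after $n$ samples is
$1/(\beta+n) + kn$, minimized over the integers at the floor/ceiling
neighbours of $\max(0, 1/\sqrt k - \beta)$. If $k = 0$ the risk decreases
forever and no stopping point exists. The optimal estimator is always the
posterior mean. Every generic code path (numeric Laplace recognition,
quadrature risk, integer action search, the full inversion) is tested
against these closed forms; brute force over $n$, not the closed form, is
the binding definition of the optimal sample size.

Two representational choices deserve a note:

* **Belief free energy is cumulative.** A `belief` stores the running sum
  of per-step Laplace bounds, so the terminal value of a trajectory bounds
  the log evidence of the whole input sequence and can be compared directly
  with the exact Gaussian marginal likelihood. The per-step increment is
  recoverable by differencing consecutive beliefs.
* **The sample-size channel is real-valued.** The Gaussian response channel
  for "how many samples did you take" uses the continuous policy value
  $\max(0, 1/\sqrt k - \beta)$ as its mean, in both the simulator and the
  inversion, keeping the generative and fitted models identical and the
  objective smooth. The integer Bayes action $n^*$ remains available
  (`toy_optimal_n()`, `toy_response_map()`, or a softmax channel); under
  the default configuration ($\beta = 2$, $k = 0.01$) the two coincide
  exactly since $1/\sqrt k - \beta = 8$.

## What the simulator emulates — and what it does not

`simulate_observer()` draws, per trial: a hidden signal mean from
$\mathcal N(\text{input\_mean}, \text{input\_sd}^2)$, the observer's $n^*$
unit-variance samples around it, the deterministic optimal response, and
Gaussian response noise. A master seed fixes every draw; noise deviates are
drawn even at $\sigma^2 = 0$ so that configurations differing only in noise
share all other randomness.

The generator emulates a *well-specified, stationary, rational* observer:
the fitted model and the generating model coincide. Passing recovery and
coverage tests therefore demonstrates that the inversion machinery is
consistent and calibrated — not that real subjects are Bayesian, rational,
or stationary. Real data add model misspecification, lapses, learning of
$\theta$ itself, and serial dependencies, none of which the generator
produces. Model comparison on such data can only rank the candidate models
actually specified.

## Study conditions and defaults

All positive parameters ($\beta$, $k$, $\sigma^2$, temperature) are
estimated on the log scale with Gaussian priors; "non-informative" priors
are proper wide Gaussians (SD 10 on the log scale) because improper flats
break the complexity term of the free energy. The default study conditions,
chosen once and used by the tests and the acceptance script alike:

* Toy observer $\beta = 2$, $k = 0.01$, $\sigma = 0.05$, signal means
  $\mathcal N(0, 1)$. $\beta = 2$ (rather than 1) keeps both true log
  parameters away from zero, so relative-bias criteria are meaningful;
  $n^* = 8$ samples per trial is a plausible laboratory sampling budget.
* Parameter recovery: 200 replicates of $T = 100$ trials, residual variance
  fixed at truth, 90% intervals. Two multistarts per fit (the study
  posterior is unimodal; the default `multistart = 5` remains for unknown
  data).
* Grid-oracle check: $T = 40$, $\sigma^2 = 0.04$, prior SD 0.25 around
  $(\log 2, \log 0.02)$, a $201\times201$ grid spanning $\pm4$ prior SDs.
  The moderately informative prior is what makes a fixed grid meaningful:
  with SD-10 priors the grid spacing (0.4 on the log scale) would be far
  wider than the posterior itself and the "oracle" would resolve nothing.
* Model recovery: generating observer $\beta = 10$, $k = 0.0025$ versus a
  near-flat-prior candidate ($\beta$ frozen at 0.01), 100 datasets; Occam
  check against a redundant response-gain parameter, 50 datasets.
* Noise scaling: one noise-free realization of $T = 60$ trials re-inverted
  across $\sigma^2 \in [0.01, 1]$. Holding the realization fixed isolates
  the affine propagation of stated measurement imprecision; a realized
  noise draw would add $O(\sigma)$ jitter to the plug-in subject variance
  through the fitted mode.

These problem sizes keep the full acceptance run at roughly two minutes on
a single core while leaving Monte-Carlo error well inside every margin.

## Numerical choices

* **Optimizer.** Newton ascent with analytic derivatives when the model
  supplies them, otherwise central finite differences (relative step
  $10^{-5}$ for gradients; $\approx 10^{-4}$ for second differences, near
  the cancellation optimum $\varepsilon^{1/4}$). Non-concave regions use a
  modified-Newton step (absolute eigenvalues of the Hessian), and
  step-halving (up to 32) guarantees a monotone objective. Convergence:
  free-energy change below `tol` ($10^{-8}$) or gradient sup-norm below
  $10^{-6}$. All caps and tolerances are arguments.
* **Curvature.** Hessians are symmetrized before inversion; a jitter of
  $10^{-10}\,\mathrm{tr}/d$ is added (with a warning) when the condition
  number exceeds $10^{12}$. A non-negative terminal eigenvalue raises a
  degenerate-curvature error naming the eigenvalue.
* **Hyperparameters.** The residual variance, when estimated, alternates
  with the parameter fit: a one-dimensional maximization of the Laplace
  free energy over $\log\sigma^2$, bounded away from zero, with a warning
  when the optimum pins at a bound (e.g. identically zero residuals). The
  point estimate is excluded from the reported parameter covariance, noted
  in the output metadata.
* **Risk quadrature.** Gauss–Hermite, order 21 per dimension, doubled
  automatically when refinement moves the value by more than $10^{-8}$;
  state dimension capped at 4 (a documented limit — beyond that,
  closed-form risks should be supplied). Quadratic losses use exact moment
  formulas.
* **Ties and degenerate inputs.** Finite-action ties break to the lowest
  index and are flagged; integer actions use relax-then-compare-neighbours;
  a dataset with no informative responses returns the prior exactly; an
  under-determined fit under a near-improper prior is refused with advice
  to supply proper priors (the complete-class indeterminacy of inverse
  decision theory).
* **Multistart.** The first start is the prior mean; further starts jitter
  it by $\min(\text{prior SD}, 2)$ — raw draws from an SD-10 log-scale
  prior would start the optimizer at absurd parameter values
  ($\beta \sim e^{25}$) and help nobody.
* **Seeds.** A master seed spawns per-replicate seeds by fixed arithmetic
  (master + replicate index); artifacts are byte-identical across runs.

## Known limitations

* Hidden states are static within the perceptual model; trial-to-trial
  dynamics enter only through the belief recursion. Diffusing or
  controlled states (actions that change the world, Bellman-style
  planning) are out of scope.
* The experimenter-level posterior is itself a Laplace approximation; for
  strongly non-Gaussian posteriors (weak identification, small $T$) the
  dense-grid oracle in `toy_grid_posterior()` shows the size of the
  discrepancy, and its logic generalizes only to low-dimensional models.
* First-order belief reconstruction ignores curvature of the belief mode
  in the parameters; with very large parameter uncertainty the inflation
  is approximate (though still a lower bound on nothing — it remains
  nonnegative by construction).
* Hierarchical (group-level) priors across subjects and formal
  design-optimization loops are not provided.
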