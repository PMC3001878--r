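Package: ibdt
Title: Meta-Bayesian Inversion of Bayesian Observer Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Meta-Bayesian tools for fitting Bayesian observer models to
    trial-wise behaviour, i.e. for making statistical inferences about a
    subject's own perceptual inferences. A subject-level perceptual model is
    inverted online by variational Bayes under the Laplace approximation,
    yielding a Markovian trajectory of beliefs (posterior mode, covariance and
    perceptual free energy). Decisions follow Bayesian decision theory via
    posterior risk, optimal actions and softmax policies. An experimenter-level
    response model that embeds the observer is inverted, again by variational
    Laplace, to recover the subject's prior precision and loss-function
    parameters, compare competing observer models by their free energy, flag
    non-identifiable parameter pairs, and reconstruct the subject's belief with
    credible intervals inflated by experimental uncertainty. Includes a
    conjugate-Gaussian sampling-cost worked example that doubles as an exact
    oracle, a synthetic-observer simulator, parameter- and model-recovery
    studies, CSV/JSON input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
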