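# Simulator determinism, file round-trips and the command-line interface.

test_that("the simulator is deterministic and respects the noise-free limit", {
  cfg <- simulation_config(n_trials = 20, seed = 7)
  d1 <- simulate_observer(cfg)
  d2 <- simulate_observer(cfg)
  expect_identical(d1, d2)

  cfg0 <- simulation_config(observer = toy_observer_config(sigma2 = 0),
                            n_trials = 20, seed = 7)
  d0 <- simulate_observer(cfg0)
  obs <- cfg0$observer
  for (t in c(1, 10, 20)) {
    post <- toy_posterior(obs$beta, obs$prior_mean, d0$inputs[[t]])
    expect_equal(d0$responses[t, 1], post$mean)
    expect_equal(d0$responses[t, 2], toy_continuous_n(obs$beta, obs$k))
  }
})

test_that("the empirical residual variance matches the configured noise", {
  cfg <- simulation_config(observer = toy_observer_config(sigma2 = 0.25),
                           n_trials = 10000, seed = 123)
  dat <- simulate_observer(cfg)
  obs <- cfg$observer
  det <- t(vapply(dat$inputs, function(u) {
    c(toy_posterior(obs$beta, obs$prior_mean, u)$mean,
      toy_continuous_n(obs$beta, obs$k))
  }, numeric(2)))
  res <- dat$responses - det
  expect_lt(abs(mean(res^2) - 0.25) / 0.25, 0.05)
})

test_that("trial CSV files round-trip losslessly", {
  dat <- make_toy_data(n_trials = 15, seed = 3)
  dat$responses[4, 1] <- NA  # a missing response survives the round trip
  path <- file.path(tempdir(), "trials_rt.csv")
  write_trials(dat, path)
  back <- read_trials(path)
  expect_identical(back$inputs, dat$inputs)
  expect_identical(back$responses, dat$responses)
  expect_identical(back$labels, dat$labels)
  expect_equal(back$meta$true$beta, dat$meta$true$beta)

  # byte-identical artifacts under a fixed master seed
  p1 <- file.path(tempdir(), "det1.csv")
  p2 <- file.path(tempdir(), "det2.csv")
  write_trials(make_toy_data(n_trials = 8, seed = 99), p1)
  write_trials(make_toy_data(n_trials = 8, seed = 99), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed trial files raise parse errors naming the culprit", {
  path <- file.path(tempdir(), "bad.csv")
  writeLines("trial,input_1,response_1", path)
  expect_error(read_trials(path), class = "ibdt_parse_error")

  writeLines(c("trial,input_1,response_1", "0,1.5,oops"), path)
  expect_error(read_trials(path), "response_1", class = "ibdt_parse_error")

  writeLines(c("trial,response_1", "0,1.5"), path)
  expect_error(read_trials(path), class = "ibdt_parse_error")

  # unknown columns are tolerated, preserved and announced
  writeLines(c("trial,input_1,response_1,condition", "0,1.5,0.2,A"), path)
  expect_warning(dat <- read_trials(path), "condition")
  expect_identical(dat$meta$extra_columns$condition, "A")
})

test_that("posterior JSON serialization round-trips", {
  dat <- make_toy_data(n_trials = 20, seed = 6)
  post <- invert_observer(toy_perceptual_model(), toy_response_spec(sigma2 = 0.0025),
                          dat, toy_default_prior(), options = list(multistart = 1))
  path <- file.path(tempdir(), "post.json")
  posterior_to_json(post, path)
  back <- posterior_from_json(path)
  expect_equal(back$mode, post$mode, tolerance = 1e-14)
  expect_equal(back$covariance, unname(post$covariance), tolerance = 1e-14)
  expect_equal(back$free_energy, post$free_energy, tolerance = 1e-14)
  expect_identical(back$noise_variance, post$noise_variance)
})

test_that("data are most likely under their own generating parameters", {
  perc <- toy_perceptual_model()
  resp <- toy_response_spec(sigma2 = 0.0025)
  for (seed in 1:6) {
    dat <- make_toy_data(n_trials = 40, seed = seed)
    ll <- function(lb, lk) {
      Y <- resp$predict_all(exp(lb), exp(lk), dat)
      sum(dnorm(dat$responses, Y, sqrt(0.0025), log = TRUE))
    }
    true_ll <- ll(log(2), log(0.01))
    expect_gt(true_ll, ll(log(2) + 3, log(0.01)))
    expect_gt(true_ll, ll(log(2), log(0.01) - 3))
  }
})

test_that("the command line drives simulate, fit and compare end to end", {
  out <- file.path(tempdir(), "cli_out")
  cfgp <- system.file("extdata", "toy_config.json", package = "ibdt")
  expect_true(nzchar(cfgp))

  s <- cli_main(c("simulate", "--config", cfgp, "--seed", "42", "--out", out,
                  "--quiet"))
  expect_identical(s, 0L)
  expect_true(file.exists(file.path(out, "trials.csv")))
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$beta, 2)

  s <- cli_main(c("fit", "--config", cfgp, "--data",
                  file.path(out, "trials.csv"), "--seed", "1", "--out", out,
                  "--quiet"))
  expect_identical(s, 0L)
  got <- posterior_from_json(file.path(out, "posterior.json"))
  # the CLI fit reproduces a direct in-session inversion of the same data
  dat <- read_trials(file.path(out, "trials.csv"))
  ref <- invert_observer(toy_perceptual_model(), toy_response_spec(sigma2 = 0.0025),
                         dat, toy_default_prior(), options = list(seed = 1))
  expect_equal(got$mode, ref$mode, tolerance = 1e-6)

  s <- cli_main(c("compare", "--config", cfgp, "--data",
                  file.path(out, "trials.csv"), "--seed", "1", "--out", out,
                  "--quiet"))
  expect_identical(s, 0L)
  cmp <- jsonlite::read_json(file.path(out, "comparison.json"),
                             simplifyVector = TRUE)
  expect_length(cmp$free_energies, 2)
  expect_equal(sum(cmp$posterior_model_probabilities), 1, tolerance = 1e-9)

  # configuration errors exit with status 2, not an R error
  expect_identical(suppressMessages(cli_main(c("fit", "--config", cfgp))), 2L)
  expect_identical(suppressMessages(cli_main(c("unknown"))), 2L)
  expect_identical(suppressMessages(
    cli_main(c("simulate", "--config", "/nonexistent.json"))), 2L)
})
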