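test_that("both trajectory families pass through (t0, p0) with slope v0", {
  cases <- list(
    fixed_effects(74, 0.5, 0.05, 0.02, 7, 0.5, family = "logistic"),
    fixed_effects(70, 0.25, 0.12, 0.01, 5, 0.3, family = "logistic"),
    fixed_effects(65, 0.9, 0.01, 0.05, 10, 0.8, family = "logistic"),
    fixed_effects(74, 0.5, 0.05, 0.02, 7, 0.5, family = "linear"),
    fixed_effects(80, -1.2, 0.3, 0.1, 4, 0.2, family = "linear"))
  h <- 1e-2
  for (fx in cases) {
    expect_identical(curve_value(fx$t0, fx), fx$p0)
    deriv <- (curve_value(fx$t0 + h, fx) - curve_value(fx$t0 - h, fx)) /
      (2 * h)
    expect_lt(abs(deriv - fx$v0) / abs(fx$v0), 1e-6)
  }
})

test_that("logistic closed form matches independent evaluation and asymptotes", {
  fx <- fixed_effects(70, 0.5, 0.25, 0.02, 7, 0.5, family = "logistic")
  # p0 = 1/2 makes the steepness v0/(p0(1-p0)) = 1, so f(t0+1) = plogis(1)
  expect_equal(curve_value(71, fx), stats::plogis(1), tolerance = 1e-12)
  expect_equal(curve_value(71, fx), 0.731059, tolerance = 1e-6)
  expect_lt(curve_value(-1e6, fx), 1e-12)
  expect_gt(curve_value(1e6, fx), 1 - 1e-12)
})

test_that("individual prediction implements the affine time warp", {
  fx <- fixed_effects(74, 0.4, 0.06, 0.02, 7, 0.5, family = "logistic")
  # subjects cross the reference value at their own onset age
  expect_equal(individual_prediction(80, fx, tau = 80, xi = 0.7), fx$p0)
  # identity warp reproduces the population curve
  t <- seq(60, 90, by = 0.5)
  expect_equal(individual_prediction(t, fx, tau = fx$t0, xi = 0),
               curve_value(t, fx))
  # doubling the pace: value at tau + d equals population value at t0 + 2d
  for (d in c(-4, 1, 2.5)) {
    expect_equal(individual_prediction(77 + d, fx, tau = 77, xi = log(2)),
                 curve_value(fx$t0 + 2 * d, fx), tolerance = 1e-12)
  }
})

test_that("complete log-posterior matches Gaussian densities at the mode", {
  fx <- fixed_effects(74, 0.5, 0.05, 0.03, 7, 0.5, family = "logistic")
  ip <- individual_parameters(tau = fx$t0, xi = 0, subject_id = "A")
  obs <- data.frame(subject_id = "A", age_years = 76,
                    value = curve_value(76, fx))
  lp <- complete_log_posterior(obs, fx, ip)
  prior <- stats::dnorm(fx$t0, fx$t0, fx$sigma_tau, log = TRUE) +
    stats::dnorm(0, 0, fx$sigma_xi, log = TRUE)
  expect_equal(lp - prior, -0.5 * log(2 * pi * fx$sigma_eps^2),
               tolerance = 1e-12)
})

test_that("doubling sigma_tau at the tau prior mode shifts the posterior by -N log 2", {
  fx <- fixed_effects(74, 0.5, 0.05, 0.03, 7, 0.5, family = "logistic")
  n <- 7
  ids <- paste0("S", seq_len(n))
  ip <- individual_parameters(rep(fx$t0, n), stats::rnorm(n, 0, 0.2),
                              subject_id = ids)
  obs <- data.frame(subject_id = rep(ids, each = 3),
                    age_years = rep(c(70, 74, 78), n))
  obs$value <- stats::plogis(obs$age_years - 74)
  fx2 <- fx
  fx2$sigma_tau <- 2 * fx$sigma_tau
  expect_equal(complete_log_posterior(obs, fx2, ip) -
                 complete_log_posterior(obs, fx, ip),
               -n * log(2), tolerance = 1e-10)
})

test_that("the data term is invariant to t0 (identifiability by construction)", {
  set.seed(4)
  for (family in c("logistic", "linear")) {
    fx <- fixed_effects(74, 0.5, 0.05, 0.02, 7, 0.5, family = family)
    n <- 5
    ids <- paste0("S", seq_len(n))
    ip <- individual_parameters(stats::rnorm(n, 74, 7),
                                stats::rnorm(n, 0, 0.5), subject_id = ids)
    obs <- data.frame(subject_id = rep(ids, each = 4),
                      age_years = stats::runif(4 * n, 65, 85),
                      value = stats::runif(4 * n, 0.05, 0.95))
    data_term <- function(fx, ip) {
      k <- match(ids, ip$subject_id)
      complete_log_posterior(obs, fx, ip) -
        sum(stats::dnorm(ip$tau[k], fx$t0, fx$sigma_tau, log = TRUE)) -
        sum(stats::dnorm(ip$xi[k], 0, fx$sigma_xi, log = TRUE))
    }
    fx_shift <- fx
    fx_shift$t0 <- fx$t0 + 11.3
    expect_equal(data_term(fx_shift, ip), data_term(fx, ip),
                 tolerance = 1e-12)
  }
})

test_that("rescaling v0 against the log-pace leaves predictions unchanged", {
  t <- seq(60, 90, length.out = 41)
  for (family in c("logistic", "linear")) {
    fx <- fixed_effects(74, 0.35, 0.04, 0.02, 7, 0.5, family = family)
    for (c_scale in c(0.25, 2, 10)) {
      fx2 <- fx
      fx2$v0 <- c_scale * fx$v0
      expect_equal(
        individual_prediction(t, fx2, tau = 71, xi = 0.3 - log(c_scale)),
        individual_prediction(t, fx, tau = 71, xi = 0.3),
        tolerance = 1e-13)
    }
  }
})

test_that("trajectories are nondecreasing in time for positive v0", {
  t <- seq(0, 150, length.out = 301)
  for (family in c("logistic", "linear")) {
    fx <- fixed_effects(74, 0.5, 0.05, 0.02, 7, 0.5, family = family)
    expect_true(all(diff(curve_value(t, fx)) >= 0))
  }
})

test_that("invalid fixed effects are rejected", {
  expect_error(fixed_effects(74, 1.2, 0.05, 0.02, 7, 0.5,
                             family = "logistic"), "p0")
  expect_error(fixed_effects(74, 0.5, 0.05, 0.02, -7, 0.5), "positive")
  expect_error(fixed_effects(74, 0.5, 0.05, 0.02, 7, 0.5, family = "cubic"))
  # sigma_eps = 0 is allowed for noiseless generation but not for likelihoods
  fx0 <- fixed_effects(74, 0.5, 0.05, 0, 7, 0.5)
  ip <- individual_parameters(74, 0, subject_id = "A")
  obs <- data.frame(subject_id = "A", age_years = 74, value = 0.5)
  expect_error(complete_log_posterior(obs, fx0, ip), "sigma_eps")
})

test_that("fixed effects round-trip through JSON with family tag", {
  fx <- fixed_effects(74.25, 0.5, 0.0521, 0.02, 7.1, 0.48,
                      family = "logistic")
  path <- tempfile(fileext = ".json")
  write_fixed_effects(fx, path)
  expect_equal(read_fixed_effects(path), fx)
})
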