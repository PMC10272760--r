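straight_line_obs <- function(n_subj = 20, slope = 0.05, noise = 0,
                              seed = 1) {
  set.seed(seed)
  ages <- lapply(seq_len(n_subj), function(i) 74 + c(-4, -2, 0, 2, 4))
  data.frame(subject_id = rep(sprintf("s%02d", seq_len(n_subj)), each = 5),
             age_years = unlist(ages),
             value = 0.5 + slope * (unlist(ages) - 74) +
               stats::rnorm(5 * n_subj, 0, noise))
}

test_that("initialization recovers slope, centre and noise from the data", {
  obs <- straight_line_obs()
  init <- saem_initialize(obs)
  expect_equal(init$fx$v0, 0.05, tolerance = 1e-10)  # pooled OLS oracle
  expect_equal(init$fx$t0, 74)                       # symmetric ages
  expect_equal(init$fx$p0, 0.5)
  expect_true(all(init$ip$tau == init$fx$t0) && all(init$ip$xi == 0))
  flat <- straight_line_obs(slope = 0)
  expect_message(init2 <- saem_initialize(flat), "flooring")
  expect_equal(init2$fx$v0, 1e-4)
})

test_that("subjects with a single visit are refused by name", {
  obs <- rbind(straight_line_obs(n_subj = 3),
               data.frame(subject_id = "lonely", age_years = 70,
                          value = 0.4))
  expect_error(saem_initialize(obs), "lonely")
  fx <- fixed_effects(74, 0.5, 0.05, 0.02, 7, 0.5)
  expect_error(personalize(obs, fx), "lonely")
})

test_that("settings enforce the stochastic-approximation conditions", {
  expect_error(saem_settings(n_iterations = 100, n_burn_in = 100, seed = 1),
               "n_burn_in")
  expect_error(saem_settings(gamma = 0.4, seed = 1), "gamma")
  expect_error(saem_settings(), "seed")
})

test_that("personalization recovers noiseless individual parameters", {
  fx <- fixed_effects(74, 0.5, 0.05, 0.005, 7, 0.5)
  tau_true <- 76.5; xi_true <- 0.3
  ages <- seq(70, 84, length.out = 6)
  obs <- data.frame(subject_id = "x", age_years = ages,
                    value = individual_prediction(ages, fx, tau_true,
                                                  xi_true))
  ip <- personalize(obs, fx)
  expect_lt(abs(ip$tau - tau_true), 1e-3)
  expect_lt(abs(ip$xi - xi_true), 1e-3)
})

test_that("a subject on the population curve personalizes to the prior mode", {
  fx <- fixed_effects(74, 0.5, 0.05, 0.01, 7, 0.5)
  ages <- seq(68, 80, length.out = 5)
  obs <- data.frame(subject_id = "pop", age_years = ages,
                    value = curve_value(ages, fx))
  ip <- personalize(obs, fx)
  expect_lt(abs(ip$tau - fx$t0), 1e-3)
  expect_lt(abs(ip$xi), 1e-3)
})

test_that("identical subjects get identical personalized parameters", {
  fx <- fixed_effects(74, 0.5, 0.05, 0.02, 7, 0.5)
  ages <- c(70, 73, 76, 79)
  vals <- curve_value(ages + 1.7, fx)
  obs <- data.frame(subject_id = rep(c("a", "b"), each = 4),
                    age_years = rep(ages, 2), value = rep(vals, 2))
  ip <- personalize(obs, fx)
  expect_identical(ip$tau[1], ip$tau[2])
  expect_identical(ip$xi[1], ip$xi[2])
})

test_that("reconstruction residuals vanish on perfectly predicted points", {
  fx <- fixed_effects(74, 0.5, 0.05, 0.02, 7, 0.5)
  ip <- individual_parameters(75, 0.2, subject_id = "a")
  obs <- data.frame(subject_id = "a", age_years = c(72, 75, 78),
                    value = individual_prediction(c(72, 75, 78), fx, 75,
                                                  0.2))
  expect_equal(reconstruct(obs, fx, ip)$residual, rep(0, 3))
})

test_that("calibration is invariant to the order of input rows", {
  coh <- generate_cohort(cohort_config(n_subjects = 40, n_regions = 1,
                                       covariate_effects = NULL, seed = 6))
  obs <- region_observations(coh$visits, "region_1")
  st <- saem_settings(n_iterations = 300, n_burn_in = 150, seed = 2)
  a <- calibrate(obs, "logistic", st)
  set.seed(99)
  b <- calibrate(obs[sample.int(nrow(obs)), ], "logistic", st)
  expect_identical(a$fx, b$fx)
  expect_identical(a$ip, b$ip)
})

test_that("calibration on noiseless data reconstructs almost exactly", {
  rp <- list(fixed_effects(74, 0.5, 0.05, 0, 7, 0.5))
  coh <- generate_cohort(cohort_config(
    n_subjects = 100, n_regions = 1, region_params = rp,
    covariate_effects = NULL, scanner_offset = 0, duplicate_fraction = 0,
    visits_per_subject_min = 4, visits_per_subject_max = 6, seed = 5))
  obs <- region_observations(coh$visits, "region_1")
  fit <- calibrate(obs, "logistic", saem_settings(seed = 3))
  rec <- reconstruct(obs, fit$fx, personalize(obs, fit$fx))
  expect_lt(sqrt(mean(rec$residual^2)), 1e-2)
})

test_that("traces, diagnostics and the pace gauge behave at convergence", {
  fit <- recovery_fit()
  expect_equal(nrow(fit$traces), fit$settings$n_iterations)
  expect_true(all(is.finite(fit$diagnostics)))
  expect_true(all(fit$acceptance > 0.05 & fit$acceptance < 0.8))
  # zero-mean prior on xi fixes the pace gauge
  expect_lt(abs(mean(fit$ip$xi)), 0.15)
})

test_that("residual spread on the default cohort matches the generating noise", {
  rec <- reconstruct(recovery_obs(), recovery_fit()$fx, recovery_map())
  expect_lt(abs(stats::sd(rec$residual) / 0.02 - 1), 0.15)
})

test_that("doubling the iteration count leaves the fit within its own wander", {
  coh <- generate_cohort(cohort_config(n_subjects = 80, n_regions = 1,
                                       covariate_effects = NULL, seed = 17))
  obs <- region_observations(additive_bias_correction(coh$visits)$visits,
                             "region_1")
  a <- calibrate(obs, "logistic",
                 saem_settings(n_iterations = 1000, n_burn_in = 500,
                               seed = 4))
  b <- calibrate(obs, "logistic",
                 saem_settings(n_iterations = 2000, n_burn_in = 1000,
                               seed = 4))
  for (nm in c("t0", "sigma_tau", "sigma_eps")) {
    tol <- 5 * (a$diagnostics[[nm]] + b$diagnostics[[nm]]) +
      0.01 * abs(b$fx[[nm]])
    expect_lt(abs(a$fx[[nm]] - b$fx[[nm]]), tol)
  }
})

test_that("calibration artifacts serialize to JSON and CSV", {
  fit <- recovery_fit()
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_calibration(fit, jp, cp, region = "region_1")
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$fixed_effects$t0, fit$fx$t0)
  ip <- utils::read.csv(cp)
  expect_identical(names(ip), c("subject_id", "region", "tau", "xi",
                                "pace"))
  expect_equal(nrow(ip), 200)
})
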