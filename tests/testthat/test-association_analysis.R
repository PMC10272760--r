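fixture_covs <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%02d", seq_len(n)),
             sex_female = rep_len(c(0, 1), n),
             apoe4_count = rep_len(c(0, 1, 2), n),
             education_years = round(stats::rnorm(n, 15, 3), 1),
             stringsAsFactors = FALSE)
}

test_that("OLS coefficients match the normal-equations solution", {
  covs <- fixture_covs()
  set.seed(2)
  ip <- data.frame(subject_id = covs$subject_id, region = "r1",
                   tau = stats::rnorm(10, 74, 5),
                   xi = stats::rnorm(10, 0, 0.4))
  res <- ols_covariance(ip, covs)
  X <- cbind(1, covs$sex_female, covs$apoe4_count, covs$education_years)
  for (par in c("onset", "log_pace")) {
    y <- if (par == "onset") ip$tau else ip$xi
    beta <- solve(t(X) %*% X, t(X) %*% y)  # normal-equations oracle
    got <- res$beta[res$parameter == par]
    expect_equal(got, beta[2:4], tolerance = 1e-10)
    # t-based p from Student t with n - 4 df
    rss <- sum((y - X %*% beta)^2)
    se <- sqrt(diag(solve(t(X) %*% X)) * rss / (10 - 4))[2:4]
    p <- 2 * stats::pt(-abs(beta[2:4] / se), df = 10 - 4)
    expect_equal(res$p[res$parameter == par], p, tolerance = 1e-10)
  }
})

test_that("a constant response yields zero effects with a warning", {
  covs <- fixture_covs()
  ip <- data.frame(subject_id = covs$subject_id, region = "r1",
                   tau = 74, xi = stats::rnorm(10))
  expect_warning(res <- ols_covariance(ip, covs), "zero variance")
  on <- res[res$parameter == "onset", ]
  expect_true(all(on$beta == 0))
  expect_true(all(is.na(on$p)))
})

test_that("a constant covariate is flagged NA without poisoning the others", {
  covs <- fixture_covs()
  covs$sex_female <- 1
  set.seed(3)
  ip <- data.frame(subject_id = covs$subject_id, region = "r1",
                   tau = stats::rnorm(10, 74, 5), xi = stats::rnorm(10))
  w <- capture_warnings(res <- ols_covariance(ip, covs))
  expect_true(all(grepl("constant covariate", w)))  # once per parameter
  expect_true(all(is.na(res$beta[res$covariate == "female"])))
  expect_true(all(is.finite(res$beta[res$covariate == "education"])))
})

test_that("an injected female pace effect is reported as percent faster", {
  # generator convention: +23% pace for women; the truth table is the oracle
  coh <- generate_cohort(cohort_config(n_subjects = 500, n_regions = 1,
                                       seed = 9))
  ip <- truth_ip_table(coh$truth)
  res <- ols_covariance(ip, coh$covariates)
  pf <- res[res$parameter == "log_pace" & res$covariate == "female", ]
  expect_gt(pf$beta, 0)
  expect_gte(pf$percent_pace, 10)
  expect_lte(pf$percent_pace, 40)
  # exponentiating the log-pace coefficient IS the percent transform
  expect_equal(pf$percent_pace, (exp(pf$beta) - 1) * 100)
})

test_that("BH adjustment matches the worked step-up example", {
  p <- c(0.001, 0.01, 0.02, 0.5)
  expect_equal(fdr_adjust(p), c(0.004, 0.02, 4 * 0.02 / 3, 0.5),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are monotone in p and never below p", {
  set.seed(4)
  for (i in 1:25) {
    p <- stats::runif(sample(2:50, 1))
    q <- fdr_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("significance maps mask q > 0.05 and sign by risk direction", {
  assoc <- data.frame(
    region = c("r1", "r2", "r3", "r4"),
    parameter = c("log_pace", "onset", "log_pace", "onset"),
    covariate = "female",
    beta = c(0.4, -2, -0.4, 2), q = c(0.001, 0.01, 0.06, 0.04))
  m <- significance_map(assoc)
  expect_equal(nrow(m), 3)            # r3 masked
  expect_false("r3" %in% m$region)
  expect_equal(m$signed_neglog10_q[m$region == "r1"], 3)   # faster = risk
  expect_gt(m$signed_neglog10_q[m$region == "r2"], 0)      # earlier = risk
  expect_lt(m$signed_neglog10_q[m$region == "r4"], 0)      # later = protective
})

test_that("FDR families can be per-map or pooled per covariate", {
  set.seed(5)
  assoc <- expand.grid(region = paste0("r", 1:20),
                       parameter = c("onset", "log_pace"),
                       covariate = c("female", "apoe4_count", "education"),
                       stringsAsFactors = FALSE)
  assoc$beta <- stats::rnorm(nrow(assoc))
  assoc$p <- stats::runif(nrow(assoc))
  per <- fdr_adjust_table(assoc, "per-map")
  pooled <- fdr_adjust_table(assoc, "pooled")
  one <- per$parameter == "onset" & per$covariate == "female"
  expect_equal(per$q[one], bh_bruteforce(assoc$p[one]))
  onecov <- pooled$covariate == "female"
  expect_equal(pooled$q[onecov], bh_bruteforce(assoc$p[onecov]))
})

test_that("covariate correlations are near zero for the independent generator", {
  coh <- generate_cohort(cohort_config(n_subjects = 2000, n_regions = 1,
                                       seed = 13))
  cc <- covariate_correlations(coh$covariates)
  expect_true(all(cc$abs_r <= 0.1))
  # a duplicated covariate correlates perfectly
  covs <- fixture_covs(12)
  covs$education_years <- covs$apoe4_count
  cc2 <- covariate_correlations(covs)
  expect_equal(cc2$abs_r[cc2$pair == "apoe4_count/education"], 1)
})

test_that("an imposed covariate correlation is recovered", {
  set.seed(6)
  n <- 2000
  covs <- data.frame(subject_id = seq_len(n),
                     sex_female = stats::rbinom(n, 1, 0.5))
  # education anti-correlated with female sex by construction
  covs$education_years <- 16 - 2 * covs$sex_female + stats::rnorm(n, 0, 2)
  covs$apoe4_count <- sample(0:2, n, TRUE)
  # analytic |r|: |cov| = 2*var(b) = 0.5, sds 0.5 and sqrt(4*0.25 + 4)
  rho <- 0.5 / (0.5 * sqrt(4 * 0.25 + 4))
  cc <- covariate_correlations(covs)
  expect_lt(abs(cc$abs_r[cc$pair == "female/education"] - rho), 0.05)
})

test_that("false discoveries stay controlled with 20 non-null regions", {
  n_regions <- 100
  nonnull <- paste0("region_", 1:20)
  eff_on <- list(female = c(tau = 0, xi = 0),
                 apoe4_count = c(tau = -1.5, xi = 0),
                 education_years = c(tau = 0, xi = 0))
  eff_off <- list(female = c(tau = 0, xi = 0),
                  apoe4_count = c(tau = 0, xi = 0),
                  education_years = c(tau = 0, xi = 0))
  effects <- c(replicate(20, eff_on, simplify = FALSE),
               replicate(80, eff_off, simplify = FALSE))
  fd <- 0; disc <- 0
  for (s in 1:10) {
    coh <- generate_cohort(cohort_config(n_subjects = 500,
                                         n_regions = n_regions,
                                         covariate_effects = effects,
                                         seed = 100 + s))
    ip <- truth_ip_table(coh$truth)
    res <- fdr_adjust_table(ols_covariance(ip, coh$covariates))
    hits <- res[res$parameter == "onset" & res$covariate == "apoe4_count" &
                  !is.na(res$q) & res$q <= 0.05, ]
    disc <- disc + nrow(hits)
    fd <- fd + sum(!hits$region %in% nonnull)
  }
  expect_gt(disc, 0)
  expect_lte(fd / max(disc, 1), 0.12)
})
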