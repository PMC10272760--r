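# Shared fixtures, memoized so expensive calibrations run once per suite.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Recovery study: one region, 200 subjects, 5 visits each, generator defaults
# otherwise (scanner offset corrected downstream, duplicates kept), covariate
# effects switched off so the population parameters are the marginal truth.
recovery_cohort <- function() memo("recovery_cohort", function() {
  generate_cohort(cohort_config(
    n_subjects = 200, n_regions = 1, covariate_effects = NULL,
    visits_per_subject_min = 5, visits_per_subject_max = 5, seed = 42))
})

recovery_obs <- function() memo("recovery_obs", function() {
  coh <- recovery_cohort()
  region_observations(additive_bias_correction(coh$visits)$visits,
                      "region_1")
})

recovery_fit <- function() memo("recovery_fit", function() {
  calibrate(recovery_obs(), "logistic", saem_settings(seed = 7))
})

recovery_map <- function() memo("recovery_map", function() {
  personalize(recovery_obs(), recovery_fit()$fx)
})

# Effect-injection study: 500 subjects, default covariate effects (onset 1.5 y
# earlier per APOE-e4 allele, pace 23% faster for women).
effect_cohort <- function() memo("effect_cohort", function() {
  generate_cohort(cohort_config(n_subjects = 500, n_regions = 1, seed = 42))
})

effect_ip <- function() memo("effect_ip", function() {
  coh <- effect_cohort()
  obs <- region_observations(additive_bias_correction(coh$visits)$visits,
                             "region_1")
  fit <- calibrate(obs, "logistic", saem_settings(seed = 7))
  ip <- personalize(obs, fit$fx)
  ip$region <- "region_1"
  ip
})

# Truth-table individual parameters stacked long, for association tests that
# exercise the statistical machinery on the generator's ground truth.
truth_ip_table <- function(truth) {
  do.call(rbind, lapply(seq_along(truth$region_names), function(r)
    data.frame(subject_id = rownames(truth$tau),
               region = truth$region_names[r],
               tau = truth$tau[, r], xi = truth$xi[, r],
               stringsAsFactors = FALSE)))
}

# Small two-region pipeline study reused by the end-to-end checks.
small_cohort <- function() memo("pipeline_cohort", function()
  generate_cohort(cohort_config(n_subjects = 60, n_regions = 2, seed = 9)))

small_run <- function(dir, seed = 123) {
  coh <- small_cohort()
  run_pipeline(pipeline_config(
    coh$visits, coh$covariates, dir,
    saem = saem_settings(n_iterations = 800, n_burn_in = 400, seed = 1),
    seed = seed))
}

# Brute-force Benjamini-Hochberg step-up, kept independent of the package.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- qs
  out
}
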