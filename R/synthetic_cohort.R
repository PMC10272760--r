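# Synthetic longitudinal cohort generator. Emulates the statistical structure
# the downstream analysis assumes: region-wise logistic (or linear) decline
# with per-subject onset age and log-pace, covariate-driven shifts of the
# random effects, Gaussian measurement noise, an additive 3T-1.5T scanner
# offset, and same-day duplicate acquisitions. Ground truth is retained so
# parameter recovery is testable.

#' Configuration of a synthetic longitudinal cohort
#'
#' Defaults emulate an amnestic-dementia observational cohort: ~74 y baseline
#' age, 44% female, APOE-e4 allele counts distributed 0/1/2 at roughly
#' 31/50/19%, 15.5 +- 2.8 years of education, two scanner field strengths in
#' near-equal proportion with an additive 3T offset, and roughly one visit
#' per year with between 2 and 7 visits per subject. Trajectory defaults
#' (t0 = 74 y, p0 = 0.5, v0 = 0.05/y, sigma_tau = 7 y, sigma_xi = 0.5,
#' sigma_eps = 0.02 in normalized units) make trajectories traverse a visible
#' fraction of [0, 1] over follow-up. Default covariate effects shift onset
#' 1.5 years earlier per APOE-e4 allele and make the pace 23% faster for
#' women; pass `covariate_effects = NULL` effects of zero for a null cohort.
#'
#' @param n_subjects,n_regions cohort size and number of regional features.
#' @param region_params list of per-region [fixed_effects()] generating
#'   values; recycled from the defaults when `NULL`.
#' @param covariate_effects per-region list; each element is a list mapping
#'   covariate name (`female`, `apoe4_count`, `education_years`) to
#'   `c(tau = <shift on onset, years>, xi = <shift on log-pace>)`. A single
#'   unnamed list is recycled across regions. `NULL` means all zero.
#' @param baseline_age_mean,baseline_age_sd baseline age distribution, years.
#' @param visits_per_subject_min,visits_per_subject_max visit count bounds
#'   (uniform draw); the minimum must be at least 2.
#' @param visit_interval_mean,visit_interval_sd inter-visit interval, years
#'   (truncated below at 0.1).
#' @param prop_female,prop_apoe4_1,prop_apoe4_2,prop_3T probabilities.
#' @param education_mean,education_sd education, years.
#' @param scanner_offset additive shift applied to 3T acquisitions
#'   (feature units).
#' @param duplicate_fraction probability that a visit is acquired twice the
#'   same day (fresh measurement noise, same age and scanner).
#' @param group_label diagnosis-group label stamped on every visit.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   tables.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 300, n_regions = 10,
                          region_params = NULL,
                          covariate_effects = list(
                            female = c(tau = 0, xi = log(1.23)),
                            apoe4_count = c(tau = -1.5, xi = 0),
                            education_years = c(tau = 0, xi = 0)),
                          baseline_age_mean = 74.3, baseline_age_sd = 7.4,
                          visits_per_subject_min = 2,
                          visits_per_subject_max = 7,
                          visit_interval_mean = 1.0, visit_interval_sd = 0.35,
                          prop_female = 0.44, prop_apoe4_1 = 0.50,
                          prop_apoe4_2 = 0.19,
                          education_mean = 15.5, education_sd = 2.8,
                          scanner_offset = 0.05, prop_3T = 0.49,
                          duplicate_fraction = 0.2,
                          group_label = "AD", seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  if (n_subjects < 1 || n_regions < 1)
    stop("n_subjects and n_regions must be positive", call. = FALSE)
  probs <- c(prop_female = prop_female, prop_apoe4_1 = prop_apoe4_1,
             prop_apoe4_2 = prop_apoe4_2, prop_3T = prop_3T,
             duplicate_fraction = duplicate_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  if (prop_apoe4_1 + prop_apoe4_2 > 1)
    stop("prop_apoe4_1 + prop_apoe4_2 must not exceed 1", call. = FALSE)
  if (visits_per_subject_min < 2)
    stop("visits_per_subject_min must be at least 2 (subjects need repeated ",
         "measurements)", call. = FALSE)
  if (visits_per_subject_max < visits_per_subject_min)
    stop("visits_per_subject_max < visits_per_subject_min", call. = FALSE)
  if (is.null(region_params)) {
    region_params <- replicate(n_regions, fixed_effects(
      t0 = 74, p0 = 0.5, v0 = 0.05, sigma_eps = 0.02, sigma_tau = 7,
      sigma_xi = 0.5, family = "logistic"), simplify = FALSE)
  }
  if (length(region_params) != n_regions)
    stop("region_params must have one entry per region", call. = FALSE)
  for (rp in region_params) {
    if (rp$sigma_tau <= 0 || rp$sigma_xi <= 0 || rp$sigma_eps < 0)
      stop("non-positive generating variances are rejected", call. = FALSE)
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- list(female = c(tau = 0, xi = 0),
                              apoe4_count = c(tau = 0, xi = 0),
                              education_years = c(tau = 0, xi = 0))
  }
  # a single map is recycled across regions
  if (!is.null(names(covariate_effects)))
    covariate_effects <- replicate(n_regions, covariate_effects,
                                   simplify = FALSE)
  if (length(covariate_effects) != n_regions)
    stop("covariate_effects must be one map or one per region", call. = FALSE)
  if (n_subjects < 4)
    warning("fewer than 4 subjects: downstream OLS on three covariates ",
            "will be rank-deficient")
  structure(list(
    n_subjects = n_subjects, n_regions = n_regions,
    region_params = region_params, covariate_effects = covariate_effects,
    baseline_age_mean = baseline_age_mean, baseline_age_sd = baseline_age_sd,
    visits_per_subject_min = as.integer(visits_per_subject_min),
    visits_per_subject_max = as.integer(visits_per_subject_max),
    visit_interval_mean = visit_interval_mean,
    visit_interval_sd = visit_interval_sd,
    prop_female = prop_female, prop_apoe4_1 = prop_apoe4_1,
    prop_apoe4_2 = prop_apoe4_2,
    education_mean = education_mean, education_sd = education_sd,
    scanner_offset = scanner_offset, prop_3T = prop_3T,
    duplicate_fraction = duplicate_fraction, group_label = group_label,
    seed = as.integer(seed)), class = "cohort_config")
}

# Run expr under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

covariate_shift <- function(effects, covs, which = c("tau", "xi")) {
  which <- match.arg(which)
  s <- numeric(nrow(covs))
  for (nm in names(effects)) {
    col <- switch(nm, female = "sex_female", apoe4_count = "apoe4_count",
                  education_years = "education_years", nm)
    if (!col %in% names(covs))
      stop("unknown covariate in effects map: ", nm, call. = FALSE)
    s <- s + effects[[nm]][[which]] * covs[[col]]
  }
  s
}

#' Generate a synthetic longitudinal cohort with retained ground truth
#'
#' Samples covariates, subject-level random effects (onset age `tau_i`
#' shifted by the covariate effects around the region's `t0`, log-pace `xi_i`
#' around the covariate shift), an irregular visit schedule, and noisy
#' observations on each region's trajectory. 3T acquisitions receive the
#' additive scanner offset; a fraction of visits is duplicated the same day
#' with fresh measurement noise.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `visits` (long visit table: `subject_id`,
#'   `age_years`, `group`, `field_strength`, `is_duplicate`, one column per
#'   region), `covariates` (`subject_id`, `sex_female`, `apoe4_count`,
#'   `education_years`) and `truth` (generating fixed effects, per-subject
#'   true `tau`/`xi` matrices, covariates and applied scanner offset).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    K <- config$n_regions
    region_names <- names(config$region_params)
    if (is.null(region_names)) region_names <- paste0("region_", seq_len(K))

    covs <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      sex_female = stats::rbinom(n, 1, config$prop_female),
      apoe4_count = sample(0:2, n, replace = TRUE,
                           prob = c(1 - config$prop_apoe4_1 -
                                      config$prop_apoe4_2,
                                    config$prop_apoe4_1,
                                    config$prop_apoe4_2)),
      education_years = pmax(0, stats::rnorm(n, config$education_mean,
                                             config$education_sd)),
      stringsAsFactors = FALSE)

    # visit schedule: baseline age + cumulative truncated-Gaussian intervals
    nv_range <- seq(config$visits_per_subject_min,
                    config$visits_per_subject_max)
    n_visits <- nv_range[sample.int(length(nv_range), n, replace = TRUE)]
    baseline <- stats::rnorm(n, config$baseline_age_mean,
                             config$baseline_age_sd)
    subj_idx <- rep(seq_len(n), n_visits)
    intervals <- pmax(0.1, stats::rnorm(sum(n_visits),
                                        config$visit_interval_mean,
                                        config$visit_interval_sd))
    intervals[!duplicated(subj_idx)] <- 0
    ages <- baseline[subj_idx] +
      unlist(lapply(split(intervals, subj_idx), cumsum), use.names = FALSE)

    field <- ifelse(stats::runif(length(ages)) < config$prop_3T, 3.0, 1.5)

    # duplicate flagged copies share age and scanner, get fresh noise below
    dup <- stats::runif(length(ages)) < config$duplicate_fraction
    row_src <- c(seq_along(ages), which(dup))
    is_dup <- c(rep(0L, length(ages)), rep(1L, sum(dup)))
    ord <- order(subj_idx[row_src], ages[row_src], is_dup)
    row_src <- row_src[ord]
    is_dup <- is_dup[ord]

    visits <- data.frame(
      subject_id = covs$subject_id[subj_idx[row_src]],
      age_years = ages[row_src],
      group = config$group_label,
      field_strength = field[row_src],
      is_duplicate = is_dup,
      stringsAsFactors = FALSE)

    tau_true <- matrix(NA_real_, n, K, dimnames = list(covs$subject_id,
                                                       region_names))
    xi_true <- tau_true
    for (r in seq_len(K)) {
      rp <- config$region_params[[r]]
      eff <- config$covariate_effects[[r]]
      tau_true[, r] <- stats::rnorm(n, rp$t0 + covariate_shift(eff, covs,
                                                               "tau"),
                                    rp$sigma_tau)
      xi_true[, r] <- stats::rnorm(n, covariate_shift(eff, covs, "xi"),
                                   rp$sigma_xi)
      i <- subj_idx[row_src]
      y <- individual_prediction(visits$age_years, rp, tau_true[i, r],
                                 xi_true[i, r])
      if (rp$sigma_eps > 0)
        y <- y + stats::rnorm(length(y), 0, rp$sigma_eps)
      y <- y + ifelse(visits$field_strength == 3.0, config$scanner_offset, 0)
      visits[[region_names[r]]] <- y
    }

    truth <- list(region_params = config$region_params,
                  region_names = region_names,
                  tau = tau_true, xi = xi_true, covariates = covs,
                  scanner_offset = config$scanner_offset,
                  group_label = config$group_label, seed = config$seed)
    list(visits = visits, covariates = covs, truth = truth)
  })
}

#' Demographic summary of a cohort, split by sex
#'
#' Mirrors the usual cohort-description table of observational imaging
#' studies: patient and scan counts, total follow-up, baseline age,
#' education, and APOE-e4 allele-count breakdown, one column per sex.
#' Duplicate same-day acquisitions count as scans.
#'
#' @param visits long visit table (one row per scan).
#' @param covariates per-subject covariate table.
#' @return A data.frame with one row per statistic and columns `male`,
#'   `female`.
#' @export
summarize_demographics <- function(visits, covariates) {
  orphans <- setdiff(unique(visits$subject_id), covariates$subject_id)
  if (length(orphans))
    stop("visit subjects missing from the covariate table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  one_sex <- function(ids) {
    v <- visits[visits$subject_id %in% ids, , drop = FALSE]
    cv <- covariates[covariates$subject_id %in% ids, , drop = FALSE]
    fu <- tapply(v$age_years, v$subject_id, function(a) max(a) - min(a))
    bl <- tapply(v$age_years, v$subject_id, min)
    c(n_patients = length(ids), n_scans = nrow(v),
      followup_mean = mean(fu), followup_sd = stats::sd(fu),
      baseline_age_mean = mean(bl), baseline_age_sd = stats::sd(bl),
      education_mean = mean(cv$education_years),
      education_sd = stats::sd(cv$education_years),
      apoe4_2 = sum(cv$apoe4_count == 2), apoe4_1 = sum(cv$apoe4_count == 1),
      apoe4_0 = sum(cv$apoe4_count == 0))
  }
  m <- one_sex(covariates$subject_id[covariates$sex_female == 0])
  f <- one_sex(covariates$subject_id[covariates$sex_female == 1])
  data.frame(statistic = names(m), male = unname(m), female = unname(f),
             stringsAsFactors = FALSE)
}

#' Write cohort tables and ground truth to an output directory
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written (`visits.csv`, `covariates.csv`,
#'   `truth.json`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- file.path(dir, "visits.csv")
  pc <- file.path(dir, "covariates.csv")
  pt <- file.path(dir, "truth.json")
  utils::write.csv(cohort$visits, pv, row.names = FALSE)
  utils::write.csv(cohort$covariates, pc, row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(list(
    region_params = lapply(tr$region_params, unclass),
    region_names = tr$region_names,
    tau = as.data.frame(tr$tau), xi = as.data.frame(tr$xi),
    covariates = tr$covariates, scanner_offset = tr$scanner_offset,
    group_label = tr$group_label, seed = tr$seed), pt,
    auto_unbox = TRUE, digits = NA)
  invisible(c(visits = pv, covariates = pc, truth = pt))
}
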