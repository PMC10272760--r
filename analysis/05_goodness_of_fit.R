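#!/usr/bin/env Rscript
# Stage 5: goodness of fit and model checking.
#
# Reconstruction errors of the calibrated models are compared to the
# measurement noise estimated from same-day duplicate scans; residuals are
# audited for bias against the covariates and the share of 3T acquisitions;
# the linear and logistic trajectory families are compared on the first
# region; and the recovery of the generating truth is summarized.

library(onsetpace)

seed <- 20260920
visits <- utils::read.csv("results/preprocessed/visits.csv",
                          stringsAsFactors = FALSE)
raw_visits <- read_visits("results/cohort/visits.csv")
covs <- read_covariates("results/cohort/covariates.csv")
ip <- utils::read.csv("results/calibration/individual_parameters.csv",
                      stringsAsFactors = FALSE)
regions <- unique(ip$region)
dir.create("results/gof", showWarnings = FALSE, recursive = TRUE)

# fixed effects live inside the calibration JSONs
read_fx <- function(r) {
  j <- jsonlite::read_json(file.path(
    "results/calibration", paste0("calibration_", r, ".json")),
    simplifyVector = TRUE)$fixed_effects
  fixed_effects(j$t0, j$p0, j$v0, j$sigma_eps, j$sigma_tau, j$sigma_xi,
                family = j$family)
}
resid_all <- do.call(rbind, lapply(regions, function(r) {
  ipr <- ip[ip$region == r, ]
  reconstruct(region_observations(visits, r),
              read_fx(r),
              individual_parameters(ipr$tau, ipr$xi, ipr$subject_id),
              region = r)
}))

retest <- test_retest_errors(visits, regions)
gof <- gof_compare(resid_all, retest)
utils::write.csv(as.data.frame(gof), "results/gof/gof_report.csv",
                 row.names = FALSE)
cat("Reconstruction error vs test-retest noise (per region):\n")
print(as.data.frame(gof)[, c("region", "resid_sd", "noise_sd",
                             "iqr_overlap")])

share3T <- tapply(raw_visits$field_strength == 3.0, raw_visits$subject_id,
                  mean)
factors <- merge(covs, data.frame(subject_id = names(share3T),
                                  share_3T = as.numeric(share3T)),
                 by = "subject_id")
audit <- residual_bias_audit(resid_all, factors)
utils::write.csv(audit, "results/gof/residual_bias_audit.csv",
                 row.names = FALSE)
cat("Residual-bias audit (p-values per factor):\n")
print(audit)

cmp <- compare_families(region_observations(visits, regions[1]),
                        saem_settings(n_iterations = 600, n_burn_in = 300,
                                      seed = seed %% 1000003))
cat(sprintf(
  "Family comparison on %s: %s selected (sigma_eps logistic %.4f vs linear %.4f%s)\n",
  regions[1], cmp$selected, cmp$sigma_eps[["logistic"]],
  cmp$sigma_eps[["linear"]], if (cmp$tie) ", tie" else ""))
jsonlite::write_json(list(selected = cmp$selected, tie = cmp$tie,
                          sigma_eps = as.list(cmp$sigma_eps)),
                     "results/gof/family_comparison.json",
                     auto_unbox = TRUE, digits = NA)

truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)
r1 <- regions[1]
ipr <- ip[ip$region == r1, ]
k <- match(ipr$subject_id, truth$covariates$subject_id)
cat(sprintf("Recovery on %s: cor(onset) = %.3f, cor(log-pace) = %.3f\n",
            r1, stats::cor(ipr$tau, truth$tau[[r1]][k]),
            stats::cor(ipr$xi, truth$xi[[r1]][k])))
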