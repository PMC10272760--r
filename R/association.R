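# Covariance analysis of the individual parameters: per region and per
# parameter (onset age tau, log-pace xi), OLS on [1, female, APOE-e4 allele
# count, education years], per-coefficient t-tests, Benjamini-Hochberg FDR
# across regions, and signed -log10 significance maps.

assoc_covariates <- c("female", "apoe4_count", "education")
assoc_cov_cols <- c(female = "sex_female", apoe4_count = "apoe4_count",
                    education = "education_years")

#' OLS covariance analysis of individual parameters
#'
#' For every region and each individual parameter (onset age and log-pace),
#' fits `parameter ~ female + apoe4_count + education_years` by ordinary
#' least squares and reports, per covariate, the coefficient, its standard
#' error, `t = beta/se` and the two-sided p-value from the Student t
#' distribution with `n - 4` degrees of freedom — so each covariate's effect
#' is evaluated after correcting for the other ones. For the log-pace
#' parameter the multiplicative effect `percent_pace = (exp(beta) - 1)*100`
#' is reported alongside.
#'
#' @param ip_table data.frame with columns `subject_id`, `region`, `tau`,
#'   `xi` (stacked over regions, as written by [write_calibration()] or
#'   built from [personalize()]).
#' @param covariates covariate table (`subject_id`, `sex_female`,
#'   `apoe4_count`, `education_years`). Subjects with missing covariates are
#'   dropped and counted.
#' @return data.frame with one row per region x parameter x covariate:
#'   `region`, `parameter` (`onset`/`log_pace`), `covariate`, `beta`, `se`,
#'   `t`, `p`, `percent_pace`, `n`. `q` is added by [fdr_adjust_table()].
#' @export
ols_covariance <- function(ip_table, covariates) {
  need <- c("subject_id", "region", "tau", "xi")
  miss <- setdiff(need, names(ip_table))
  if (length(miss))
    stop("individual-parameter table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  covariates <- covariates[, c("subject_id", unname(assoc_cov_cols))]
  dropped <- sum(!stats::complete.cases(covariates))
  if (dropped > 0) {
    message(dropped, " subject(s) dropped for missing covariates")
    covariates <- covariates[stats::complete.cases(covariates), ]
  }
  d <- merge(ip_table, covariates, by = "subject_id")
  out <- list()
  for (r in unique(d$region)) {
    dr <- d[d$region == r, ]
    n <- nrow(dr)
    if (n < 10)
      stop("region '", r, "': need at least 10 subjects, got ", n,
           call. = FALSE)
    for (par in c("onset", "log_pace")) {
      yv <- if (par == "onset") dr$tau else dr$xi
      rows <- data.frame(region = r, parameter = par,
                         covariate = assoc_covariates,
                         beta = NA_real_, se = NA_real_, t = NA_real_,
                         p = NA_real_, percent_pace = NA_real_, n = n,
                         stringsAsFactors = FALSE)
      degenerate <- vapply(assoc_cov_cols,
                           function(cl) stats::var(dr[[cl]]) == 0,
                           logical(1))
      if (stats::var(yv) == 0) {
        rows$beta <- 0; rows$t <- 0; rows$p <- NA_real_
        warning("region '", r, "', parameter '", par,
                "': response has zero variance")
        out[[length(out) + 1L]] <- rows
        next
      }
      if (any(degenerate))
        warning("region '", r, "': constant covariate(s) ",
                paste(assoc_covariates[degenerate], collapse = ", "),
                "; their coefficients are NA")
      keep <- assoc_cov_cols[!degenerate]
      fml <- stats::reformulate(unname(keep), response = "y")
      fit <- stats::lm(fml, data = cbind(dr, y = yv))
      sm <- summary(fit)$coefficients
      for (i in which(!degenerate)) {
        cl <- assoc_cov_cols[[i]]
        if (!cl %in% rownames(sm)) next
        rows$beta[i] <- sm[cl, "Estimate"]
        rows$se[i] <- sm[cl, "Std. Error"]
        rows$t[i] <- sm[cl, "t value"]
        rows$p[i] <- sm[cl, "Pr(>|t|)"]
      }
      if (par == "log_pace")
        rows$percent_pace <- (exp(rows$beta) - 1) * 100
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_{j >= i} m p_(j) / j`, clipped to
#' 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in [0, 1] forming one test family
#'   (NAs are passed through).
#' @return Vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Add FDR-adjusted q-values to an association table
#'
#' The default family is all regions for a fixed (parameter, covariate)
#' pair, matching a per-map presentation of region-wise results; `pooled`
#' treats all regions and both parameters of one covariate as a single
#' family.
#'
#' @param assoc output of [ols_covariance()].
#' @param family_mode `"per-map"` (default) or `"pooled"`.
#' @return `assoc` with a `q` column.
#' @export
fdr_adjust_table <- function(assoc, family_mode = c("per-map", "pooled")) {
  family_mode <- match.arg(family_mode)
  key <- if (family_mode == "per-map")
    interaction(assoc$parameter, assoc$covariate, drop = TRUE)
  else factor(assoc$covariate)
  assoc$q <- NA_real_
  for (lv in levels(key)) {
    idx <- which(key == lv)
    assoc$q[idx] <- fdr_adjust(assoc$p[idx])
  }
  assoc
}

#' Signed -log10 significance map
#'
#' Regions whose q-value exceeds the significance level are masked (absent
#' from the map). The remaining regions get `-log10(q)` signed by risk
#' direction: positive (risk) when the covariate brings onset earlier
#' (`beta_tau < 0`) or makes the pace faster (`beta_xi > 0`), negative
#' (protective) otherwise.
#'
#' @param assoc association table with `q` (see [fdr_adjust_table()]).
#' @param alpha significance level on q (default 0.05).
#' @return data.frame `region`, `parameter`, `covariate`,
#'   `signed_neglog10_q` containing only unmasked regions.
#' @export
significance_map <- function(assoc, alpha = 0.05) {
  if (!"q" %in% names(assoc))
    stop("run fdr_adjust_table() first: no 'q' column", call. = FALSE)
  keep <- !is.na(assoc$q) & assoc$q <= alpha
  a <- assoc[keep, , drop = FALSE]
  risk <- ifelse(a$parameter == "onset", a$beta < 0, a$beta > 0)
  data.frame(region = a$region, parameter = a$parameter,
             covariate = a$covariate,
             signed_neglog10_q = -log10(a$q) * ifelse(risk, 1, -1),
             stringsAsFactors = FALSE)
}

#' Pairwise absolute correlations between the covariates
#'
#' Reported alongside association results as a collinearity check: strongly
#' correlated covariates would make the "after correcting for the other
#' ones" interpretation fragile.
#'
#' @param covariates covariate table with at least 3 subjects.
#' @return data.frame `pair`, `abs_r`.
#' @export
covariate_correlations <- function(covariates) {
  if (nrow(covariates) < 3)
    stop("need at least 3 subjects", call. = FALSE)
  cols <- assoc_cov_cols
  pairs <- utils::combn(names(cols), 2, simplify = FALSE)
  res <- lapply(pairs, function(pp) {
    x <- covariates[[cols[[pp[1]]]]]; y <- covariates[[cols[[pp[2]]]]]
    r <- if (stats::var(x) == 0 || stats::var(y) == 0) {
      warning("zero-variance covariate in pair ", paste(pp, collapse = "/"))
      NA_real_
    } else abs(stats::cor(x, y))
    data.frame(pair = paste(pp, collapse = "/"), abs_r = r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
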