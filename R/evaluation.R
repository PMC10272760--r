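# Goodness of fit: reconstruction errors are compared to the measurement
# noise estimated from same-day duplicate acquisitions; residuals are
# audited for bias against covariates and acquisition factors; and the
# linear and logistic trajectory families are compared on fitted noise and
# convergence stability.

#' Measurement-noise sample from same-day duplicate scans
#'
#' For every set of duplicate acquisitions (same subject, same age, at least
#' one row flagged `is_duplicate`), forms all pairwise differences scaled by
#' `1/sqrt(2)`: if the two measurements share a mean and carry independent
#' noise of sd sigma, the proxy `(y1 - y2)/sqrt(2)` has sd sigma, so the sd
#' of the sample estimates the single-measurement noise.
#'
#' @param visits visit table with duplicates flagged.
#' @param regions region columns to use.
#' @return data.frame `region`, `subject_id`, `age_years`, `error`; empty
#'   (with a warning) when there are no duplicates.
#' @export
test_retest_errors <- function(visits, regions = region_columns(visits)) {
  key <- paste(visits$subject_id, format(visits$age_years, digits = 12))
  grp <- split(seq_len(nrow(visits)), key)
  grp <- grp[vapply(grp, length, 1L) >= 2]
  if (length(grp) == 0) {
    warning("no duplicate acquisitions found; empty noise sample")
    return(data.frame(region = character(0), subject_id = character(0),
                      age_years = numeric(0), error = numeric(0)))
  }
  out <- vector("list", length(grp) * length(regions))
  k <- 0L
  for (idx in grp) {
    prs <- utils::combn(idx, 2)
    for (r in regions) {
      k <- k + 1L
      e <- (visits[[r]][prs[1, ]] - visits[[r]][prs[2, ]]) / sqrt(2)
      out[[k]] <- data.frame(region = r,
                             subject_id = visits$subject_id[prs[1, ]],
                             age_years = visits$age_years[prs[1, ]],
                             error = e, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res[stats::complete.cases(res), ]
}

gof_quantiles <- c(0.05, 0.25, 0.50, 0.75, 0.95)

#' Compare reconstruction errors with test-retest measurement noise
#'
#' Summarizes both distributions per region by their 5/25/50/75/95%
#' quantiles and reports an interquartile-range overlap indicator — the
#' machine-checkable counterpart of "the error distributions largely
#' overlap": the length of the intersection of the two IQRs must reach half
#' the length of the wider one, so a noise IQR merely nested inside a much
#' wider residual IQR does not count as overlap. A model whose
#' reconstruction errors fall close to the measurement uncertainty cannot be
#' improved without overfitting.
#'
#' @param residuals residual table from [reconstruct()] (column `residual`,
#'   `region`).
#' @param retest test-retest error sample from [test_retest_errors()]; may
#'   be empty.
#' @return An object of class `gof_report`: data.frame with per-region
#'   residual and noise quantiles, the two sds, and `iqr_overlap`.
#' @export
gof_compare <- function(residuals, retest) {
  if (nrow(residuals) == 0) stop("empty residual table", call. = FALSE)
  rows <- lapply(unique(residuals$region), function(r) {
    x <- residuals$residual[residuals$region == r]
    qx <- stats::quantile(x, gof_quantiles, names = FALSE)
    nx <- retest$error[retest$region == r]
    if (length(nx) == 0) {
      qn <- rep(NA_real_, length(gof_quantiles))
      ov <- NA
    } else {
      qn <- stats::quantile(nx, gof_quantiles, names = FALSE)
      inter <- min(qx[4], qn[4]) - max(qx[2], qn[2])
      ov <- inter >= 0.5 * max(qx[4] - qx[2], qn[4] - qn[2])
    }
    data.frame(region = r,
               resid_q05 = qx[1], resid_q25 = qx[2], resid_q50 = qx[3],
               resid_q75 = qx[4], resid_q95 = qx[5],
               noise_q05 = qn[1], noise_q25 = qn[2], noise_q50 = qn[3],
               noise_q75 = qn[4], noise_q95 = qn[5],
               resid_sd = stats::sd(x),
               noise_sd = if (length(nx) >= 2) stats::sd(nx) else NA_real_,
               iqr_overlap = ov, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("gof_report", "data.frame"))
}

#' Audit reconstruction residuals for bias
#'
#' Regresses each subject's mean absolute residual on each covariate or
#' acquisition factor separately (OLS) and reports the two-sided p-value of
#' the factor's slope. Large systematic p-values would indicate the model
#' absorbs some factors better than others; an unbiased fit gives roughly
#' uniform p-values. The signed per-subject mean residual is available as an
#' alternative summary.
#'
#' @param residuals residual table from [reconstruct()].
#' @param factors data.frame with `subject_id` and one column per factor to
#'   audit (covariates, per-subject acquisition summaries such as the share
#'   of 3T scans).
#' @param summary_fun `"abs"` (default: mean |residual| per subject) or
#'   `"signed"` (mean residual).
#' @return data.frame `factor`, `beta`, `p`, `n`.
#' @export
residual_bias_audit <- function(residuals, factors,
                                summary_fun = c("abs", "signed")) {
  summary_fun <- match.arg(summary_fun)
  f <- if (summary_fun == "abs") function(x) mean(abs(x)) else mean
  per_subj <- tapply(residuals$residual, residuals$subject_id, f)
  d <- data.frame(subject_id = names(per_subj), mresid = as.numeric(per_subj),
                  stringsAsFactors = FALSE)
  d <- merge(d, factors, by = "subject_id")
  cols <- setdiff(names(factors), "subject_id")
  rows <- lapply(cols, function(cl) {
    x <- d[[cl]]
    if (stats::var(x, na.rm = TRUE) == 0)
      return(data.frame(factor = cl, beta = NA_real_, p = NA_real_,
                        n = nrow(d), stringsAsFactors = FALSE))
    sm <- summary(stats::lm(d$mresid ~ x))$coefficients
    data.frame(factor = cl, beta = sm["x", "Estimate"],
               p = sm["x", "Pr(>|t|)"], n = nrow(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare the linear and logistic trajectory families
#'
#' Calibrates both families on the same observations and compares the
#' fitted observation noise `sigma_eps` (lower is better) and convergence
#' stability (final-window trace sds). When the fitted noises agree within
#' a relative tie margin the comparison is reported as a tie and the
#' logistic family is favored (bounded trajectories with realistic
#' asymptotes). If one family diverges the other is selected and flagged.
#'
#' @param obs observation table.
#' @param settings a [saem_settings()].
#' @param tie_margin relative `sigma_eps` margin treated as a tie.
#' @return A list with `selected` family, `tie`, per-family `sigma_eps`,
#'   stability (`sigma_eps` final-window sd), `diverged` flags, and both
#'   `calibration_result`s (NULL on divergence).
#' @export
compare_families <- function(obs, settings, tie_margin = 0.02) {
  fit <- lapply(c(logistic = "logistic", linear = "linear"), function(fam)
    tryCatch(calibrate(obs, family = fam, settings = settings),
             error = function(e) e))
  diverged <- vapply(fit, inherits, logical(1), what = "error")
  if (all(diverged))
    stop("both families failed to calibrate", call. = FALSE)
  sig <- vapply(names(fit), function(f)
    if (diverged[[f]]) NA_real_ else fit[[f]]$fx$sigma_eps, numeric(1))
  stab <- vapply(names(fit), function(f)
    if (diverged[[f]]) NA_real_ else fit[[f]]$diagnostics[["sigma_eps"]],
    numeric(1))
  rule <- select_family_rule(sig, diverged, tie_margin)
  list(selected = rule$selected, tie = rule$tie, sigma_eps = sig,
       stability = stab, diverged = diverged,
       fits = lapply(fit, function(f) if (inherits(f, "error")) NULL else f))
}

# Selection rule: lower fitted noise wins; relative agreement within
# tie_margin is a tie, resolved in favor of the logistic family.
select_family_rule <- function(sigma_eps, diverged = c(logistic = FALSE,
                                                       linear = FALSE),
                               tie_margin = 0.02) {
  if (any(diverged))
    return(list(selected = names(diverged)[!diverged], tie = FALSE))
  rel <- abs(sigma_eps[["logistic"]] - sigma_eps[["linear"]]) /
    min(sigma_eps)
  tie <- rel <= tie_margin
  list(selected = if (tie) "logistic" else
    names(sigma_eps)[which.min(sigma_eps)], tie = tie)
}
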