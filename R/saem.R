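# MAP estimation of the trajectory model by MCMC-SAEM: the E-step
# expectation is replaced by a Metropolis-within-Gibbs sweep over the
# subject-level random effects (tau_i, xi_i), sufficient statistics are
# updated by stochastic approximation with a Robbins-Monro step, and the
# M-step updates the fixed effects (closed forms for t0 and the variances,
# one damped Newton step on (p0, v0)).

#' Settings of the MCMC-SAEM sampler
#'
#' @param n_iterations total iterations.
#' @param n_burn_in iterations with step size 1 (full stochastic
#'   approximation memory starts afterwards); must be < `n_iterations`.
#' @param gamma Robbins-Monro step exponent, in (0.5, 1]: after burn-in the
#'   step at iteration k is `(k - n_burn_in)^(-gamma)`.
#' @param prop_sd_tau,prop_sd_xi initial random-walk proposal sds for the
#'   onset age (years) and log-pace.
#' @param target_acceptance proposal sds are adapted toward this acceptance
#'   rate during burn-in.
#' @param adaptation_interval iterations between proposal-sd adaptations.
#' @param convergence_window trailing iterations over which fixed-effect
#'   trace sds are reported as convergence diagnostics.
#' @param seed integer seed (mandatory).
#' @return An object of class `saem_settings`.
#' @export
saem_settings <- function(n_iterations = 2000, n_burn_in = 1000,
                          gamma = 0.65, prop_sd_tau = 2, prop_sd_xi = 0.3,
                          target_acceptance = 0.3, adaptation_interval = 25,
                          convergence_window = 200, seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  if (n_burn_in >= n_iterations)
    stop("n_burn_in must be smaller than n_iterations", call. = FALSE)
  if (gamma <= 0.5 || gamma > 1)
    stop("gamma must lie in (0.5, 1] for stochastic-approximation ",
         "convergence", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burn_in = as.integer(n_burn_in), gamma = gamma,
                 prop_sd_tau = prop_sd_tau, prop_sd_xi = prop_sd_xi,
                 target_acceptance = target_acceptance,
                 adaptation_interval = as.integer(adaptation_interval),
                 convergence_window = as.integer(convergence_window),
                 seed = as.integer(seed)), class = "saem_settings")
}

#' Data-driven initialization of the fixed effects
#'
#' `t0` starts at the mean visit age, `p0` at 0.5 (features are min-max
#' normalized), `v0` at the pooled within-subject OLS slope (floored at
#' 1e-4/y), `sigma_eps` at the pooled within-subject residual sd,
#' `sigma_tau` at the sd of visit ages and `sigma_xi` at 0.5. All subjects
#' start at the prior modes `tau_i = t0`, `xi_i = 0`.
#'
#' @param obs observation table (`subject_id`, `age_years`, `value`).
#' @param family trajectory family.
#' @return A list with `fx` ([fixed_effects()]) and `ip`
#'   ([individual_parameters()]).
#' @export
saem_initialize <- function(obs, family = c("logistic", "linear")) {
  family <- match.arg(family)
  obs <- as_observations(obs)
  nv <- table(obs$subject_id)
  if (any(nv < 2))
    stop("subjects with fewer than 2 visits: ",
         paste(names(nv)[nv < 2], collapse = ", "), call. = FALSE)
  t0 <- mean(obs$age_years)
  slope <- pooled_slope(obs$value, obs$age_years, obs$subject_id)
  if (abs(slope) < 1e-4) {
    message("pooled slope below 1e-4/y; flooring v0")
    slope <- 1e-4
  }
  # pooled residual sd around per-subject lines (2 df per subject)
  ca <- obs$age_years - stats::ave(obs$age_years, obs$subject_id)
  cv <- obs$value - stats::ave(obs$value, obs$subject_id)
  b <- stats::ave(ca * cv, obs$subject_id, FUN = sum) /
    pmax(stats::ave(ca^2, obs$subject_id, FUN = sum), 1e-12)
  res <- cv - b * ca
  df <- max(1, nrow(obs) - 2 * length(nv))
  s_eps <- sqrt(sum(res^2) / df)
  if (!is.finite(s_eps) || s_eps < 1e-4) s_eps <- 1e-4
  fx <- fixed_effects(t0 = t0, p0 = 0.5, v0 = abs(slope), sigma_eps = s_eps,
                      sigma_tau = max(stats::sd(obs$age_years), 0.5),
                      sigma_xi = 0.5, family = family)
  ids <- unique(obs$subject_id)
  list(fx = fx, ip = individual_parameters(rep(t0, length(ids)),
                                           rep(0, length(ids)),
                                           subject_id = ids))
}

# Per-subject residual sum of squares for given random effects; the work
# horse of the sampler, vectorized over all observations.
rss_by_subject <- function(t, y, si, n_subj, fx, tau, xi) {
  pred <- curve_value(exp(xi[si]) * (t - tau[si]) + fx$t0, fx)
  as.numeric(rowsum((y - pred)^2, si, reorder = TRUE))
}

#' Calibrate the trajectory model with MCMC-SAEM
#'
#' Alternates, at each iteration: (S) one Metropolis-within-Gibbs sweep that
#' updates every subject's `tau_i` then `xi_i` with Gaussian random-walk
#' proposals scored against the complete log-posterior; (SA) a stochastic
#' approximation update of the sufficient statistics with step 1 during
#' burn-in and `(k - n_burn_in)^(-gamma)` after; (M) closed-form updates of
#' `t0` and the three variances from the smoothed statistics (each blended
#' with its hyperprior) and one damped Newton step on `(p0, v0)` applied to
#' the penalized data attachment. Proposal sds are adapted toward the target
#' acceptance rate during burn-in and frozen afterwards.
#'
#' @param obs observation table (`subject_id`, `age_years`, `value`);
#'   values should be preprocessed to [0, 1] for the logistic family.
#' @param family trajectory family.
#' @param settings a [saem_settings()].
#' @return An object of class `calibration_result`: fitted [fixed_effects()]
#'   (`fx`), stochastic-approximation posterior-mean individual parameters
#'   (`ip`), iteration traces of the fixed effects (`traces`), acceptance
#'   rates, final-window trace sds (`diagnostics`), and the settings used.
#' @export
calibrate <- function(obs, family = c("logistic", "linear"), settings) {
  family <- match.arg(family)
  stopifnot(inherits(settings, "saem_settings"))
  init <- saem_initialize(obs, family)
  obs <- as_observations(obs)
  t <- obs$age_years; y <- obs$value; si <- obs$.subj
  ids <- unique(obs$subject_id)
  N <- length(ids)
  n_obs <- length(y)
  fx <- init$fx
  hp <- hyperpriors(fx)
  tau <- rep(fx$t0, N); xi <- rep(0, N)
  tau_bar <- tau; xi_bar <- xi

  # smoothed sufficient statistics: E[tau], E[tau^2], E[xi^2], E[resid^2]
  rss <- rss_by_subject(t, y, si, N, fx, tau, xi)
  S <- c(m_tau = mean(tau), m_tau2 = mean(tau^2), m_xi2 = mean(xi^2),
         msr = sum(rss) / n_obs)

  ns <- settings$n_iterations
  traces <- matrix(NA_real_, ns, 6,
                   dimnames = list(NULL, c("t0", "p0", "v0", "sigma_eps",
                                           "sigma_tau", "sigma_xi")))
  sd_tau <- settings$prop_sd_tau; sd_xi <- settings$prop_sd_xi
  acc <- c(tau = 0, xi = 0); acc_win <- c(tau = 0, xi = 0); win_n <- 0L

  theta_of <- function(fx) c(if (family == "logistic") stats::qlogis(fx$p0)
                             else fx$p0, log(fx$v0))
  fx_of <- function(theta, fx) {
    fx$p0 <- if (family == "logistic") stats::plogis(theta[1]) else theta[1]
    fx$v0 <- exp(theta[2])
    fx
  }
  pen_obj <- function(theta, fx, tau, xi) {
    f2 <- fx_of(theta, fx)
    pred <- curve_value(exp(xi[si]) * (t - tau[si]) + f2$t0, f2)
    sum((y - pred)^2) / (2 * fx$sigma_eps^2) +
      (theta[1] - hp$m_lp0)^2 / (2 * hp$sd_p0^2) +
      (theta[2] - hp$m_lv0)^2 / (2 * hp$sd_v0^2)
  }

  with_seed(settings$seed, {
    for (k in seq_len(ns)) {
      eps_k <- if (k <= settings$n_burn_in) 1 else
        (k - settings$n_burn_in)^(-settings$gamma)
      inv2s2 <- 1 / (2 * fx$sigma_eps^2)

      # --- (S) Metropolis-within-Gibbs sweep (blocked across subjects) ---
      tau_p <- tau + stats::rnorm(N, 0, sd_tau)
      rss_p <- rss_by_subject(t, y, si, N, fx, tau_p, xi)
      ldiff <- (rss - rss_p) * inv2s2 +
        ((tau - fx$t0)^2 - (tau_p - fx$t0)^2) / (2 * fx$sigma_tau^2)
      ok <- log(stats::runif(N)) < ldiff
      tau[ok] <- tau_p[ok]; rss[ok] <- rss_p[ok]
      acc["tau"] <- acc["tau"] + mean(ok); acc_win["tau"] <- acc_win["tau"] + mean(ok)

      xi_p <- xi + stats::rnorm(N, 0, sd_xi)
      rss_p <- rss_by_subject(t, y, si, N, fx, tau, xi_p)
      ldiff <- (rss - rss_p) * inv2s2 +
        (xi^2 - xi_p^2) / (2 * fx$sigma_xi^2)
      ok <- log(stats::runif(N)) < ldiff
      xi[ok] <- xi_p[ok]; rss[ok] <- rss_p[ok]
      acc["xi"] <- acc["xi"] + mean(ok); acc_win["xi"] <- acc_win["xi"] + mean(ok)
      win_n <- win_n + 1L

      # proposal adaptation during burn-in only
      if (k <= settings$n_burn_in && win_n >= settings$adaptation_interval) {
        rate <- acc_win / win_n
        sd_tau <- sd_tau * exp(rate[["tau"]] - settings$target_acceptance)
        sd_xi <- sd_xi * exp(rate[["xi"]] - settings$target_acceptance)
        acc_win[] <- 0; win_n <- 0L
      }

      # --- (SA) sufficient-statistic update ---
      stat <- c(m_tau = mean(tau), m_tau2 = mean(tau^2), m_xi2 = mean(xi^2),
                msr = sum(rss) / n_obs)
      S <- S + eps_k * (stat - S)
      tau_bar <- tau_bar + eps_k * (tau - tau_bar)
      xi_bar <- xi_bar + eps_k * (xi - xi_bar)

      # --- (M) fixed-effect updates ---
      # t0: Gaussian posterior mode given the smoothed tau statistics
      prec <- N / fx$sigma_tau^2 + 1 / hp$sd_t0^2
      fx$t0 <- (N * S[["m_tau"]] / fx$sigma_tau^2 + hp$m_t0 / hp$sd_t0^2) /
        prec
      v_tau <- max(S[["m_tau2"]] - 2 * fx$t0 * S[["m_tau"]] + fx$t0^2, 1e-8)
      # one-observation-weight log-space blend with the hyperprior mode
      fx$sigma_tau <- exp((N * 0.5 * log(v_tau) + hp$m_ltau) / (N + 1))
      fx$sigma_xi <- exp((N * 0.5 * log(max(S[["m_xi2"]], 1e-8)) + hp$m_lxi) /
                           (N + 1))
      fx$sigma_eps <- exp((n_obs * 0.5 * log(max(S[["msr"]], 1e-12)) +
                             hp$m_leps) / (n_obs + 1))

      # (p0, v0): one damped Newton step on the penalized data attachment
      th <- theta_of(fx)
      h <- 1e-4
      f0 <- pen_obj(th, fx, tau, xi)
      fpp <- pen_obj(th + c(h, 0), fx, tau, xi)
      fpm <- pen_obj(th - c(h, 0), fx, tau, xi)
      fqp <- pen_obj(th + c(0, h), fx, tau, xi)
      fqm <- pen_obj(th - c(0, h), fx, tau, xi)
      fab <- pen_obj(th + c(h, h), fx, tau, xi)
      fmm <- pen_obj(th - c(h, h), fx, tau, xi)
      g <- c((fpp - fpm) / (2 * h), (fqp - fqm) / (2 * h))
      H <- matrix(0, 2, 2)
      H[1, 1] <- (fpp - 2 * f0 + fpm) / h^2
      H[2, 2] <- (fqp - 2 * f0 + fqm) / h^2
      H[1, 2] <- H[2, 1] <-
        (fab - fpp - fqp + 2 * f0 - fpm - fqm + fmm) / (2 * h^2)
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      ridge <- max(0, 1e-6 - min(ev))
      step <- tryCatch(-solve(H + diag(ridge + 1e-8, 2), g),
                       error = function(e) -0.01 * g)
      step <- step * 0.5 * eps_k
      nrm <- sqrt(sum(step^2))
      if (nrm > 0.2) step <- step * 0.2 / nrm
      fx <- fx_of(th + step, fx)

      if (!all(is.finite(c(fx$t0, fx$p0, fx$v0, fx$sigma_eps, fx$sigma_tau,
                           fx$sigma_xi, tau, xi))))
        stop("MCMC-SAEM diverged at iteration ", k,
             " (non-finite state); last fixed effects: ",
             paste(sprintf("%s=%.4g", colnames(traces),
                           traces[max(1, k - 1), ]), collapse = ", "),
             call. = FALSE)
      rss <- rss_by_subject(t, y, si, N, fx, tau, xi)
      traces[k, ] <- c(fx$t0, fx$p0, fx$v0, fx$sigma_eps, fx$sigma_tau,
                       fx$sigma_xi)
    }
  })

  acc <- acc / ns
  if (any(acc < 0.01))
    warning("acceptance rate below 1% for ",
            paste(names(acc)[acc < 0.01], collapse = ", "),
            "; proposals may be poorly scaled")
  w <- min(settings$convergence_window, ns)
  diag_sd <- apply(traces[(ns - w + 1):ns, , drop = FALSE], 2, stats::sd)
  structure(list(
    fx = fx,
    ip = individual_parameters(tau_bar, xi_bar, subject_id = ids),
    ip_last = individual_parameters(tau, xi, subject_id = ids),
    traces = traces, acceptance = acc, diagnostics = diag_sd,
    proposal_sds = c(tau = sd_tau, xi = sd_xi),
    settings = settings, family = family), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("MCMC-SAEM calibration (", x$family, " family, ",
      x$settings$n_iterations, " iterations)\n", sep = "")
  print(x$fx)
  cat(sprintf("  acceptance: tau %.2f, xi %.2f\n", x$acceptance[["tau"]],
              x$acceptance[["xi"]]))
  cat("  final-window trace sds:\n")
  print(signif(x$diagnostics, 3))
  invisible(x)
}

#' Personalize frozen population parameters to subjects
#'
#' With the fixed effects frozen, estimates each subject's `(tau, xi)` as
#' the posterior mode of that subject's terms of the complete log-posterior,
#' by multi-start quasi-Newton optimization (starts at
#' `tau in {t0 - sigma_tau, t0, t0 + sigma_tau}` crossed with
#' `xi in {-sigma_xi, 0, sigma_xi}`). Ties are resolved by highest posterior
#' then smallest `|xi|`, which makes the output deterministic.
#'
#' @param obs observation table of the subjects to personalize (each needs
#'   at least 2 visits).
#' @param fx frozen [fixed_effects()].
#' @param family trajectory family.
#' @return An [individual_parameters()] data.frame; subjects on which every
#'   optimizer start failed are dropped with a warning.
#' @export
personalize <- function(obs, fx, family = fx$family) {
  obs <- as_observations(obs)
  nv <- table(obs$subject_id)
  if (any(nv < 2))
    stop("subjects with fewer than 2 visits: ",
         paste(names(nv)[nv < 2], collapse = ", "), call. = FALSE)
  ids <- unique(obs$subject_id)
  starts <- expand.grid(tau = fx$t0 + c(-fx$sigma_tau, 0, fx$sigma_tau),
                        xi = c(0, -fx$sigma_xi, fx$sigma_xi))
  out_tau <- numeric(0); out_xi <- numeric(0); out_id <- character(0)
  failed <- character(0)
  for (id in ids) {
    rows <- obs$subject_id == id
    ti <- obs$age_years[rows]; yi <- obs$value[rows]
    nll <- function(par) {
      p <- individual_prediction(ti, fx, par[1], par[2], family = family)
      -(sum(stats::dnorm(yi, p, fx$sigma_eps, log = TRUE)) +
          stats::dnorm(par[1], fx$t0, fx$sigma_tau, log = TRUE) +
          stats::dnorm(par[2], 0, fx$sigma_xi, log = TRUE))
    }
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(c(starts$tau[s], starts$xi[s]), nll,
                                 method = "BFGS",
                                 control = list(maxit = 200)),
                    error = function(e) NULL)
      if (is.null(o) || !is.finite(o$value)) next
      if (is.null(best) || o$value < best$value - 1e-9 ||
          (abs(o$value - best$value) <= 1e-9 &&
           abs(o$par[2]) < abs(best$par[2])))
        best <- o
    }
    if (is.null(best)) { failed <- c(failed, id); next }
    out_id <- c(out_id, id)
    out_tau <- c(out_tau, best$par[1]); out_xi <- c(out_xi, best$par[2])
  }
  if (length(failed))
    warning("personalization failed for subjects: ",
            paste(failed, collapse = ", "), "; they are excluded")
  individual_parameters(out_tau, out_xi, subject_id = out_id)
}

#' Reconstruction residuals of a calibrated model
#'
#' Differences between the model prediction at each visit age and the actual
#' measurement, for every observation.
#'
#' @param obs observation table.
#' @param fx fitted [fixed_effects()].
#' @param ip [individual_parameters()] covering the observed subjects.
#' @param region optional region label stamped on the output.
#' @return data.frame `subject_id`, `age_years`, `region`, `observed`,
#'   `predicted`, `residual`.
#' @export
reconstruct <- function(obs, fx, ip, region = "feature") {
  obs <- as_observations(obs)
  k <- match(obs$subject_id, ip$subject_id)
  if (anyNA(k))
    stop("missing individual parameters for subjects: ",
         paste(unique(obs$subject_id[is.na(k)]), collapse = ", "),
         call. = FALSE)
  pred <- individual_prediction(obs$age_years, fx, ip$tau[k], ip$xi[k])
  data.frame(subject_id = obs$subject_id, age_years = obs$age_years,
             region = region, observed = obs$value, predicted = pred,
             residual = obs$value - pred, stringsAsFactors = FALSE)
}

#' Extract one region's observations from a visit table
#'
#' Convenience accessor producing the long observation format the model
#' functions consume. Duplicate same-day scans are kept (they are real
#' observations); rows with `NA` for the region (e.g. removed outliers) are
#' dropped, and subjects left with fewer than 2 visits — the study's
#' selection criterion — are excluded with a message.
#'
#' @param visits visit table.
#' @param region region column name.
#' @return data.frame `subject_id`, `age_years`, `value`.
#' @export
region_observations <- function(visits, region) {
  if (!region %in% names(visits))
    stop("no column '", region, "' in the visit table", call. = FALSE)
  ok <- !is.na(visits[[region]])
  d <- data.frame(subject_id = visits$subject_id[ok],
                  age_years = visits$age_years[ok],
                  value = visits[[region]][ok], stringsAsFactors = FALSE)
  nv <- table(d$subject_id)
  few <- names(nv)[nv < 2]
  if (length(few)) {
    message("region '", region, "': excluding ", length(few),
            " subject(s) with fewer than 2 retained visits")
    d <- d[!d$subject_id %in% few, , drop = FALSE]
  }
  d
}

#' Serialize a calibration result
#'
#' Fixed effects and diagnostics go to JSON; individual parameters to CSV.
#'
#' @param result a `calibration_result`.
#' @param json_path,csv_path output paths.
#' @param region region label for the CSV.
#' @export
write_calibration <- function(result, json_path, csv_path,
                              region = "feature") {
  jsonlite::write_json(list(
    fixed_effects = unclass(result$fx),
    acceptance = as.list(result$acceptance),
    final_window_sd = as.list(result$diagnostics),
    settings = unclass(result$settings), format_version = 1L),
    json_path, auto_unbox = TRUE, digits = NA)
  ip <- result$ip
  ip$region <- region
  utils::write.csv(ip[, c("subject_id", "region", "tau", "xi", "pace")],
                   csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
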