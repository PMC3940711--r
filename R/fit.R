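#' Remove extreme latencies
#'
#' Single-pass outlier rule: values more than `n_sd` standard deviations
#' from the mean (mean and SD computed once, from the full input) are
#' dropped; the remainder is returned in its original order. With a
#' constant input the SD is zero and nothing is removed.
#'
#' @param latencies numeric vector of latencies (seconds).
#' @param n_sd cutoff in standard deviations (default 5).
#' @return The filtered vector.
#' @export
filter_outliers <- function(latencies, n_sd = 5) {
  x <- latencies[!is.na(latencies)]
  if (length(x) < 2L) return(x)
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x)
  x[abs(x - m) <= n_sd * s]
}

# One subject's labelled target-present trials with the 5-SD outlier rule
# applied to all latencies jointly (per subject, not per condition).
.prepare_fit_data <- function(records) {
  need <- c("condition", "target_present", "latency", "correct")
  if (!all(need %in% names(records)))
    stop("missing columns: ", paste(setdiff(need, names(records)), collapse = ", "),
         call. = FALSE)
  if ("subject" %in% names(records) && length(unique(records$subject)) > 1L)
    stop("fitting operates on one subject at a time; split the table by subject",
         call. = FALSE)
  d <- records[records$target_present & records$condition %in% conditions() &
                 !is.na(records$latency), , drop = FALSE]
  if (!nrow(d)) stop("no labelled target-present trials to fit", call. = FALSE)
  m <- mean(d$latency); s <- stats::sd(d$latency)
  if (is.finite(s) && s > 0)
    d <- d[abs(d$latency - m) <= 5 * s, , drop = FALSE]
  d
}

#' Per-condition data summary for the quantile fit
#'
#' Counts correct and error trials and computes the 10/30/50/70/90%
#' latency quantiles of correct trials (linear interpolation between order
#' statistics), after per-subject outlier filtering.
#'
#' @param records one subject's trial data frame (see [generate_study()]
#'   for the columns).
#' @param condition one of the four condition labels.
#' @return An object of class `condition_summary` with fields `condition`,
#'   `n_trials`, `n_correct`, `n_error`, `quantiles`, and the auxiliary
#'   `min_latency` / `mean_latency` used by the fit initialiser.
#' @export
summarize_condition <- function(records, condition) {
  condition <- match.arg(condition, conditions())
  d <- .prepare_fit_data(records)
  .summarize_prepared(d, condition)
}

.summarize_prepared <- function(d, condition) {
  d <- d[d$condition == condition, , drop = FALSE]
  lat_c <- d$latency[d$correct]
  if (length(lat_c) < 6L)
    stop(sprintf("condition %s has only %d correct trials; at least 6 are needed",
                 condition, length(lat_c)), call. = FALSE)
  q <- stats::quantile(lat_c, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                       type = 7, names = FALSE)
  structure(list(condition = condition,
                 n_trials = nrow(d),
                 n_correct = length(lat_c),
                 n_error = nrow(d) - length(lat_c),
                 quantiles = q,
                 min_latency = min(d$latency),
                 mean_latency = mean(d$latency)),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("%s: %d trials (%d correct, %d error); quantiles (ms): %s\n",
              x$condition, x$n_trials, x$n_correct, x$n_error,
              paste(round(x$quantiles * 1000, 1), collapse = " ")))
  invisible(x)
}

#' @rdname summarize_condition
#' @export
condition_summaries <- function(records) {
  d <- .prepare_fit_data(records)
  lapply(stats::setNames(conditions(), conditions()),
         function(cc) .summarize_prepared(d, cc))
}

#' Chi-square components for one condition
#'
#' The modified quantile chi-square cells: observed correct-latency mass is
#' split `(.1, .2, .2, .2, .2, .1) * accuracy` across the six quantile
#' bins, errors form a single seventh cell, and each cell contributes
#' `N * (p_obs - p_exp)^2 / p_exp` with the model mass from
#' [bin_probabilities()]. The error cell is omitted when the condition has
#' no errors. Expected masses are floored at `p_floor` so no cell divides
#' by zero.
#'
#' @param summary a `condition_summary`.
#' @param p the condition's [rdm_params()].
#' @param p_floor lower bound applied to expected masses.
#' @inheritParams response_prob
#' @return Numeric vector of 7 (or 6, when `n_error = 0`) components.
#' @export
chisq_components <- function(summary, p, p_floor = 1e-5,
                             n_gh = 24L, n_gl = 12L) {
  if (!inherits(summary, "condition_summary"))
    stop("expected a 'condition_summary' object", call. = FALSE)
  p_exp <- pmax(bin_probabilities(p, summary$quantiles, n_gh, n_gl), p_floor)
  acc <- summary$n_correct / summary$n_trials
  p_obs <- c(c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1) * acc,
             summary$n_error / summary$n_trials)
  comp <- summary$n_trials * (p_obs - p_exp)^2 / p_exp
  if (summary$n_error == 0L) comp <- comp[1:6]
  comp
}

#' Total chi-square objective for a sub-model
#'
#' Sums the chi-square components of all four conditions at the
#' per-condition expansion of the free parameter vector `theta` (on the
#' optimiser's unconstrained scale). Parameter vectors that violate the
#' model invariants receive a large finite penalty so derivative-free
#' search stays in-domain.
#'
#' @param summaries list of four `condition_summary` objects (from
#'   [condition_summaries()]).
#' @param spec a `submodel_spec` or its name.
#' @param theta free parameter vector of length
#'   [free_parameter_count()]`(spec)`, unconstrained scale.
#' @param s diffusion scaling constant used for the fit.
#' @inheritParams chisq_components
#' @return Total chi-square (scalar).
#' @export
rdm_objective <- function(summaries, spec, theta, s = 1,
                          n_gh = 20L, n_gl = 10L, p_floor = 1e-5) {
  if (is.character(spec)) spec <- submodel(spec)
  full <- tryCatch(.theta_to_full(theta, spec, s), error = function(e) NULL)
  if (is.null(full)) return(1e8 + sum(theta^2))
  total <- 0
  for (cond in conditions()) {
    p <- tryCatch(expand_condition(full, cond), error = function(e) NULL)
    if (is.null(p)) return(1e8 + sum(theta^2))
    total <- total + sum(chisq_components(summaries[[cond]], p,
                                          p_floor = p_floor,
                                          n_gh = n_gh, n_gl = n_gl))
  }
  if (!is.finite(total)) total <- 1e8
  total
}

# Method-of-moments style starting values: non-decision time from the
# fastest latency, normalised drift from overall accuracy via the logistic
# form of the absorption probability, boundary from the mean decision time.
.init_full <- function(summaries, s) {
  n_tot <- sum(vapply(summaries, `[[`, 0, "n_trials"))
  acc <- sum(vapply(summaries, `[[`, 0, "n_correct")) / n_tot
  acc <- min(max(acc, 0.55), 0.995)
  min_lat <- min(vapply(summaries, `[[`, 0, "min_latency"))
  ter0 <- 0.9 * min_lat
  md <- max(mean(vapply(summaries, `[[`, 0, "mean_latency")) - ter0, 0.005)
  vt <- stats::qlogis(acc)
  a0 <- sqrt(2 * vt * s^2 * md / tanh(vt / 2))
  v0 <- vt * s^2 / a0
  st0 <- min(0.04, ter0)
  full_model_params(dB_dpe = 0, dB_pop = 0, v0 = v0, dv_dpe = 0, dv_pop = 0,
                    a_dpe = a0, a_pop = a0, Ter_dpe = ter0, Ter_pop = ter0,
                    Sz = 0.1 * a0, St = st0, eta = 0.25 * v0, s = s)
}

#' Fit the diffusion model by quantile chi-square
#'
#' Minimises [rdm_objective()] for one subject by Nelder-Mead simplex with
#' multistart: the first start is a method-of-moments heuristic, the
#' remaining starts are jittered copies, and the best optimum is polished
#' by a final simplex run. Deterministic given `seed`.
#'
#' @param records one subject's trial data frame.
#' @param spec sub-model name or `submodel_spec` (default `"full"`).
#' @param s diffusion scaling constant (fixed, not fitted).
#' @param seed integer seed for the start-point jitter.
#' @param n_restarts number of simplex starts.
#' @param maxit maximum iterations per simplex run.
#' @param reltol simplex relative convergence tolerance.
#' @inheritParams rdm_objective
#' @param init optional [full_model_params()] used as the central start
#'   instead of the heuristic.
#' @return An object of class `rdm_fit`: best-fit parameters (`params`),
#'   `chi_square`, `n_components`, `df`, `critical_value`, `log_lik`,
#'   `aic`, `bic`, `n_obs`, `summaries` and optimiser `diagnostics`.
#' @export
fit_rdm <- function(records, spec = "full", s = 1, seed = 1,
                    n_restarts = 5, maxit = 1500, reltol = 1e-6,
                    n_gh = 20L, n_gl = 10L, init = NULL) {
  if (is.character(spec)) spec <- submodel(spec)
  summaries <- condition_summaries(records)
  start_full <- if (is.null(init)) .init_full(summaries, s) else init
  theta0 <- .full_to_theta(start_full, spec)
  d <- length(theta0)

  set.seed(seed)
  starts <- c(list(theta0),
              lapply(seq_len(max(n_restarts - 1, 0)),
                     function(i) theta0 + stats::rnorm(d, 0, 0.3)))

  obj <- function(th) rdm_objective(summaries, spec, th, s = s,
                                    n_gh = n_gh, n_gl = n_gl)
  best <- NULL
  evals <- 0L
  conv <- integer(0)
  for (st in starts) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    evals <- evals + o$counts[["function"]]
    conv <- c(conv, o$convergence)
    if (is.null(best) || o$value < best$value) best <- o
  }
  # quasi-Newton polish: the simplex reliably finds the basin but stalls
  # short of the minimum in 10-12 dimensions; a gradient-based finisher
  # recovers the last ~1 chi-square unit
  po <- stats::nlminb(best$par, obj,
                      control = list(iter.max = 500, eval.max = 2000))
  evals <- evals + sum(po$evaluations)
  if (po$objective <= best$value)
    best <- list(par = po$par, value = po$objective, convergence = po$convergence)
  conv <- c(conv, best$convergence)
  converged <- any(conv == 0)
  if (!converged)
    warning("fit_rdm: no simplex run converged within maxit; result flagged",
            call. = FALSE)

  params <- .theta_to_full(best$par, spec, s)
  M <- free_parameter_count(spec)
  n_dropped <- sum(vapply(summaries, function(x) x$n_error == 0L, logical(1)))
  df <- chisq_dof(J = 4, K = 7, M = M, n_dropped = n_dropped)
  lnL <- multinomial_loglik(records, params, n_gh = n_gh, n_gl = n_gl)
  n_obs <- sum(vapply(summaries, `[[`, 0, "n_trials"))
  subject <- if ("subject" %in% names(records)) unique(records$subject) else NA

  structure(list(
    submodel = spec$name,
    subject = subject,
    params = params,
    theta = best$par,
    chi_square = best$value,
    n_components = 28L - n_dropped,
    n_dropped = n_dropped,
    df = df,
    critical_value = critical_chisq(0.05, df),
    log_lik = lnL,
    M = M,
    aic = -2 * lnL + 2 * M,
    bic = -2 * lnL + M * log(n_obs),
    n_obs = n_obs,
    summaries = summaries,
    diagnostics = list(restarts = length(starts), evaluations = evals,
                       converged = converged, seed = seed)),
    class = "rdm_fit")
}

#' @export
print.rdm_fit <- function(x, ...) {
  cat(sprintf("Diffusion-model fit: sub-model '%s' (M = %d)%s\n",
              x$submodel, x$M,
              if (!is.na(x$subject[1])) paste0(", subject ", x$subject[1]) else ""))
  cat(sprintf("  chi-square = %.3f on %d df (critical %.3f at alpha = 0.05) -> %s\n",
              x$chi_square, x$df, x$critical_value,
              if (x$chi_square < x$critical_value) "acceptable" else "rejected"))
  cat(sprintf("  lnL = %.2f, AIC = %.1f, BIC = %.1f, n = %d trials (%d chi-square cells)\n",
              x$log_lik, x$aic, x$bic, x$n_obs, x$n_components))
  cat("  parameters:\n")
  v <- unlist(x$params)
  print(round(v, 4))
  invisible(x)
}
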