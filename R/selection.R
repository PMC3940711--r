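#' Degrees of freedom of the quantile chi-square fit
#'
#' `df = J*(K - 1) - M - n_dropped`, where `J` is the number of conditions,
#' `K` the number of chi-square cells per full condition, `M` the number of
#' free model parameters, and `n_dropped` the number of error cells omitted
#' because a condition had perfect accuracy.
#'
#' @param J number of conditions (>= 1).
#' @param K chi-square cells per full condition (>= 2).
#' @param M free model parameters (>= 1).
#' @param n_dropped dropped error cells (>= 0).
#' @return Integer degrees of freedom (>= 1).
#' @examples
#' chisq_dof(4, 7, 12)     # 12
#' chisq_dof(4, 7, 12, 1)  # 11
#' @export
chisq_dof <- function(J, K, M, n_dropped = 0) {
  if (J < 1 || K < 2 || M < 1 || n_dropped < 0)
    stop("chisq_dof: require J >= 1, K >= 2, M >= 1, n_dropped >= 0",
         call. = FALSE)
  df <- J * (K - 1) - M - n_dropped
  if (df < 1)
    stop(sprintf("chisq_dof: J(K-1) - M - n_dropped = %d is below 1", df),
         call. = FALSE)
  as.integer(df)
}

#' Critical chi-square value for the goodness-of-fit test
#'
#' Upper-tail `1 - alpha` quantile of the chi-square distribution: a fitted
#' model is acceptable when its minimised chi-square falls below this
#' threshold.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return The threshold (full precision; round to 3 decimals for
#'   reporting).
#' @examples
#' round(critical_chisq(0.05, 12), 3)  # 21.026
#' @export
critical_chisq <- function(alpha, df) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("critical_chisq: alpha must be in (0, 1)", call. = FALSE)
  if (!is.finite(df) || df < 1)
    stop("critical_chisq: df must be >= 1", call. = FALSE)
  stats::qchisq(1 - alpha, df)
}

#' Multinomial log-likelihood over the quantile bins
#'
#' The likelihood used for AIC/BIC: per condition, observed trial counts in
#' the six correct-latency quantile bins plus the error cell, under the
#' model's bin masses ([bin_probabilities()]) for that condition. The
#' binning is identical to the chi-square objective, so the information
#' criteria compare models on the same summary of the data. The
#' multinomial coefficient is omitted (it is model-independent), so
#' `lnL = sum n_i log p_i <= 0`.
#'
#' @param records one subject's trial data frame.
#' @param params a [full_model_params()] object.
#' @inheritParams response_prob
#' @return Scalar log-likelihood (natural log). A model cell with zero
#'   probability but nonzero count yields `-Inf` with a warning.
#' @export
multinomial_loglik <- function(records, params, n_gh = 24L, n_gl = 12L) {
  if (!inherits(params, "full_model_params"))
    stop("expected a 'full_model_params' object", call. = FALSE)
  d <- .prepare_fit_data(records)
  lnL <- 0
  for (cond in conditions()) {
    sm <- .summarize_prepared(d, cond)
    lat_c <- d$latency[d$condition == cond & d$correct]
    counts <- c(tabulate(findInterval(lat_c, sm$quantiles,
                                      left.open = TRUE) + 1L, nbins = 6L),
                sm$n_error)
    p <- bin_probabilities(expand_condition(params, cond), sm$quantiles,
                           n_gh, n_gl)
    bad <- p <= 0 & counts > 0
    if (any(bad)) {
      warning("multinomial_loglik: model assigns zero mass to an occupied cell",
              call. = FALSE)
      return(-Inf)
    }
    nz <- counts > 0
    lnL <- lnL + sum(counts[nz] * log(p[nz]))
  }
  lnL
}

#' Compare fitted sub-models by AIC and BIC
#'
#' Tabulates per-subject AIC/BIC for every fitted sub-model, sums across
#' subjects (the across-subject comparison, valid under subject
#' independence) and flags the minima.
#'
#' @param fits list of [fit_rdm()] results covering every (subject,
#'   sub-model) combination; a missing combination is an error.
#' @return A list of class `model_comparison`: `table` (one row per
#'   subject and sub-model: `M`, `log_lik`, `aic`, `bic`, per-subject
#'   best flags) and `summed` (per sub-model column sums with overall
#'   best flags).
#' @export
compare_models <- function(fits) {
  ok <- vapply(fits, inherits, logical(1), "rdm_fit")
  if (!length(fits) || !all(ok))
    stop("compare_models: 'fits' must be a list of rdm_fit objects", call. = FALSE)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(subject = as.character(f$subject[1]), submodel = f$submodel,
               M = f$M, log_lik = f$log_lik, aic = f$aic, bic = f$bic,
               stringsAsFactors = FALSE)))
  subjects <- unique(tab$subject)
  models <- unique(tab$submodel)
  grid <- expand.grid(subject = subjects, submodel = models,
                      stringsAsFactors = FALSE)
  have <- paste(tab$subject, tab$submodel)
  missing <- grid[!paste(grid$subject, grid$submodel) %in% have, , drop = FALSE]
  if (nrow(missing))
    stop("compare_models: missing fits for: ",
         paste(sprintf("%s/%s", missing$subject, missing$submodel),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(have))
    stop("compare_models: duplicated (subject, submodel) fits", call. = FALSE)

  tab$aic_best <- stats::ave(tab$aic, tab$subject, FUN = function(x) x == min(x)) == 1
  tab$bic_best <- stats::ave(tab$bic, tab$subject, FUN = function(x) x == min(x)) == 1

  summed <- do.call(rbind, lapply(split(tab, tab$submodel), function(g)
    data.frame(submodel = g$submodel[1], M = g$M[1],
               log_lik = sum(g$log_lik), aic = sum(g$aic), bic = sum(g$bic),
               stringsAsFactors = FALSE)))
  summed <- summed[match(models, summed$submodel), , drop = FALSE]
  rownames(summed) <- NULL
  summed$aic_best <- summed$aic == min(summed$aic)
  summed$bic_best <- summed$bic == min(summed$bic)
  structure(list(table = tab, summed = summed), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Across-subject model comparison (summed AIC/BIC):\n")
  s <- x$summed
  s$aic <- round(s$aic, 1); s$bic <- round(s$bic, 1)
  s$log_lik <- round(s$log_lik, 2)
  print(s, row.names = FALSE)
  invisible(x)
}
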