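#' Group-level tests on fitted parameters
#'
#' `one_tailed_t` tests whether a parameter's across-subject mean exceeds
#' zero (one-sample t against 0, upper tail, `df = n - 1`);
#' `paired_two_tailed_t` tests whether two parameters differ within
#' subjects (paired t, two tails).
#'
#' @param values numeric vector of per-subject parameter values (n >= 2,
#'   nonzero variance).
#' @return A list with `t`, `df` and `p` (unrounded; round to 3 decimals
#'   for reporting).
#' @export
one_tailed_t <- function(values) {
  if (length(values) < 2L)
    stop("one_tailed_t: at least 2 values are required", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("one_tailed_t: zero variance", call. = FALSE)
  tt <- stats::t.test(values, mu = 0, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' @rdname one_tailed_t
#' @param x,y equal-length numeric vectors of paired per-subject values.
#' @export
paired_two_tailed_t <- function(x, y) {
  if (length(x) != length(y))
    stop("paired_two_tailed_t: x and y must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("paired_two_tailed_t: at least 2 pairs are required", call. = FALSE)
  if (stats::sd(x - y) == 0)
    stop("paired_two_tailed_t: zero variance of the differences", call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Chi-square test for an accuracy difference
#'
#' 2x2 test of independence on correct/error counts between two
#' conditions; no continuity correction by default.
#'
#' @param correct1,n1 correct count and trial count in condition 1.
#' @param correct2,n2 likewise for condition 2.
#' @param yates apply the continuity correction.
#' @return The p-value.
#' @export
accuracy_chisq <- function(correct1, n1, correct2, n2, yates = FALSE) {
  if (any(c(correct1, n1, correct2, n2) < 0) || correct1 > n1 || correct2 > n2)
    stop("accuracy_chisq: invalid counts", call. = FALSE)
  m <- rbind(c(correct1, n1 - correct1), c(correct2, n2 - correct2))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("accuracy_chisq: a table margin is empty", call. = FALSE)
  unname(suppressWarnings(stats::chisq.test(m, correct = yates))$p.value)
}

#' Two-sample t-test for a latency difference
#'
#' Welch (unequal-variance) two-tailed test by default; set
#' `var_equal = TRUE` for the pooled-variance version.
#'
#' @param latencies1,latencies2 latency vectors (n >= 2 each).
#' @param var_equal pooled-variance toggle.
#' @return A list with `t`, `df` and `p`.
#' @export
latency_t_test <- function(latencies1, latencies2, var_equal = FALSE) {
  if (length(latencies1) < 2L || length(latencies2) < 2L)
    stop("latency_t_test: at least 2 latencies per condition", call. = FALSE)
  if (stats::sd(latencies1) == 0 && stats::sd(latencies2) == 0)
    stop("latency_t_test: both samples are constant", call. = FALSE)
  tt <- stats::t.test(latencies1, latencies2, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Mean and standard error of a parameter column
#'
#' @param values per-subject values (n >= 2).
#' @return Named vector `c(mean, sem)` with `sem = sd / sqrt(n)`
#'   (n - 1 denominator SD).
#' @export
column_summary <- function(values) {
  if (length(values) < 2L)
    stop("column_summary: at least 2 values are required", call. = FALSE)
  c(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)))
}

#' Quantile-probability data for observed versus predicted fits
#'
#' One row per condition: observed accuracy and correct-latency quantiles
#' next to the model's predicted accuracy and quantiles (the inverse of the
#' conditional correct-latency CDF at the same cumulative fractions), plus
#' observed and expected error counts. This is the data behind a quantile
#' probability plot.
#'
#' @param records the subject's trial data frame used for the fit.
#' @param fit an [fit_rdm()] result.
#' @inheritParams response_prob
#' @return A 4-row data frame.
#' @export
qpp_table <- function(records, fit, n_gh = 24L, n_gl = 12L) {
  if (!inherits(fit, "rdm_fit"))
    stop("expected an 'rdm_fit' object", call. = FALSE)
  summaries <- condition_summaries(records)
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  rows <- lapply(conditions(), function(cond) {
    sm <- summaries[[cond]]
    p <- expand_condition(fit$params, cond)
    pc <- response_prob(p, n_gh, n_gl)
    mq <- vapply(probs, function(fr)
      .rt_quantile(p, fr, pc, n_gh, n_gl), numeric(1))
    out <- data.frame(condition = cond, n_trials = sm$n_trials,
                      obs_accuracy = sm$n_correct / sm$n_trials,
                      pred_accuracy = pc,
                      obs_errors = sm$n_error,
                      pred_errors = sm$n_trials * (1 - pc))
    out[paste0("obs_q", probs * 100)] <- as.list(sm$quantiles)
    out[paste0("pred_q", probs * 100)] <- as.list(mq)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Inverse of the conditional correct-latency CDF at fraction `fr`.
.rt_quantile <- function(p, fr, pc, n_gh = 24L, n_gl = 12L) {
  target <- fr * pc
  lo <- max(p$Ter - p$St / 2, 0)
  hi <- p$Ter + p$St / 2 + 5 * p$a^2 / p$s^2 + 2 * p$a / max(abs(p$v), 0.1)
  while (rt_cdf(hi, p, "correct", n_gh, n_gl) < target && hi < 1e3) hi <- hi * 2
  stats::uniroot(function(t) rt_cdf(t, p, "correct", n_gh, n_gl) - target,
                 lower = lo, upper = hi, tol = 1e-8)$root
}
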