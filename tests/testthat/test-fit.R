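test_that("the 5-SD outlier rule removes only extreme latencies", {
  expect_identical(filter_outliers(numeric(0)), numeric(0))
  expect_identical(filter_outliers(rep(0.3, 10)), rep(0.3, 10))
  set.seed(8)
  x <- c(0.3 + runif(199, -0.01, 0.01), 5)
  filtered <- filter_outliers(x)
  # the 5-second value is more than 5 SDs from the mean of the full input
  expect_true(abs(5 - mean(x)) > 5 * sd(x))
  expect_identical(filtered, x[1:199])
  # order preserved
  expect_identical(filter_outliers(c(0.4, 0.2, 0.3)), c(0.4, 0.2, 0.3))
})

test_that("condition summaries count trials and interpolate quantiles correctly", {
  lat <- (1:100) / 200
  rec <- data.frame(subject = 1, condition = "SRe", target_present = TRUE,
                    latency = lat, correct = TRUE)
  sm <- summarize_condition(rec, "SRe")
  expect_identical(sm$n_trials, 100L)
  expect_identical(sm$n_error, 0L)
  expect_equal(sm$quantiles[3], median(lat))
  expect_true(all(diff(sm$quantiles) >= 0))
  # 10-value toy against the brute-force interpolation oracle
  set.seed(14)
  y <- sort(runif(10, 0.2, 0.5))
  rec2 <- data.frame(subject = 1, condition = "TP", target_present = TRUE,
                     latency = y, correct = TRUE)
  sm2 <- summarize_condition(rec2, "TP")
  expect_equal(sm2$quantiles,
               vapply(c(.1, .3, .5, .7, .9), function(p) brute_quantile7(y, p),
                      numeric(1)))
  # too few correct trials is an explicit error
  rec3 <- rec2; rec3$correct <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_error(summarize_condition(rec3, "TP"), "at least 6")
})

test_that("chi-square components match hand-computed cell arithmetic", {
  # no-variability model whose bin masses follow from the Wiener CDF alone
  p <- rdm_params(v = 0.66, a = 0.064, B = 0.55, Ter = 0.24, s = 0.1)
  w <- wiener_params(0.66, 0.064, 0.55 * 0.064, s = 0.1)
  pc <- absorb_prob_upper(w)
  # edges at the model's own 10/30/50/70/90 correct percentiles
  edges <- vapply(c(.1, .3, .5, .7, .9), function(fr)
    0.24 + stats::uniroot(function(t) fpt_cdf(t, w, "upper") - fr * pc,
                          lower = 1e-6, upper = 3, tol = 1e-12)$root,
    numeric(1))
  sm <- structure(list(condition = "SRe", n_trials = 100L, n_correct = 90L,
                       n_error = 10L, quantiles = edges,
                       min_latency = 0.25, mean_latency = 0.3),
                  class = "condition_summary")
  comp <- chisq_components(sm, p)
  p_exp <- c(c(.1, .2, .2, .2, .2, .1) * pc, 1 - pc)
  p_obs <- c(c(.1, .2, .2, .2, .2, .1) * 0.9, 0.1)
  expect_equal(comp, 100 * (p_obs - p_exp)^2 / p_exp, tolerance = 1e-4)
  # perfect agreement gives all-zero components
  sm0 <- sm
  sm0$n_correct <- as.integer(round(100 * pc))
  sm0$n_error <- 100L - sm0$n_correct
  comp0 <- chisq_components(sm0, p)
  expect_lt(max(abs(comp0)), 0.01)
  # a condition with no errors contributes six components
  sm6 <- sm; sm6$n_correct <- 100L; sm6$n_error <- 0L
  expect_length(chisq_components(sm6, p), 6)
  expect_length(comp, 7)
})

test_that("the objective sums 28 cells, ignores trial order and penalises invalid vectors", {
  d <- small_study()
  summ <- condition_summaries(d)
  spec <- submodel("full")
  th <- seldiff:::.full_to_theta(reference_full_params("P1"), spec)
  v1 <- rdm_objective(summ, spec, th, s = 0.1)
  # component count: 7 per condition minus dropped error cells
  n_comp <- sum(vapply(summ, function(x) if (x$n_error == 0) 6L else 7L,
                       integer(1)))
  expect_identical(28L - sum(vapply(summ, function(x) x$n_error == 0,
                                    logical(1))), n_comp)
  # permutation invariance: shuffling rows leaves the summaries and value
  set.seed(2)
  d2 <- d[sample.int(nrow(d)), ]
  expect_equal(rdm_objective(condition_summaries(d2), spec, th, s = 0.1), v1)
  # an out-of-domain vector gets a large finite penalty
  th_bad <- th; th_bad[which(seldiff:::.free_names(spec) == "Sz")] <- 10
  v_bad <- rdm_objective(summ, spec, th_bad, s = 0.1)
  expect_true(is.finite(v_bad) && v_bad >= 1e8)
})

test_that("fitting is deterministic, beats the generating parameters and nests properly", {
  d <- small_study()
  spec <- submodel("full")
  m_true <- reference_full_params("P1")
  f1 <- fit_rdm(d, "full", s = 0.1, seed = 3, n_restarts = 2, maxit = 800)
  # optimality: no worse than the generating parameters
  at_truth <- rdm_objective(condition_summaries(d), spec,
                            seldiff:::.full_to_theta(m_true, spec), s = 0.1)
  expect_lte(f1$chi_square, at_truth + 1e-6)
  # determinism
  f2 <- fit_rdm(d, "full", s = 0.1, seed = 3, n_restarts = 2, maxit = 800)
  expect_identical(f1$chi_square, f2$chi_square)
  expect_identical(f1$theta, f2$theta)
  # bookkeeping: df, component count, information criteria
  expect_identical(f1$M, 12L)
  expect_identical(f1$df, chisq_dof(4, 7, 12, f1$n_dropped))
  expect_equal(f1$aic, -2 * f1$log_lik + 2 * 12)
  expect_equal(f1$bic, -2 * f1$log_lik + 12 * log(f1$n_obs))
  # nested-model dominance: the full model, started from the constrained
  # optimum, can only improve on it
  fsub <- fit_rdm(d, "nov_all", s = 0.1, seed = 3, n_restarts = 2, maxit = 800)
  ffull <- fit_rdm(d, "full", s = 0.1, seed = 3, n_restarts = 2, maxit = 800,
                   init = apply_constraints(fsub$params, "nov_all"))
  expect_lte(ffull$chi_square, fsub$chi_square + 1e-3)
  expect_identical(fsub$M, 10L)
})
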