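test_that("response probability reduces to the Wiener closed form and obeys symmetry", {
  # degenerate symmetric case
  expect_equal(response_prob(rdm_params(v = 0, a = 0.3, B = 0.5, Ter = 0.2)), 0.5)
  # degenerate-variability identity (eta = Sz = 0)
  p <- rdm_params(v = 0.6785, a = 0.0567, B = 0.5, Ter = 0.25, St = 0.04, s = 0.1)
  expect_equal(response_prob(p),
               absorb_prob_upper(wiener_params(0.6785, 0.0567, 0.02835, s = 0.1)),
               tolerance = 1e-10)
  # frozen 10^6-trial simulation oracle at the P1 DP condition
  pdp <- rdm_params(v = 0.6785 - 0.0839, a = 0.0567, B = 0.5 + 0.1852,
                    Ter = 0.2579, eta = 0.2083, Sz = 0, St = 0.0467, s = 0.1)
  expect_lt(abs(response_prob(pdp) - mc_oracle_p1dp_response$value),
            3 * mc_oracle_p1dp_response$se)
  # bias monotonicity, everything else fixed
  pr <- vapply(seq(0.15, 0.85, length.out = 15), function(B)
    response_prob(rdm_params(v = 0.4, a = 0.08, B = B, Ter = 0.25,
                             eta = 0.3, St = 0.05, s = 0.1)), numeric(1))
  expect_true(all(diff(pr) > 0))
  # invariant enforcement
  expect_error(rdm_params(v = 1, a = 0.1, B = 0.9, Ter = 0.2, Sz = 0.05), "Sz")
  expect_error(rdm_params(v = 1, a = 0.1, B = 0.5, Ter = 0.01, St = 0.1), "Ter")
})

test_that("latency CDF respects the non-decision floor, totality and degenerate identity", {
  p <- rdm_params(v = 0.5, a = 0.08, B = 0.6, Ter = 0.25, eta = 0.2,
                  Sz = 0.02, St = 0.05, s = 0.1)
  # nothing can be absorbed before Ter - St/2
  expect_equal(rt_cdf(c(0, 0.1, 0.2249), p, "correct"), c(0, 0, 0))
  expect_equal(rt_cdf(0.2249, p, "error"), 0)
  # totality
  expect_equal(rt_cdf(Inf, p, "correct") + rt_cdf(Inf, p, "error"), 1,
               tolerance = 1e-6)
  # monotone
  Fs <- rt_cdf(seq(0.2, 0.8, length.out = 60), p, "correct")
  expect_true(all(diff(Fs) >= -1e-12))
  # degenerate variability: rt_cdf(t) = fpt_cdf(t - Ter)
  p0 <- rdm_params(v = 0.5, a = 0.08, B = 0.6, Ter = 0.25, s = 0.1)
  w0 <- wiener_params(0.5, 0.08, 0.048, s = 0.1)
  ts <- c(0.26, 0.3, 0.4, 0.7)
  expect_equal(rt_cdf(ts, p0, "correct"), fpt_cdf(ts - 0.25, w0, "upper"),
               tolerance = 1e-10)
  expect_error(rt_cdf(-0.1, p, "correct"), ">= 0")
})

test_that("simulated latencies agree with the analytic distribution (KS)", {
  set.seed(91)
  p <- rdm_params(v = 0.51, a = 0.0759, B = 0.5 + 0.096, Ter = 0.2419,
                  eta = 0, Sz = 0, St = 0.0726, s = 0.1)
  sim <- simulate_trials(20000, p, dt = 5e-5)
  pc <- response_prob(p)
  expect_lt(abs(mean(sim$correct) - pc), 3 * sqrt(pc * (1 - pc) / 20000))
  lat <- sim$latency[sim$correct]
  ks <- suppressWarnings(
    stats::ks.test(lat, function(t) rt_cdf(t, p, "correct") / pc))
  expect_gt(ks$p.value, 0.01)
})

test_that("bin probabilities are a partition: normalisation, self-consistency, quadrature", {
  # toy no-variability case against direct quadrature of the density
  p <- rdm_params(v = 1, a = 1, B = 0.5, Ter = 0.2)
  edges <- c(0.3, 0.4, 0.5, 0.7, 1.0)
  bp <- bin_probabilities(p, edges)
  w <- wiener_params(1, 1, 0.5)
  cuts <- c(0, edges - 0.2, Inf)
  quad <- vapply(seq_len(6), function(i) {
    stats::integrate(function(t) fpt_density(t, w, "upper"),
                     cuts[i], cuts[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(bp[1:6], quad, tolerance = 1e-5)
  expect_equal(bp[7], absorb_prob_lower(w), tolerance = 1e-6)

  # normalisation for random valid parameter sets
  set.seed(5)
  for (i in 1:5) {
    pr <- rdm_params(v = runif(1, -0.5, 1), a = runif(1, 0.05, 0.12),
                     B = runif(1, 0.3, 0.7), Ter = 0.25,
                     eta = runif(1, 0, 0.4), Sz = 0.01, St = 0.04, s = 0.1)
    e <- sort(runif(5, 0.25, 0.5))
    expect_equal(sum(bin_probabilities(pr, e)), 1, tolerance = 1e-6)
  }

  # edges at the model's own percentiles give (.1,.2,.2,.2,.2,.1) * P(correct)
  p2 <- rdm_params(v = 0.66, a = 0.064, B = 0.64, Ter = 0.2466,
                   eta = 0.2, St = 0.0467, s = 0.1)
  pc <- response_prob(p2)
  own <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(fr)
    stats::uniroot(function(t) rt_cdf(t, p2, "correct") - fr * pc,
                   lower = 0.22, upper = 2, tol = 1e-10)$root, numeric(1))
  bp2 <- bin_probabilities(p2, own)
  expect_equal(bp2[1:6], c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1) * pc, tolerance = 1e-4)
  expect_equal(bp2[7], 1 - pc, tolerance = 1e-6)

  expect_error(bin_probabilities(p, c(0.3, 0.3, 0.5, 0.7, 1)), "increasing")
  expect_error(bin_probabilities(p, c(0.3, 0.5)), "5")
})
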