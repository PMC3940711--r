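# Independent oracles and shared fixtures for the suite.

# Upper-tail chi-square quantile by bisection on the regularised incomplete
# gamma function (pracma::gammainc), independent of stats::qchisq.
bisect_critical_chisq <- function(alpha, df, tol = 1e-8) {
  f <- function(x) pracma::gammainc(x / 2, df / 2)[["reginc"]] - (1 - alpha)
  lo <- 0; hi <- df
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force type-7 quantile (linear interpolation between order
# statistics), written out from the definition.
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Frozen Monte-Carlo oracles, each computed once from 10^6 independent
# Euler-Maruyama paths (boundary-corrected; plain vectorised R for the
# Wiener case, the package simulator at dt = 2.5e-5 for the marginalised
# case) and stored with the binomial standard error of the run.
mc_oracle_absorb_v1a1z05 <- list(value = 0.730394, se = 0.000444)  # v=1,a=1,z=0.5,s=1
mc_oracle_p1dp_response <- list(value = 0.977831, se = 0.000147)   # P1 DP params, s=0.1

# Small synthetic single-subject study shared by the fitting tests
# (2 sessions x 5 blocks x 64 trials = 640 trials).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- reference_full_params("P1")
      cache <<- generate_study(list(m), sessions = 2, blocks = 5,
                               trials_per_block = 64,
                               false_alarm_rate = 0.0094, seed = 11)
    }
    cache
  }
})
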