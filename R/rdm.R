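#' Per-condition diffusion-model parameters
#'
#' Parameters of the full Ratcliff diffusion model for one experimental
#' condition, including trial-to-trial variability: Gaussian variability in
#' drift (`eta`), uniform variability in the starting point (`Sz`, full
#' range) and uniform variability in the non-decision time (`St`, full
#' range). The starting point is parameterised by the relative bias
#' `B = z/a`, the quantity of scientific interest: `B = 0.5` is unbiased,
#' `B > 0.5` favours the target-colour boundary.
#'
#' @param v mean drift rate (evidence units per second).
#' @param a boundary separation (> 0).
#' @param B relative bias `z/a`, strictly between 0 and 1.
#' @param Ter mean non-decision time in seconds; must satisfy
#'   `Ter - St/2 >= 0`.
#' @param eta standard deviation of the trial-to-trial Gaussian drift
#'   variability (>= 0).
#' @param Sz full range of the uniform starting-point variability (evidence
#'   units); must keep the start strictly inside the boundaries:
#'   `Sz <= 2 * min(B, 1 - B) * a`.
#' @param St full range of the uniform non-decision-time variability
#'   (seconds, >= 0).
#' @param s within-trial diffusion coefficient (scaling constant).
#' @return An object of class `rdm_params`.
#' @examples
#' p <- rdm_params(v = 0.6, a = 0.08, B = 0.55, Ter = 0.25, s = 0.1)
#' response_prob(p)
#' @export
rdm_params <- function(v, a, B, Ter, eta = 0, Sz = 0, St = 0, s = 1) {
  vals <- c(v = v, a = a, B = B, Ter = Ter, eta = eta, Sz = Sz, St = St, s = s)
  if (!all(is.finite(vals)))
    stop("rdm_params: all parameters must be finite", call. = FALSE)
  if (a <= 0) stop("rdm_params: 'a' must be > 0", call. = FALSE)
  if (B <= 0 || B >= 1) stop("rdm_params: 'B' must satisfy 0 < B < 1", call. = FALSE)
  if (eta < 0) stop("rdm_params: 'eta' must be >= 0", call. = FALSE)
  if (Sz < 0) stop("rdm_params: 'Sz' must be >= 0", call. = FALSE)
  if (Sz > 2 * min(B, 1 - B) * a + 1e-12)
    stop("rdm_params: 'Sz' exceeds 2*min(B, 1-B)*a; start point would leave the boundaries",
         call. = FALSE)
  if (St < 0) stop("rdm_params: 'St' must be >= 0", call. = FALSE)
  if (Ter - St / 2 < 0)
    stop("rdm_params: 'Ter - St/2' must be >= 0", call. = FALSE)
  if (s <= 0) stop("rdm_params: 's' must be > 0", call. = FALSE)
  structure(list(v = v, a = a, B = B, Ter = Ter, eta = eta, Sz = Sz, St = St, s = s),
            class = "rdm_params")
}

#' @export
print.rdm_params <- function(x, ...) {
  cat(sprintf(
    "RDM condition parameters: v = %g, a = %g, B = %g, Ter = %g\n  eta = %g, Sz = %g, St = %g, s = %g\n",
    x$v, x$a, x$B, x$Ter, x$eta, x$Sz, x$St, x$s))
  invisible(x)
}

.as_rdm <- function(p) {
  if (!inherits(p, "rdm_params"))
    stop("expected an 'rdm_params' object", call. = FALSE)
  p
}

# Quadrature grids for the three variability integrals.  Gauss-Hermite for
# the Gaussian drift (exact weight function), Gauss-Legendre for the two
# uniform ranges.  Node counts are the package defaults; both integrands are
# smooth, and the defaults hold bin-mass error below ~1e-5.  Reference nodes
# are cached per node count (the fit objective calls this in a tight loop).
.quad_cache <- new.env(parent = emptyenv())

.gh_nodes <- function(n) {
  key <- paste0("gh", n)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussHermite(n)
  .quad_cache[[key]]
}

.gl_nodes <- function(n) {
  key <- paste0("gl", n)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .quad_cache[[key]]
}

.rdm_nodes <- function(p, n_gh = 24L, n_gl = 12L) {
  if (p$eta > 0) {
    gh <- .gh_nodes(n_gh)
    vs <- p$v + sqrt(2) * p$eta * gh$x
    wv <- gh$w / sqrt(pi)
  } else {
    vs <- p$v; wv <- 1
  }
  z0 <- p$B * p$a
  if (p$Sz > 0) {
    gl <- .gl_nodes(n_gl)
    zs <- z0 + gl$x * p$Sz / 2
    wz <- gl$w / 2
  } else {
    zs <- z0; wz <- 1
  }
  if (p$St > 0) {
    gl <- .gl_nodes(n_gl)
    ts <- p$Ter + gl$x * p$St / 2
    wt <- gl$w / 2
  } else {
    ts <- p$Ter; wt <- 1
  }
  list(vs = vs, wv = wv, zs = zs, wz = wz, ters = ts, wt = wt)
}

#' Predicted probability of a correct response
#'
#' Probability of absorption at the upper (target-colour) boundary,
#' marginalised over the Gaussian drift variability and the uniform
#' starting-point variability. Reduces exactly to [absorb_prob_upper()] when
#' `eta = Sz = 0`.
#'
#' @param p an [rdm_params()] object.
#' @param n_gh number of Gauss-Hermite nodes for the drift integral.
#' @param n_gl number of Gauss-Legendre nodes for each uniform integral.
#' @return A probability in \[0, 1\].
#' @export
response_prob <- function(p, n_gh = 24L, n_gl = 12L) {
  p <- .as_rdm(p)
  nd <- .rdm_nodes(p, n_gh, n_gl)
  pr <- cpp_rdm_prob_upper(nd$vs, nd$wv, nd$zs, nd$wz, p$a, p$s)
  min(max(pr, 0), 1)
}

#' Predicted latency distribution for correct or error responses
#'
#' Defective CDF of the observed saccade latency,
#' \eqn{P(\text{outcome and latency} \le t)}, where latency = decision time
#' + non-decision time. Uniform non-decision-time variability enters as an
#' average of shifted decision-time CDFs (exact for CDFs). `rt_cdf(Inf,
#' correct) + rt_cdf(Inf, error) = 1`.
#'
#' @param t vector of latencies in seconds (`>= 0`).
#' @param p an [rdm_params()] object.
#' @param outcome `"correct"` (upper boundary) or `"error"` (lower).
#' @inheritParams response_prob
#' @return Vector of defective cumulative probabilities, nondecreasing in
#'   `t` and zero for all `t < Ter - St/2`.
#' @export
rt_cdf <- function(t, p, outcome = c("correct", "error"),
                   n_gh = 24L, n_gl = 12L) {
  p <- .as_rdm(p)
  outcome <- match.arg(outcome)
  if (any(is.na(t)) || any(t < 0))
    stop("rt_cdf: latencies must be >= 0", call. = FALSE)
  upper <- outcome == "correct"
  pmax_val <- if (upper) response_prob(p, n_gh, n_gl) else 1 - response_prob(p, n_gh, n_gl)
  out <- numeric(length(t))
  fin <- is.finite(t)
  if (any(fin)) {
    nd <- .rdm_nodes(p, n_gh, n_gl)
    out[fin] <- cpp_rdm_cdf(as.numeric(t[fin]), nd$vs, nd$wv, nd$zs, nd$wz,
                            nd$ters, nd$wt, p$a, p$s, upper)
  }
  out[!fin] <- pmax_val
  pmin(pmax(out, 0), pmax_val)
}

#' Predicted bin masses for the quantile chi-square fit
#'
#' Splits the predicted latency distribution into the seven cells used by
#' the fitting objective: six correct-response bins delimited by the five
#' observed latency quantiles, plus a single error cell holding the entire
#' error probability. The seven masses sum to 1.
#'
#' @param p an [rdm_params()] object.
#' @param edges five strictly increasing latency values (seconds), normally
#'   the observed 10/30/50/70/90% quantiles of correct latencies.
#' @inheritParams response_prob
#' @return Numeric vector of 7 probabilities: 6 correct bins then 1 error
#'   cell.
#' @export
bin_probabilities <- function(p, edges, n_gh = 24L, n_gl = 12L) {
  p <- .as_rdm(p)
  if (length(edges) != 5L)
    stop("bin_probabilities: exactly 5 quantile edges are required", call. = FALSE)
  if (any(diff(edges) <= 0))
    stop("bin_probabilities: edges must be strictly increasing", call. = FALSE)
  pc <- response_prob(p, n_gh, n_gl)
  cc <- rt_cdf(edges, p, "correct", n_gh, n_gl)
  masses <- diff(c(0, cc, pc))
  masses[masses < 0] <- 0
  c(masses, 1 - pc)
}
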