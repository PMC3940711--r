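#' Single-trial Wiener process parameters
#'
#' Container for a drifted Wiener (Brownian) process between two absorbing
#' boundaries, the decision core of the diffusion model: evidence starts at
#' `z`, drifts at mean rate `v` with within-trial standard deviation `s`, and
#' is absorbed at the upper boundary `a` (target-colour decision) or the
#' lower boundary 0 (distractor-colour decision).
#'
#' @param v drift rate (evidence units per second).
#' @param a boundary separation; upper boundary at `a`, lower at 0. Must be
#'   positive.
#' @param z starting point, strictly between 0 and `a`.
#' @param s within-trial diffusion coefficient. A scaling constant: only the
#'   ratios `v/s^2`, `a`, `z` matter, so it is conventionally fixed (1 here;
#'   0.1 in some fitting toolboxes).
#' @return An object of class `wiener_params`.
#' @examples
#' p <- wiener_params(v = 1, a = 1, z = 0.5)
#' absorb_prob_upper(p)
#' @export
wiener_params <- function(v, a, z, s = 1) {
  stopifnot(length(v) == 1L, length(a) == 1L, length(z) == 1L, length(s) == 1L)
  if (!all(is.finite(c(v, a, z, s))))
    stop("wiener_params: all parameters must be finite", call. = FALSE)
  if (a <= 0) stop("wiener_params: boundary separation 'a' must be > 0", call. = FALSE)
  if (z <= 0 || z >= a)
    stop("wiener_params: starting point 'z' must satisfy 0 < z < a", call. = FALSE)
  if (s <= 0) stop("wiener_params: diffusion coefficient 's' must be > 0", call. = FALSE)
  structure(list(v = v, a = a, z = z, s = s), class = "wiener_params")
}

#' @export
print.wiener_params <- function(x, ...) {
  cat(sprintf("Wiener process: v = %g, a = %g, z = %g (z/a = %.4f), s = %g\n",
              x$v, x$a, x$z, x$z / x$a, x$s))
  invisible(x)
}

.as_wiener <- function(p) {
  if (!inherits(p, "wiener_params"))
    stop("expected a 'wiener_params' object", call. = FALSE)
  p
}

#' Absorption probabilities at the decision boundaries
#'
#' Probability that the process is absorbed at the upper boundary `a` (resp.
#' lower boundary 0) before the other. Closed form
#' \deqn{P_a = \frac{1 - e^{-2vz/s^2}}{1 - e^{-2va/s^2}},}
#' continuous in `v` with the driftless limit \eqn{z/a}.
#'
#' @param p a [wiener_params()] object.
#' @return A probability in \[0, 1\].
#' @export
absorb_prob_upper <- function(p) {
  p <- .as_wiener(p)
  cpp_absorb_upper(p$v, p$a, p$z, p$s)
}

#' @rdname absorb_prob_upper
#' @export
absorb_prob_lower <- function(p) {
  1 - absorb_prob_upper(p)
}

.match_boundary <- function(boundary) {
  match.arg(boundary, c("upper", "lower"))
}

#' First-passage-time density at a boundary
#'
#' Defective density of the absorption time at the named boundary: it
#' integrates over \eqn{t \in (0, \infty)} to the corresponding absorption
#' probability, not to 1. The evaluation switches between the classical
#' small-time (method of images) series and the large-time trigonometric
#' series at normalised time \eqn{t s^2 / a^2 = 0.1}, with adaptive
#' truncation (absolute error well below 1e-7).
#'
#' @param t vector of times in seconds (all `>= 0`).
#' @param p a [wiener_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @return Vector of nonnegative densities (per second).
#' @export
fpt_density <- function(t, p, boundary = c("upper", "lower")) {
  p <- .as_wiener(p)
  boundary <- .match_boundary(boundary)
  if (any(!is.finite(t)) || any(t < 0))
    stop("fpt_density: times must be finite and >= 0", call. = FALSE)
  cpp_wiener_pdf(as.numeric(t), p$v, p$a, p$z, p$s, boundary == "upper")
}

#' First-passage-time distribution function at a boundary
#'
#' Defective CDF \eqn{P(\text{absorbed at boundary and } T \le t)};
#' nondecreasing in `t` with limit equal to the absorption probability. The
#' large-time series is integrated term by term in closed form, so no
#' numerical quadrature is involved.
#'
#' @inheritParams fpt_density
#' @return Vector of defective cumulative probabilities.
#' @export
fpt_cdf <- function(t, p, boundary = c("upper", "lower")) {
  p <- .as_wiener(p)
  boundary <- .match_boundary(boundary)
  if (any(!is.finite(t)) || any(t < 0))
    stop("fpt_cdf: times must be finite and >= 0", call. = FALSE)
  cpp_wiener_cdf(as.numeric(t), p$v, p$a, p$z, p$s, boundary == "upper")
}
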