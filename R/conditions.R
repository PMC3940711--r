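#' The four inter-trial search conditions
#'
#' Target-present trials are classified by their relation to the preceding
#' trial: `SRe` (search repeated: same target/distractor colour assignment),
#' `SSw` (search switched), `TP` (target-colour previewed: the preceding
#' target-absent display was in the current target's colour) and `DP`
#' (distractor-colour previewed). SRe/SSw carry priming of pop-out; TP/DP
#' carry the distractor preview effect.
#'
#' @return Character vector of the four condition labels.
#' @export
conditions <- function() c("SRe", "SSw", "TP", "DP")

#' Full-model parameter vector
#'
#' The 12 free parameters of the full diffusion model of selection history.
#' Bias and drift in each condition are tied to the preceding-trial family:
#' `B = 0.5 + dB_dpe` (DP), `0.5 - dB_dpe` (TP), `0.5 + dB_pop` (SRe),
#' `0.5 - dB_pop` (SSw); `v = v0 + dv_dpe` (DP), `v0 - dv_dpe` (TP),
#' `v0 + dv_pop` (SRe), `v0 - dv_pop` (SSw). Boundary separation and
#' non-decision time are shared within each family (`a_dpe`/`Ter_dpe` for
#' TP and DP, `a_pop`/`Ter_pop` for SRe and SSw) because the preceding
#' trial — the only thing that differs between members of a family — is
#' identical. The variability parameters `Sz`, `St`, `eta` are shared by
#' all four conditions.
#'
#' @param dB_dpe,dB_pop bias deltas (dimensionless; may be negative;
#'   positive values favour DP and SRe respectively).
#' @param v0 baseline drift rate.
#' @param dv_dpe,dv_pop drift deltas (may be negative).
#' @param a_dpe,a_pop boundary separations (> 0).
#' @param Ter_dpe,Ter_pop non-decision times (seconds, each `> St/2`).
#' @param Sz,St,eta shared trial-to-trial variability parameters (>= 0).
#' @param s within-trial diffusion coefficient (scaling constant, not a
#'   free parameter).
#' @return An object of class `full_model_params`.
#' @examples
#' m <- full_model_params(dB_dpe = 0.19, dB_pop = 0.14, v0 = 0.68,
#'                        dv_dpe = -0.08, dv_pop = -0.02,
#'                        a_dpe = 0.057, a_pop = 0.064,
#'                        Ter_dpe = 0.258, Ter_pop = 0.247,
#'                        Sz = 0, St = 0.047, eta = 0.21, s = 0.1)
#' expand_condition(m, "TP")
#' @export
full_model_params <- function(dB_dpe, dB_pop, v0, dv_dpe, dv_pop,
                              a_dpe, a_pop, Ter_dpe, Ter_pop,
                              Sz = 0, St = 0, eta = 0, s = 1) {
  vals <- c(dB_dpe = dB_dpe, dB_pop = dB_pop, v0 = v0, dv_dpe = dv_dpe,
            dv_pop = dv_pop, a_dpe = a_dpe, a_pop = a_pop,
            Ter_dpe = Ter_dpe, Ter_pop = Ter_pop, Sz = Sz, St = St,
            eta = eta, s = s)
  if (!all(is.finite(vals)))
    stop("full_model_params: all parameters must be finite", call. = FALSE)
  if (a_dpe <= 0 || a_pop <= 0)
    stop("full_model_params: boundary separations must be > 0", call. = FALSE)
  for (d in c(dB_dpe, dB_pop))
    if (0.5 + d <= 0 || 0.5 + d >= 1 || 0.5 - d <= 0 || 0.5 - d >= 1)
      stop("full_model_params: bias deltas must keep 0 < 0.5 +/- dB < 1",
           call. = FALSE)
  if (Sz < 0 || St < 0 || eta < 0)
    stop("full_model_params: Sz, St, eta must be >= 0", call. = FALSE)
  if (Ter_dpe <= St / 2 || Ter_pop <= St / 2)
    stop("full_model_params: non-decision times must exceed St/2", call. = FALSE)
  if (s <= 0) stop("full_model_params: 's' must be > 0", call. = FALSE)
  structure(list(dB_dpe = dB_dpe, dB_pop = dB_pop, v0 = v0,
                 dv_dpe = dv_dpe, dv_pop = dv_pop,
                 a_dpe = a_dpe, a_pop = a_pop,
                 Ter_dpe = Ter_dpe, Ter_pop = Ter_pop,
                 Sz = Sz, St = St, eta = eta, s = s),
            class = "full_model_params")
}

#' @export
print.full_model_params <- function(x, ...) {
  cat("Full-model parameters (12 free + scaling s):\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' Expand the full model into one condition's diffusion parameters
#'
#' Applies the condition-constraint scheme (see [full_model_params()]) to
#' produce the per-condition parameter set consumed by [response_prob()],
#' [rt_cdf()] and the simulator.
#'
#' @param m a [full_model_params()] object.
#' @param condition one of `"SRe"`, `"SSw"`, `"TP"`, `"DP"`.
#' @return An [rdm_params()] object.
#' @export
expand_condition <- function(m, condition) {
  if (!inherits(m, "full_model_params"))
    stop("expected a 'full_model_params' object", call. = FALSE)
  condition <- match.arg(condition, conditions())
  par <- switch(condition,
    DP  = list(B = 0.5 + m$dB_dpe, v = m$v0 + m$dv_dpe, a = m$a_dpe, Ter = m$Ter_dpe),
    TP  = list(B = 0.5 - m$dB_dpe, v = m$v0 - m$dv_dpe, a = m$a_dpe, Ter = m$Ter_dpe),
    SRe = list(B = 0.5 + m$dB_pop, v = m$v0 + m$dv_pop, a = m$a_pop, Ter = m$Ter_pop),
    SSw = list(B = 0.5 - m$dB_pop, v = m$v0 - m$dv_pop, a = m$a_pop, Ter = m$Ter_pop))
  out <- tryCatch(
    rdm_params(v = par$v, a = par$a, B = par$B, Ter = par$Ter,
               eta = m$eta, Sz = m$Sz, St = m$St, s = m$s),
    error = function(e)
      stop(sprintf("expand_condition: invalid parameters for condition %s: %s",
                   condition, conditionMessage(e)), call. = FALSE))
  out
}

# --- sub-model catalogue ----------------------------------------------------

.submodel_table <- list(
  full     = character(0),
  noB_all  = c("dB_dpe=0", "dB_pop=0"),
  noB_dpe  = "dB_dpe=0",
  noB_pop  = "dB_pop=0",
  nov_all  = c("dv_dpe=0", "dv_pop=0"),
  nov_dpe  = "dv_dpe=0",
  nov_pop  = "dv_pop=0",
  a_shared = "a_shared",
  t_shared = "t_shared"
)

#' Enumerate the nine candidate models
#'
#' The full 12-parameter model plus the eight constrained variants compared
#' by AIC/BIC: no bias change (in all, DPE-only or POP-only trials), no
#' drift change (likewise), a single shared boundary separation, and a
#' single shared non-decision time.
#'
#' @return A named list of `submodel_spec` objects, length 9.
#' @export
submodel_specs <- function() {
  lapply(stats::setNames(names(.submodel_table), names(.submodel_table)), submodel)
}

#' @rdname submodel_specs
#' @param name one of `"full"`, `"noB_all"`, `"noB_dpe"`, `"noB_pop"`,
#'   `"nov_all"`, `"nov_dpe"`, `"nov_pop"`, `"a_shared"`, `"t_shared"`.
#' @export
submodel <- function(name) {
  name <- match.arg(name, names(.submodel_table))
  structure(list(name = name, constraints = .submodel_table[[name]]),
            class = "submodel_spec")
}

#' @export
print.submodel_spec <- function(x, ...) {
  cons <- if (length(x$constraints)) paste(x$constraints, collapse = ", ") else "none"
  cat(sprintf("Sub-model '%s' (M = %d): constraints: %s\n",
              x$name, free_parameter_count(x), cons))
  invisible(x)
}

#' Number of free parameters of a sub-model
#'
#' The full model has 12 free parameters; each zero constraint and each
#' sharing constraint removes one.
#'
#' @param spec a `submodel_spec` (see [submodel()]), or its name.
#' @return Integer count `M`, used for degrees of freedom and AIC/BIC.
#' @export
free_parameter_count <- function(spec) {
  if (is.character(spec)) spec <- submodel(spec)
  if (!inherits(spec, "submodel_spec"))
    stop("expected a 'submodel_spec' object", call. = FALSE)
  12L - length(spec$constraints)
}

#' Impose a sub-model's constraints on a full parameter vector
#'
#' Zeroes the constrained deltas and/or collapses shared parameters (shared
#' values are taken as the mean of the two family-specific values).
#'
#' @param m a [full_model_params()] object.
#' @param spec a `submodel_spec` or its name.
#' @return A [full_model_params()] object satisfying the constraints.
#' @export
apply_constraints <- function(m, spec) {
  if (is.character(spec)) spec <- submodel(spec)
  if (!inherits(m, "full_model_params"))
    stop("expected a 'full_model_params' object", call. = FALSE)
  for (cons in spec$constraints) {
    m <- switch(cons,
      "dB_dpe=0" = { m$dB_dpe <- 0; m },
      "dB_pop=0" = { m$dB_pop <- 0; m },
      "dv_dpe=0" = { m$dv_dpe <- 0; m },
      "dv_pop=0" = { m$dv_pop <- 0; m },
      "a_shared" = { m$a_dpe <- m$a_pop <- (m$a_dpe + m$a_pop) / 2; m },
      "t_shared" = { m$Ter_dpe <- m$Ter_pop <- (m$Ter_dpe + m$Ter_pop) / 2; m },
      stop("unknown constraint: ", cons))
  }
  m
}

# --- reparameterisation between the optimiser's free vector and the full
# --- parameter structure ----------------------------------------------------
#
# The optimiser works on an unconstrained vector whose dimension equals the
# sub-model's free parameter count M (so AIC/BIC counting and optimiser
# dimension agree).  Transforms: logistic for bias deltas (keeps
# |dB| < 0.5), log for boundary separations, St, Sz and eta (positivity),
# and log for the gap Ter - St/2 (keeps the minimum non-decision time
# nonnegative).  Drift parameters are untransformed.

.free_names <- function(spec) {
  nm <- c("dB_dpe", "dB_pop", "v0", "dv_dpe", "dv_pop",
          "a_dpe", "a_pop", "Ter_dpe", "Ter_pop", "Sz", "St", "eta")
  drop <- character(0)
  for (cons in spec$constraints) {
    drop <- c(drop, switch(cons,
      "dB_dpe=0" = "dB_dpe", "dB_pop=0" = "dB_pop",
      "dv_dpe=0" = "dv_dpe", "dv_pop=0" = "dv_pop",
      "a_shared" = "a_pop", "t_shared" = "Ter_pop"))
  }
  setdiff(nm, drop)
}

.theta_to_full <- function(theta, spec, s = 1) {
  nm <- .free_names(spec)
  stopifnot(length(theta) == length(nm))
  th <- stats::setNames(as.numeric(theta), nm)
  g <- function(name, default) if (name %in% nm) th[[name]] else default
  dB_dpe <- if ("dB_dpe" %in% nm) stats::plogis(th[["dB_dpe"]]) - 0.5 else 0
  dB_pop <- if ("dB_pop" %in% nm) stats::plogis(th[["dB_pop"]]) - 0.5 else 0
  dv_dpe <- g("dv_dpe", 0)
  dv_pop <- g("dv_pop", 0)
  v0 <- th[["v0"]]
  a_dpe <- exp(th[["a_dpe"]])
  a_pop <- if ("a_pop" %in% nm) exp(th[["a_pop"]]) else a_dpe
  Sz  <- exp(th[["Sz"]])
  St  <- exp(th[["St"]])
  eta <- exp(th[["eta"]])
  Ter_dpe <- St / 2 + exp(th[["Ter_dpe"]])
  Ter_pop <- if ("Ter_pop" %in% nm) St / 2 + exp(th[["Ter_pop"]]) else Ter_dpe
  full_model_params(dB_dpe = dB_dpe, dB_pop = dB_pop, v0 = v0,
                    dv_dpe = dv_dpe, dv_pop = dv_pop,
                    a_dpe = a_dpe, a_pop = a_pop,
                    Ter_dpe = Ter_dpe, Ter_pop = Ter_pop,
                    Sz = Sz, St = St, eta = eta, s = s)
}

.full_to_theta <- function(m, spec) {
  nm <- .free_names(spec)
  logit_delta <- function(d) stats::qlogis(min(max(d + 0.5, 1e-6), 1 - 1e-6))
  logpos <- function(x) log(max(x, 1e-8))
  vals <- c(
    dB_dpe = logit_delta(m$dB_dpe), dB_pop = logit_delta(m$dB_pop),
    v0 = m$v0, dv_dpe = m$dv_dpe, dv_pop = m$dv_pop,
    a_dpe = logpos(m$a_dpe), a_pop = logpos(m$a_pop),
    Ter_dpe = logpos(m$Ter_dpe - m$St / 2),
    Ter_pop = logpos(m$Ter_pop - m$St / 2),
    Sz = logpos(m$Sz), St = logpos(m$St), eta = logpos(m$eta))
  vals[nm]
}
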