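#' Reference full-model parameter set
#'
#' Best-fit full-model parameters for the five observers (P1-P5) of the
#' saccadic colour-oddball study that this package models, together with
#' each fit's minimised chi-square. These values serve two purposes: as
#' worked inputs for the group-level statistics (the across-subject tests
#' on the bias and drift deltas) and as realistic generating conditions
#' for synthetic studies and parameter-recovery experiments.
#'
#' The values were estimated under the fitting-toolbox convention that
#' fixes the within-trial diffusion coefficient at `s = 0.1`; they are
#' returned with that scaling (a fit or simulation at these values must
#' use `s = 0.1` to reproduce the observed ~94-100% accuracies and ~300 ms
#' latencies). See the methods vignette for the scaling discussion.
#'
#' @return A data frame with one row per parameter (`chi_square`,
#'   `dv_dpe`, `dv_pop`, `dB_dpe`, `dB_pop`, `a_dpe`, `a_pop`, `Ter_dpe`,
#'   `Ter_pop`, `v0`, `Sz`, `St`, `eta`) and one column per observer
#'   (`P1`-`P5`).
#' @examples
#' ref <- reference_parameters()
#' one_tailed_t(unlist(ref["dB_pop", ]))$p  # across-subject bias test
#' @export
reference_parameters <- function() {
  out <- data.frame(
    P1 = c(8.617, -0.0839, -0.0168, 0.1852, 0.1437, 0.0567, 0.0640,
           0.2579, 0.2466, 0.6785, 0.0000, 0.0467, 0.2083),
    P2 = c(14.928, -0.0102, 0.0017, 0.1560, 0.0960, 0.0749, 0.0759,
           0.2497, 0.2419, 0.5084, 0.0000, 0.0726, 0.0000),
    P3 = c(23.202, 0.0187, 0.0582, 0.1038, 0.0889, 0.1229, 0.0832,
           0.2313, 0.2415, 0.7754, 0.0674, 0.0490, 0.5000),
    P4 = c(3.693, 0.0798, -0.1287, -0.0517, 0.1379, 0.0749, 0.0941,
           0.3275, 0.3052, 0.5854, 0.0000, 0.0903, 0.1439),
    P5 = c(18.871, 0.0201, -0.0187, 0.0621, 0.0666, 0.0916, 0.0933,
           0.2530, 0.2537, 0.6466, 0.0623, 0.0157, 0.0000))
  rownames(out) <- c("chi_square", "dv_dpe", "dv_pop", "dB_dpe", "dB_pop",
                     "a_dpe", "a_pop", "Ter_dpe", "Ter_pop", "v0",
                     "Sz", "St", "eta")
  out
}

#' @rdname reference_parameters
#' @param subject observer id, `"P1"` to `"P5"`.
#' @param zero_drift_deltas set `dv_dpe = dv_pop = 0` (the drift-constrained
#'   generating regime used in model-recovery experiments).
#' @return `reference_full_params` returns the observer's column as a
#'   [full_model_params()] object with `s = 0.1`.
#' @export
reference_full_params <- function(subject = "P1", zero_drift_deltas = FALSE) {
  ref <- reference_parameters()
  subject <- match.arg(subject, colnames(ref))
  v <- stats::setNames(ref[[subject]], rownames(ref))
  full_model_params(
    dB_dpe = v[["dB_dpe"]], dB_pop = v[["dB_pop"]], v0 = v[["v0"]],
    dv_dpe = if (zero_drift_deltas) 0 else v[["dv_dpe"]],
    dv_pop = if (zero_drift_deltas) 0 else v[["dv_pop"]],
    a_dpe = v[["a_dpe"]], a_pop = v[["a_pop"]],
    Ter_dpe = v[["Ter_dpe"]], Ter_pop = v[["Ter_pop"]],
    Sz = v[["Sz"]], St = v[["St"]], eta = v[["eta"]], s = 0.1)
}
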