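#' Simulate single-condition diffusion trials
#'
#' Draws trial-level saccade latencies and boundary outcomes from the full
#' diffusion model: per trial, drift ~ Normal(`v`, `eta`), starting point ~
#' Uniform(`z - Sz/2`, `z + Sz/2`), non-decision time ~ Uniform(`Ter -
#' St/2`, `Ter + St/2`), then an Euler-Maruyama path to absorption. The
#' integrator applies a boundary continuity correction (boundaries pulled
#' inward by `0.5826 * s * sqrt(dt)`), which removes the leading
#' O(sqrt(dt)) overshoot bias of discrete-time first-passage simulation.
#' Reproducible under `set.seed()`.
#'
#' @param n number of trials.
#' @param p an [rdm_params()] object.
#' @param dt Euler time step in seconds (default 0.1 ms).
#' @return A data frame with columns `latency` (seconds) and `correct`
#'   (logical; `TRUE` = upper/target boundary).
#' @examples
#' set.seed(1)
#' p <- rdm_params(v = 0.6, a = 0.08, B = 0.5, Ter = 0.25, s = 0.1)
#' sim <- simulate_trials(1000, p)
#' mean(sim$correct)
#' @export
simulate_trials <- function(n, p, dt = 1e-4) {
  p <- .as_rdm(p)
  stopifnot(n >= 0, dt > 0)
  if (n == 0)
    return(data.frame(latency = numeric(0), correct = logical(0)))
  m <- cpp_simulate_trials(as.integer(n), p$v, p$a, p$B * p$a, p$Ter,
                           p$eta, p$Sz, p$St, p$s, dt)
  data.frame(latency = m[, 1], correct = m[, 2] == 1)
}

#' Generate a complete synthetic study
#'
#' The synthetic-data stage end to end: builds pseudorandom trial sequences
#' with [build_study()], classifies inter-trial conditions with
#' [classify_trials()], then simulates every labelled target-present trial
#' from the per-condition expansion of each subject's full-model
#' parameters. Target-present trials without a usable predecessor (first
#' of a block) are simulated from an unbiased parameter set (`B = 0.5`,
#' `v = v0`, POP-family boundary and non-decision time) and keep the label
#' `unlabeled`, which excludes them from fitting. Target-absent trials
#' receive Bernoulli false alarms and carry no latency.
#'
#' @param params_by_subject list of [full_model_params()] objects, one per
#'   subject (names become subject ids when given).
#' @param sessions,blocks,trials_per_block design size per subject
#'   (defaults reproduce the 1600-trial study).
#' @param false_alarm_rate probability of a saccade on a target-absent
#'   trial; scalar or one value per subject.
#' @param seed integer seed governing the whole table (sequence and
#'   diffusion noise); identical seeds give identical tables.
#' @param dt Euler step for the trial simulator, seconds.
#' @return A trial data frame with columns `subject`, `session`, `block`,
#'   `trial`, `condition`, `target_present`, `target_color`,
#'   `distractor_color`, `latency` (seconds, `NA` on absent trials),
#'   `correct` (`NA` on absent trials) and `false_alarm` (`NA` on present
#'   trials).
#' @export
generate_study <- function(params_by_subject, sessions = 5, blocks = 5,
                           trials_per_block = 64, false_alarm_rate = 0.02,
                           seed = 1, dt = 1e-4) {
  if (inherits(params_by_subject, "full_model_params"))
    params_by_subject <- list(params_by_subject)
  ok <- vapply(params_by_subject, inherits, logical(1), "full_model_params")
  if (!all(ok))
    stop("generate_study: params_by_subject must be full_model_params objects",
         call. = FALSE)
  n_subj <- length(params_by_subject)
  far <- rep_len(false_alarm_rate, n_subj)
  set.seed(seed)

  d <- build_study(n_subjects = n_subj, sessions = sessions, blocks = blocks,
                   trials_per_block = trials_per_block, seed = NULL)
  d <- classify_trials(d)
  d$latency <- NA_real_
  d$correct <- NA
  d$false_alarm <- NA

  for (si in seq_len(n_subj)) {
    m <- params_by_subject[[si]]
    rows_subj <- which(d$subject == si)
    for (cond in c(conditions(), "unlabeled")) {
      idx <- rows_subj[d$condition[rows_subj] == cond & d$target_present[rows_subj]]
      if (!length(idx)) next
      p <- if (cond == "unlabeled") {
        rdm_params(v = m$v0, a = m$a_pop, B = 0.5, Ter = m$Ter_pop,
                   eta = m$eta, Sz = min(m$Sz, m$a_pop * (1 - 1e-9)),
                   St = m$St, s = m$s)
      } else {
        expand_condition(m, cond)
      }
      sim <- simulate_trials(length(idx), p, dt = dt)
      d$latency[idx] <- sim$latency
      d$correct[idx] <- sim$correct
    }
    abs_idx <- rows_subj[!d$target_present[rows_subj]]
    d$false_alarm[abs_idx] <- stats::runif(length(abs_idx)) < far[si]
  }
  subj_names <- names(params_by_subject)
  if (!is.null(subj_names) && all(nzchar(subj_names)))
    d$subject <- subj_names[d$subject]
  d[, c("subject", "session", "block", "trial", "condition",
        "target_present", "target_color", "distractor_color",
        "latency", "correct", "false_alarm")]
}
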