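#' @title Trial-sequence generation for the paired pop-out / preview design
#' @description Helpers that emulate the study design: 32-trial sets built
#'   from eight designed condition pairs plus sixteen randomly inserted
#'   filler trials, assembled into blocks, sessions and subjects, and
#'   classified by each trial's relation to the preceding trial.
#' @name experiment-design
NULL

.colors <- c("red", "green")

.other_color <- function(color) .colors[.colors != color]

.trial_present <- function(target_color, distractor_color) {
  data.frame(target_present = TRUE, target_color = target_color,
             distractor_color = distractor_color, stringsAsFactors = FALSE)
}

.trial_absent <- function(color) {
  # target-absent display: all three items share one colour, stored as the
  # distractor colour; there is no target
  data.frame(target_present = FALSE, target_color = NA_character_,
             distractor_color = color, stringsAsFactors = FALSE)
}

#' Build one designed inter-trial pair
#'
#' Constructs the two consecutive displays that realise one inter-trial
#' condition, given the distractor colour of the second (current) trial:
#' `SRe` repeats the same target/distractor assignment, `SSw` swaps it,
#' `TP` precedes the search display with a target-absent display in the
#' current target's colour, and `DP` with one in the current distractors'
#' colour.
#'
#' @param condition one of `"SRe"`, `"SSw"`, `"TP"`, `"DP"`.
#' @param distractor_color distractor colour of the second trial, `"red"`
#'   or `"green"`.
#' @return A 2-row data frame with columns `target_present`,
#'   `target_color`, `distractor_color`.
#' @export
build_pair <- function(condition, distractor_color) {
  condition <- match.arg(condition, conditions())
  distractor_color <- match.arg(distractor_color, .colors)
  tcol <- .other_color(distractor_color)
  current <- .trial_present(tcol, distractor_color)
  first <- switch(condition,
    SRe = current,
    SSw = .trial_present(distractor_color, tcol),
    TP  = .trial_absent(tcol),
    DP  = .trial_absent(distractor_color))
  rbind(first, current)
}

#' Build one pseudorandom 32-trial set
#'
#' Eight designed pairs (four conditions crossed with two distractor
#' colours) are shuffled, then sixteen filler trials — eight target-absent
#' (four per colour) and eight target-present (four per distractor colour)
#' — are inserted uniformly at random into the nine gaps between pairs,
#' never splitting a pair. Consumes the current R RNG stream.
#'
#' @return A 32-row data frame with the trial columns of [build_pair()]
#'   plus `pair_condition` (the designed condition, `NA` for fillers) and
#'   `pair_role` (1 = first of pair, 2 = second, `NA` for fillers).
#' @export
build_set <- function() {
  grid <- expand.grid(condition = conditions(), color = .colors,
                      stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(grid)), function(i) {
    pr <- build_pair(grid$condition[i], grid$color[i])
    pr$pair_condition <- grid$condition[i]
    pr$pair_role <- c(1L, 2L)
    pr
  })
  pairs <- pairs[sample.int(length(pairs))]

  singles <- rbind(
    do.call(rbind, lapply(rep(.colors, each = 4), .trial_absent)),
    do.call(rbind, lapply(rep(.colors, each = 4), function(col)
      .trial_present(.other_color(col), col))))
  singles$pair_condition <- NA_character_
  singles$pair_role <- NA_integer_
  singles <- singles[sample.int(nrow(singles)), , drop = FALSE]
  gap <- sample(0:8, nrow(singles), replace = TRUE)

  out <- singles[gap == 0, , drop = FALSE]
  for (g in seq_along(pairs)) {
    out <- rbind(out, pairs[[g]], singles[gap == g, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Build a full multi-subject trial sequence
#'
#' Concatenates 32-trial sets into blocks, sessions and subjects. The
#' default configuration (5 sessions of 5 blocks of 64 trials) yields the
#' study size of 1600 trials per subject.
#'
#' @param n_subjects number of subjects.
#' @param sessions sessions per subject.
#' @param blocks blocks per session.
#' @param trials_per_block trials per block; must be a multiple of 32.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @return A data frame with columns `subject`, `session`, `block`,
#'   `trial` and the trial columns of [build_set()].
#' @examples
#' d <- build_study(n_subjects = 1, seed = 1)
#' nrow(d)  # 1600
#' @export
build_study <- function(n_subjects = 5, sessions = 5, blocks = 5,
                        trials_per_block = 64, seed = NULL) {
  if (trials_per_block %% 32 != 0)
    stop("build_study: trials_per_block must be a multiple of 32", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sets_per_block <- trials_per_block %/% 32
  rows <- vector("list", n_subjects * sessions * blocks * sets_per_block)
  i <- 0L
  for (subj in seq_len(n_subjects)) {
    for (sess in seq_len(sessions)) {
      for (blk in seq_len(blocks)) {
        for (k in seq_len(sets_per_block)) {
          st <- build_set()
          st$subject <- subj; st$session <- sess; st$block <- blk
          i <- i + 1L
          rows[[i]] <- st
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$trial <- stats::ave(seq_len(nrow(out)),
                          out$subject, out$session, out$block,
                          FUN = seq_along)
  rownames(out) <- NULL
  out[, c("subject", "session", "block", "trial", "target_present",
          "target_color", "distractor_color", "pair_condition", "pair_role")]
}

#' Classify each trial's inter-trial condition
#'
#' Labels every target-present trial by its relation to the immediately
#' preceding trial within the same block: same assignment `SRe`, swapped
#' assignment `SSw`, preceding target-absent display in the current
#' target's colour `TP`, in the current distractors' colour `DP`.
#' Target-absent trials are labelled `absent`; the first trial of a block
#' (no usable predecessor — a drift correction intervenes between blocks)
#' is `unlabeled` when target-present.
#'
#' @param trials a data frame as produced by [build_study()] (columns
#'   `subject`, `session`, `block`, `target_present`, `target_color`,
#'   `distractor_color`, in presentation order).
#' @return The input with a `condition` column added.
#' @export
classify_trials <- function(trials) {
  need <- c("subject", "session", "block", "target_present",
            "target_color", "distractor_color")
  if (!all(need %in% names(trials)))
    stop("classify_trials: missing columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "), call. = FALSE)
  key <- interaction(trials$subject, trials$session, trials$block, drop = TRUE)
  lab <- character(nrow(trials))
  for (idx in split(seq_len(nrow(trials)), key)) {
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (!trials$target_present[i]) { lab[i] <- "absent"; next }
      if (j == 1L) { lab[i] <- "unlabeled"; next }
      prev <- idx[j - 1L]
      if (trials$target_present[prev]) {
        lab[i] <- if (identical(trials$target_color[prev],
                                trials$target_color[i])) "SRe" else "SSw"
      } else {
        lab[i] <- if (identical(trials$distractor_color[prev],
                                trials$target_color[i])) "TP" else "DP"
      }
    }
  }
  trials$condition <- lab
  trials
}

#' Read and write trial tables as delimited text
#'
#' The on-disk dialect stores latencies in milliseconds (`latency_ms`) and
#' logical flags as 0/1; in memory latencies are in seconds.
#'
#' @param trials a trial data frame (with or without the behavioural
#'   columns `latency`, `correct`, `false_alarm`).
#' @param path file path.
#' @return `read_trials` returns the trial data frame; `write_trials`
#'   invisibly returns `path`.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  out$target_present <- as.integer(out$target_present)
  if ("latency" %in% names(out)) {
    out$latency_ms <- round(out$latency * 1000, 6)
    out$latency <- NULL
  }
  for (cl in c("correct", "false_alarm"))
    if (cl %in% names(out)) out[[cl]] <- as.integer(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  out$target_present <- out$target_present == 1
  if ("latency_ms" %in% names(out)) {
    out$latency <- out$latency_ms / 1000
    out$latency_ms <- NULL
  }
  for (cl in c("correct", "false_alarm"))
    if (cl %in% names(out)) out[[cl]] <- out[[cl]] == 1
  out
}
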