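#' @title n-back task schedule
#' @description Timing and stimulus structure of the blocked letter n-back
#'   paradigm: three load conditions (0-back, 1-back, 2-back), each presented
#'   in two blocks of 100 trials, letters drawn from an 18-consonant set,
#'   targets in exactly half of the trials of every block. The schedule drives
#'   both the BOLD simulator and GLM design construction.
#' @name task_design
NULL

NBACK_CONDITIONS <- c("0back", "1back", "2back")
#' @rdname task_design
#' @details The stimulus alphabet is the consonant set without Q, Y and J
#'   (18 letters); the 0-back target letter is X.
#' @export
NBACK_LETTERS <- setdiff(LETTERS, c("A", "E", "I", "O", "U", "Q", "Y", "J"))

#' Build an n-back task schedule
#'
#' Constructs the full trial-level timing of one run: block order is
#' semi-randomized (each condition appears once in the first half and once in
#' the second half of the run), inter-trial intervals are uniform on
#' `iti_range`, each stimulus lasts `stimulus_duration` seconds, and every
#' block contains exactly `round(target_fraction * trials_per_block)` targets.
#' Target structure is exact ground truth: a trial marked as target in the
#' n-back conditions repeats the letter presented n trials earlier (case is
#' ignored), and non-target letters are constrained never to satisfy the rule
#' accidentally.
#'
#' @param seed integer seed; identical seeds give identical schedules.
#' @param trials_per_block trials in each block (default 100).
#' @param blocks_per_condition number of blocks per load condition (default 2).
#' @param target_fraction fraction of target trials per block (default 0.5,
#'   enforced as an exact count).
#' @param stimulus_duration stimulus presentation time in seconds.
#' @param iti_range inter-stimulus interval range in seconds (uniform).
#' @param rest_duration rest/instruction period before each block and after
#'   the last one, seconds.
#' @param tr_seconds repetition time of the accompanying scan, seconds.
#' @return an object of class `task_schedule`: list with `blocks`
#'   (block-level onsets/durations), `trials` (trial-level onsets, letters,
#'   case, target flags), `tr_seconds`, `n_scans`.
#' @export
build_schedule <- function(seed = 1L,
                           trials_per_block = 100L,
                           blocks_per_condition = 2L,
                           target_fraction = 0.5,
                           stimulus_duration = 0.5,
                           iti_range = c(1, 2),
                           rest_duration = 20,
                           tr_seconds = 2) {
  stopifnot(trials_per_block >= 1, blocks_per_condition >= 1,
            target_fraction >= 0, target_fraction <= 1,
            stimulus_duration > 0, length(iti_range) == 2,
            iti_range[1] <= iti_range[2], iti_range[1] >= 0,
            rest_duration >= 0, tr_seconds > 0)
  n_targets <- round(target_fraction * trials_per_block)

  with_substream(seed, "schedule", expr = {
    # each condition once per half of the run ("semi-randomized")
    order <- character(0)
    for (half in seq_len(blocks_per_condition)) {
      order <- c(order, sample(NBACK_CONDITIONS))
    }

    blocks <- list()
    trials <- list()
    t_cursor <- rest_duration
    for (b in seq_along(order)) {
      cond <- order[b]
      nback <- match(cond, NBACK_CONDITIONS) - 1L
      itis <- stats::runif(trials_per_block, iti_range[1], iti_range[2])
      rel_onsets <- cumsum(c(0, (stimulus_duration + itis)[-trials_per_block]))
      block_dur <- rel_onsets[trials_per_block] + stimulus_duration +
        itis[trials_per_block]

      tt <- make_block_trials(nback, trials_per_block, n_targets)
      trials[[b]] <- data.frame(
        block = b, condition = cond, trial = seq_len(trials_per_block),
        onset = t_cursor + rel_onsets, duration = stimulus_duration,
        letter = tt$letter,
        case = sample(c("upper", "lower"), trials_per_block, replace = TRUE),
        is_target = tt$is_target,
        stringsAsFactors = FALSE)
      blocks[[b]] <- data.frame(block = b, condition = cond,
                                onset = t_cursor, duration = block_dur,
                                stringsAsFactors = FALSE)
      t_cursor <- t_cursor + block_dur + rest_duration
    }
    out <- list(blocks = do.call(rbind, blocks),
                trials = do.call(rbind, trials),
                tr_seconds = tr_seconds,
                n_scans = as.integer(ceiling(t_cursor / tr_seconds)))
    class(out) <- "task_schedule"
    out
  })
}

# Letter stream + target placement for one block. Targets are sampled
# exactly (no binomial jitter) from the positions where an n-back referent
# exists; non-target letters must differ from the referent so is_target is
# the unique ground truth.
make_block_trials <- function(nback, n_trials, n_targets) {
  eligible <- if (nback == 0L) seq_len(n_trials) else seq_len(n_trials)[-seq_len(nback)]
  if (n_targets > length(eligible)) {
    stop("infeasible target placement: ", n_targets, " targets requested but only ",
         length(eligible), " trials have an ", nback, "-back referent")
  }
  is_target <- rep(FALSE, n_trials)
  is_target[sample(eligible, n_targets)] <- TRUE
  letter <- character(n_trials)
  for (i in seq_len(n_trials)) {
    referent <- if (nback == 0L) "X" else if (i > nback) letter[i - nback] else NA_character_
    if (is_target[i]) {
      letter[i] <- referent
    } else {
      pool <- NBACK_LETTERS
      if (!is.na(referent)) pool <- setdiff(pool, referent)
      if (nback != 0L) pool <- setdiff(pool, "X")  # keep X unambiguous
      letter[i] <- sample(pool, 1)
    }
  }
  list(letter = letter, is_target = is_target)
}

#' Per-condition event onsets for design construction
#'
#' Returns, for each load condition, the trial onsets and durations used as
#' GLM events. All trials are included: events on trials later answered
#' incorrectly are deliberately not excluded.
#'
#' @param schedule a `task_schedule`.
#' @return named list (`0back`, `1back`, `2back`) of data frames with columns
#'   `onset` and `duration` (seconds from run start).
#' @export
condition_onsets <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  out <- lapply(NBACK_CONDITIONS, function(cond) {
    tr <- schedule$trials[schedule$trials$condition == cond, , drop = FALSE]
    data.frame(onset = as.numeric(tr$onset), duration = as.numeric(tr$duration))
  })
  names(out) <- NBACK_CONDITIONS
  out
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("n-back task schedule:", nrow(x$blocks), "blocks,",
      nrow(x$trials), "trials,", sum(x$trials$is_target), "targets\n")
  cat("  TR", x$tr_seconds, "s,", x$n_scans, "scans, run length",
      round(x$n_scans * x$tr_seconds), "s\n")
  invisible(x)
}
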