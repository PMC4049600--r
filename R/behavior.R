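#' Mark invalid-RT trials as incorrect
#'
#' Responses faster than 200 ms or slower than 1500 ms are considered
#' incorrect; the boundary values themselves are valid. Trials are never
#' dropped — only their correctness flag changes — so accuracy denominators
#' are unaffected. Missing RTs (non-responses) are treated as incorrect.
#'
#' @param trials behavioral trial data frame with columns `subject`,
#'   `condition`, `rt_ms`, `correct`.
#' @param rt_min,rt_max valid RT range in ms (inclusive).
#' @return the input with added logical columns `rt_valid` and
#'   `correct_filtered` (= `correct` AND `rt_valid`).
#' @export
filter_trials <- function(trials, rt_min = 200, rt_max = 1500) {
  required_columns(trials, c("subject", "condition", "rt_ms", "correct"),
                   "trials")
  if (any(trials$rt_ms < 0, na.rm = TRUE)) {
    stop("negative RT in trial table")
  }
  trials$rt_valid <- !is.na(trials$rt_ms) &
    trials$rt_ms >= rt_min & trials$rt_ms <= rt_max
  trials$correct_filtered <- as.integer(trials$correct == 1 & trials$rt_valid)
  trials
}

#' Per-subject behavioral summary
#'
#' Accuracy is the rate of (filtered) correct responses over all trials of a
#' condition; the RT summary is the median over correct valid trials. A
#' subject with zero correct trials in some condition has an undefined median
#' there and is flagged (or, with `on_empty = "error"`, aborts the summary).
#'
#' @param trials trial table; passed through [filter_trials()] if the
#'   validity flags are absent.
#' @param on_empty `"flag"` (default) or `"error"`: what to do when a
#'   condition has no correct valid trials.
#' @return object of class `behavior_summary`: list with `by_condition`
#'   (subject x condition accuracy and median RT) and `by_subject`
#'   (group, flags; cost columns added by [cost_indices()]).
#' @export
summarize_behavior <- function(trials, on_empty = c("flag", "error")) {
  on_empty <- match.arg(on_empty)
  if (is.null(trials$correct_filtered)) trials <- filter_trials(trials)
  if (nrow(trials) == 0) {
    empty <- data.frame(subject = character(0), group = character(0),
                        condition = character(0), n_trials = integer(0),
                        accuracy = numeric(0), median_rt = numeric(0))
    return(structure(list(by_condition = empty,
                          by_subject = data.frame(subject = character(0),
                                                  group = character(0),
                                                  flagged = logical(0),
                                                  flag_reason = character(0))),
                     class = "behavior_summary"))
  }
  grp <- if (!is.null(trials$group)) trials$group else NA_character_
  key <- interaction(trials$subject, trials$condition, drop = TRUE)
  split_idx <- split(seq_len(nrow(trials)), key)
  by_condition <- do.call(rbind, lapply(split_idx, function(ix) {
    tt <- trials[ix, , drop = FALSE]
    ok <- tt$correct_filtered == 1
    data.frame(subject = tt$subject[1],
               group = if (!is.null(tt$group)) tt$group[1] else NA_character_,
               condition = tt$condition[1],
               n_trials = nrow(tt),
               accuracy = mean(ok),
               median_rt = if (any(ok)) stats::median(tt$rt_ms[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(by_condition) <- NULL
  no_correct <- by_condition$subject[is.na(by_condition$median_rt)]
  if (length(no_correct) > 0 && on_empty == "error") {
    stop("no correct trials for subject(s) ",
         paste(unique(no_correct), collapse = ", "),
         " in some condition; median RT undefined")
  }
  subj <- unique(by_condition[, c("subject", "group")])
  subj$flagged <- subj$subject %in% no_correct
  subj$flag_reason <- ifelse(subj$flagged, "no_correct_trials", "")
  rownames(subj) <- NULL
  structure(list(by_condition = by_condition, by_subject = subj),
            class = "behavior_summary")
}

#' Speed and accuracy cost indices
#'
#' The working-memory performance indices contrasting the most demanding
#' load with baseline: `speed_cost = (RT_2back - RT_0back) / RT_0back` and
#' `accuracy_cost = (acc_0back - acc_2back) / acc_0back`. Higher values mean
#' less efficient performance. Both are unitless, hence invariant to the RT
#' unit.
#'
#' @param summary a `behavior_summary`, or a data frame shaped like its
#'   `by_condition` element.
#' @return the `behavior_summary` with `speed_cost` and `accuracy_cost`
#'   columns added to `by_subject`; for a plain data-frame input, the
#'   per-subject cost data frame itself.
#' @export
cost_indices <- function(summary) {
  bc <- if (inherits(summary, "behavior_summary")) summary$by_condition else summary
  required_columns(bc, c("subject", "condition", "accuracy", "median_rt"),
                   "by-condition summary")
  wide <- function(col) {
    w0 <- bc[bc$condition == "0back", c("subject", col)]
    w2 <- bc[bc$condition == "2back", c("subject", col)]
    merge(w0, w2, by = "subject", suffixes = c("_0", "_2"))
  }
  rt <- wide("median_rt"); acc <- wide("accuracy")
  if (any(!is.na(rt$median_rt_0) & rt$median_rt_0 <= 0) ||
      any(acc$accuracy_0 <= 0)) {
    stop("zero 0-back denominator: cost indices undefined")
  }
  costs <- data.frame(subject = rt$subject,
                      speed_cost = (rt$median_rt_2 - rt$median_rt_0) / rt$median_rt_0,
                      accuracy_cost = (acc$accuracy_0 - acc$accuracy_2) / acc$accuracy_0,
                      stringsAsFactors = FALSE)
  if (!inherits(summary, "behavior_summary")) return(costs)
  summary$by_subject <- merge(summary$by_subject, costs, by = "subject",
                              sort = TRUE)
  summary
}

#' Scalar cost indices from condition-level values
#'
#' Convenience form of the cost formulas for two RT or accuracy values,
#' e.g. group means.
#'
#' @param rt0,rt2 RT in the 0-back and 2-back conditions (any unit).
#' @param acc0,acc2 accuracy proportions.
#' @return named numeric vector with `speed_cost` and `accuracy_cost`.
#' @export
cost_from_means <- function(rt0, rt2, acc0, acc2) {
  if (rt0 <= 0 || acc0 <= 0) stop("zero or negative 0-back denominator")
  c(speed_cost = (rt2 - rt0) / rt0, accuracy_cost = (acc0 - acc2) / acc0)
}

#' Apply performance-based exclusions
#'
#' Excludes subjects performing below chance (accuracy < 0.5) in the memory
#' conditions. The default, conservative reading excludes on below-chance
#' performance in *either* the 1-back or the 2-back condition; `rule =
#' "both"` requires below-chance performance in both. Boundary accuracy of
#' exactly 0.5 is retained. Subjects already flagged (undefined median) are
#' excluded too, with their own reason.
#'
#' @param summary a `behavior_summary` (costs optional).
#' @param rule `"either"` (default) or `"both"`.
#' @param threshold chance-level accuracy (default 0.5, strict inequality).
#' @return list with `included` (subject data frame), `excluded`, and
#'   `log` (one row per exclusion with the rule that fired).
#' @export
apply_exclusions <- function(summary, rule = c("either", "both"),
                             threshold = 0.5) {
  rule <- match.arg(rule)
  stopifnot(inherits(summary, "behavior_summary"))
  bc <- summary$by_condition
  subj <- summary$by_subject
  if (nrow(subj) == 0) {
    return(list(included = subj, excluded = subj,
                log = data.frame(subject = character(0), rule = character(0))))
  }
  acc_of <- function(s, cond) {
    v <- bc$accuracy[bc$subject == s & bc$condition == cond]
    if (length(v) == 0) NA_real_ else v[1]
  }
  log <- list()
  drop <- logical(nrow(subj))
  for (i in seq_len(nrow(subj))) {
    s <- subj$subject[i]
    a1 <- acc_of(s, "1back"); a2 <- acc_of(s, "2back")
    below <- c(`1back` = isTRUE(a1 < threshold), `2back` = isTRUE(a2 < threshold))
    hit <- if (rule == "either") any(below) else all(below)
    if (isTRUE(subj$flagged[i])) {
      drop[i] <- TRUE
      log[[length(log) + 1L]] <- data.frame(subject = s, rule = subj$flag_reason[i])
    } else if (hit) {
      drop[i] <- TRUE
      log[[length(log) + 1L]] <- data.frame(
        subject = s,
        rule = paste0("below_chance_", paste(names(below)[below], collapse = "_")))
    }
  }
  list(included = subj[!drop, , drop = FALSE],
       excluded = subj[drop, , drop = FALSE],
       log = if (length(log)) do.call(rbind, log) else
         data.frame(subject = character(0), rule = character(0)))
}

required_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}
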