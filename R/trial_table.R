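#' Canonical trial-history context labels
#'
#' The four combinations of the previous completed trial's choice and outcome,
#' in the fixed order used throughout the package (behavioral GLM regressors,
#' decoder classes, encoding-model kernel groups).
#'
#' @return Character vector of length 4.
#' @export
history_contexts <- function() {
  c("prev_correct_left", "prev_incorrect_left",
    "prev_incorrect_right", "prev_correct_right")
}

#' Stimulus rates used in the rate-discrimination task
#'
#' Event rates (events/s) presented during the 1-s stimulus train. The 12 Hz
#' category boundary itself is never presented; rates below 12 are "low"
#' (rewarded at the left port), rates above 12 are "high" (right port).
#'
#' @return Integer vector of the 8 admissible rates.
#' @export
stimulus_rates <- function() c(4L, 6L, 8L, 10L, 14L, 16L, 18L, 20L)

#' Rate category boundary (Hz)
#' @keywords internal
RATE_BOUNDARY <- 12

.trial_table_required <- c(
  "trial_index", "stimulus_rate_hz", "category", "choice", "outcome",
  "completed", "t_init", "t_stim_onset", "t_go_cue", "t_center_exit",
  "t_choice_report", "t_outcome_end"
)

#' Validate a trial table
#'
#' Checks the column schema and the structural invariants of a per-trial
#' event table: the outcome rule (correct iff the choice matches the rate
#' category), event-time ordering for completed trials, and stimulus-train
#' timing constraints (15 ms events separated by at least 25 ms within 1 s).
#'
#' @param table Data frame with one row per trial. Required columns:
#'   `trial_index`, `stimulus_rate_hz`, `category` (`"low"`/`"high"`),
#'   `choice` (`"left"`/`"right"`/`"none"`), `outcome`
#'   (`"correct"`/`"incorrect"`/`"undefined"`), `completed` (logical), and
#'   session-clock event times `t_init`, `t_stim_onset`, `t_go_cue`,
#'   `t_center_exit`, `t_choice_report`, `t_outcome_end` (seconds; NA where
#'   the event did not occur). An optional list column `stimulus_events`
#'   holds event onsets in seconds relative to stimulus onset.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_trial_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("trial table is empty: no trials to analyze")
  missing <- setdiff(.trial_table_required, names(table))
  if (length(missing))
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (is.unsorted(table$trial_index, strictly = TRUE))
    stop("trial_index must be strictly increasing")
  bad_rate <- !table$stimulus_rate_hz %in% stimulus_rates()
  if (any(bad_rate))
    stop("invalid stimulus_rate_hz (12 Hz and off-grid rates are not used): ",
         paste(unique(table$stimulus_rate_hz[bad_rate]), collapse = ", "))
  expect_cat <- ifelse(table$stimulus_rate_hz < RATE_BOUNDARY, "low", "high")
  if (!identical(as.character(table$category), expect_cat))
    stop("category must be 'low' iff stimulus_rate_hz < 12")
  done <- which(table$completed)
  if (length(done)) {
    ch <- table$choice[done]; oc <- table$outcome[done]
    cat_ <- table$category[done]
    expect_oc <- ifelse((cat_ == "high" & ch == "right") |
                          (cat_ == "low" & ch == "left"),
                        "correct", "incorrect")
    if (!identical(as.character(oc), expect_oc))
      stop("outcome rule violated: correct iff choice matches rate category")
    tm <- table[done, c("t_init", "t_stim_onset", "t_go_cue",
                        "t_center_exit", "t_choice_report", "t_outcome_end")]
    ok <- tm$t_init < tm$t_stim_onset & tm$t_stim_onset < tm$t_go_cue &
      tm$t_go_cue <= tm$t_center_exit & tm$t_center_exit <= tm$t_choice_report &
      tm$t_choice_report <= tm$t_outcome_end
    if (any(!ok | is.na(ok)))
      stop("event times out of order for completed trial(s): ",
           paste(utils::head(table$trial_index[done][!ok | is.na(ok)], 5),
                 collapse = ", "))
  }
  if (!is.null(table$stimulus_events)) {
    for (ev in table$stimulus_events) {
      if (length(ev) == 0L) next
      if (any(ev < 0) || any(ev > 1 - 0.015))
        stop("stimulus events must lie within the 1-s train")
      if (length(ev) > 1L && any(diff(sort(ev)) < 0.040 - 1e-12))
        stop("stimulus event onsets must be separated by >= 40 ms ",
             "(15 ms event + 25 ms gap)")
    }
  }
  invisible(table)
}

#' Label each trial with its trial-history context
#'
#' Trial `t` is labeled by the choice and outcome of trial `t - 1` when that
#' trial was completed; the first trial and trials preceded by an early
#' withdrawal or no-choice trial are `"undefined"`. Only trials with a
#' defined context enter the decoding and encoding analyses.
#'
#' @param table Trial table sorted by `trial_index` (see
#'   [validate_trial_table()]).
#' @return Factor of length `nrow(table)` with levels
#'   `c(history_contexts(), "undefined")`.
#' @export
derive_history_context <- function(table) {
  if (is.null(table) || !is.data.frame(table) || nrow(table) == 0L)
    stop("trial table is empty: no trials to label")
  if (is.unsorted(table$trial_index, strictly = TRUE))
    stop("trial table must be sorted by trial_index")
  n <- nrow(table)
  lab <- rep("undefined", n)
  if (n > 1L) {
    prev_done <- table$completed[-n]
    prev_ch <- as.character(table$choice[-n])
    prev_oc <- as.character(table$outcome[-n])
    idx <- which(prev_done) + 1L
    lab[idx] <- paste0("prev_", prev_oc[idx - 1L], "_", prev_ch[idx - 1L])
  }
  factor(lab, levels = c(history_contexts(), "undefined"))
}
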