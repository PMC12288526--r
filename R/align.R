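#' Canonical trial-phase windows
#'
#' The four analysis windows that tile a trial, each anchored on a behavioral
#' event and expressed as a half-open interval `[pre, post)` in seconds
#' relative to the anchor:
#'
#' * `early_iti`: the second after the previous trial's choice report
#'   (`prev_choice_report`, 0 to +1.0 s);
#' * `late_iti`: 1 s before until 0.3 s after the end of the previous trial's
#'   outcome (`prev_outcome_end`, -1.0 to +0.3 s);
#' * `stimulus`: 0.5 s before to 1 s after stimulus onset;
#' * `action`: 0.2 s before to 0.3 s after the center-port exit.
#'
#' At 30 frames/s these windows contribute 30, 39, 45 and 15 timepoints.
#'
#' @return Data frame with columns `phase`, `anchor_event`, `pre`, `post`.
#' @export
phase_windows <- function() {
  data.frame(
    phase = c("early_iti", "late_iti", "stimulus", "action"),
    anchor_event = c("prev_choice_report", "prev_outcome_end",
                     "stim_onset", "center_exit"),
    pre = c(0, -1.0, -0.5, -0.2),
    post = c(1.0, 0.3, 1.0, 0.3),
    stringsAsFactors = FALSE
  )
}

.anchor_times <- function(table, anchor_event) {
  n <- nrow(table)
  prev <- function(x) c(NA_real_, x[-n])
  switch(anchor_event,
    init = table$t_init,
    stim_onset = table$t_stim_onset,
    go_cue = table$t_go_cue,
    center_exit = table$t_center_exit,
    choice_report = table$t_choice_report,
    outcome_end = table$t_outcome_end,
    prev_choice_report = prev(table$t_choice_report),
    prev_outcome_end = prev(table$t_outcome_end),
    stop("unknown anchor event: ", anchor_event)
  )
}

#' Number of frames in a phase window
#' @param window One row of [phase_windows()] (or a list with `pre`, `post`).
#' @param frame_rate Frames per second.
#' @return Integer frame count, `round((post - pre) * frame_rate)`.
#' @export
window_timepoints <- function(window, frame_rate = 30) {
  as.integer(round((window$post - window$pre) * frame_rate))
}

#' Align neural activity to a trial-phase window
#'
#' Extracts, for every usable trial, the activity snippet around the window's
#' anchor event on the neural frame grid. Anchor times are snapped to the
#' nearest frame; the window is half-open `[pre, post)` so a 1-s window at
#' 30 Hz yields exactly 30 timepoints. Trials are dropped (with a warning,
#' never an error) when the anchor is missing, the window runs past the
#' recording bounds, or (by default) the trial lacks a defined trial-history
#' context.
#'
#' @param session Neural session: a list with `activity` (neurons x frames
#'   matrix) and `frame_rate`.
#' @param table Trial table (see [validate_trial_table()]).
#' @param window One row of [phase_windows()], or a list with `phase`,
#'   `anchor_event`, `pre`, `post`.
#' @param drop_undefined Drop trials that are not completed or whose
#'   trial-history context is undefined (default `TRUE`).
#' @return List of class `"aligned_activity"` with `tensor`
#'   (trials x neurons x timepoints), `time_offsets` (seconds relative to the
#'   anchor), `phase`, `included_trial_indices`, `context` (factor for the
#'   included trials) and `dropped_trial_indices`.
#' @export
align_activity <- function(session, table, window, drop_undefined = TRUE) {
  stopifnot(is.matrix(session$activity))
  fr <- session$frame_rate
  n_frames <- ncol(session$activity)
  n_tp <- window_timepoints(window, fr)
  anchors <- .anchor_times(table, window$anchor_event)
  ctx <- derive_history_context(table)

  keep <- rep(TRUE, nrow(table))
  if (drop_undefined) keep <- table$completed & ctx != "undefined"
  keep <- keep & !is.na(anchors)
  start <- as.integer(round(anchors * fr) + round(window$pre * fr)) # 0-based
  in_bounds <- !is.na(start) & start >= 0L & (start + n_tp - 1L) <= n_frames - 1L
  dropped <- table$trial_index[keep & !in_bounds]
  if (length(dropped))
    warning(sprintf("align_activity(%s): dropped %d trial(s) outside recording bounds",
                    window$phase, length(dropped)))
  keep <- keep & in_bounds

  idx <- which(keep)
  n_neur <- nrow(session$activity)
  tensor <- array(NA_real_, dim = c(length(idx), n_neur, n_tp))
  for (i in seq_along(idx)) {
    fr0 <- start[idx[i]]
    tensor[i, , ] <- session$activity[, (fr0 + 1L):(fr0 + n_tp), drop = FALSE]
  }
  structure(list(
    tensor = tensor,
    time_offsets = window$pre + (seq_len(n_tp) - 1L) / fr,
    phase = window$phase,
    included_trial_indices = table$trial_index[idx],
    context = factor(as.character(ctx[idx]),
                     levels = if (drop_undefined) history_contexts()
                              else c(history_contexts(), "undefined")),
    dropped_trial_indices = dropped
  ), class = "aligned_activity")
}

#' Align activity to all four canonical phases and concatenate
#'
#' Runs [align_activity()] for every window and concatenates the snippets
#' along the time axis, keeping only trials usable in every phase, so that
#' each included trial contributes one row of the full trial-time grid
#' (129 timepoints at the canonical windows and 30 Hz).
#'
#' @inheritParams align_activity
#' @param windows Data frame of windows, default [phase_windows()].
#' @return List of class `"aligned_activity"` with the concatenated `tensor`,
#'   `timepoint_phase` and `time_offsets` labels per timepoint, `context`,
#'   and `included_trial_indices`.
#' @export
align_phases <- function(session, table, windows = phase_windows(),
                         drop_undefined = TRUE) {
  parts <- lapply(seq_len(nrow(windows)), function(i)
    align_activity(session, table, windows[i, ], drop_undefined = drop_undefined))
  common <- Reduce(intersect, lapply(parts, `[[`, "included_trial_indices"))
  if (length(common) == 0L) stop("no trials usable in every phase")
  tensors <- lapply(parts, function(p) {
    sel <- match(common, p$included_trial_indices)
    p$tensor[sel, , , drop = FALSE]
  })
  tensor <- array(NA_real_, dim = c(length(common), dim(tensors[[1]])[2],
                                    sum(vapply(tensors, function(x) dim(x)[3], 1L))))
  off <- 0L
  for (tns in tensors) {
    tensor[, , off + seq_len(dim(tns)[3])] <- tns
    off <- off + dim(tns)[3]
  }
  ctx <- derive_history_context(table)
  structure(list(
    tensor = tensor,
    timepoint_phase = rep(windows$phase,
                          vapply(parts, function(p) length(p$time_offsets), 1L)),
    time_offsets = unlist(lapply(parts, `[[`, "time_offsets")),
    included_trial_indices = common,
    context = factor(as.character(ctx[match(common, table$trial_index)]),
                     levels = if (drop_undefined) history_contexts()
                              else c(history_contexts(), "undefined"))
  ), class = "aligned_activity")
}

#' Smooth activity traces with a Gaussian kernel
#'
#' Convolves each neuron's trace with a unit-area Gaussian kernel (truncated
#' at 4 standard deviations and renormalized), the standard preprocessing
#' for inferred event-rate signals before decoding. Zero padding is used at
#' the edges, so per-neuron totals are conserved for interior-supported
#' signals.
#'
#' @param activity Neurons x frames matrix.
#' @param sd_frames Kernel standard deviation in frames (default 1).
#' @return Matrix of the same dimensions.
#' @export
smooth_rates <- function(activity, sd_frames = 1) {
  stopifnot(is.matrix(activity), sd_frames > 0)
  if (any(!is.finite(activity))) stop("activity contains non-finite values")
  half <- max(1L, ceiling(4 * sd_frames))
  k <- stats::dnorm(seq(-half, half), sd = sd_frames)
  k <- k / sum(k)
  out <- activity
  nf <- ncol(activity)
  for (i in seq_len(nrow(activity))) {
    padded <- c(numeric(half), activity[i, ], numeric(half))
    sm <- stats::filter(padded, k, method = "convolution", sides = 2)
    out[i, ] <- sm[(half + 1L):(half + nf)]
  }
  out
}
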