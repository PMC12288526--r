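#' Configuration of the encoding-model design matrix
#'
#' Controls the regressor groups assembled by [build_design_matrix()]:
#' the trial-time grid (phase windows at the neural frame rate), event-kernel
#' spans, occupancy-bin sizes and the number of analog video components.
#' Defaults follow the full analysis configuration: stimulus-event kernels up
#' to 0.5 s after each event, port-poke kernels from 0.5 s before to 1 s
#' after each poke, 60 bins of 6 degrees per head-orientation angle, a
#' 1.28 cm square chest-position grid over the arena, and the top 200 video
#' and motion-energy components (orthogonalized against the stimulus
#' columns). Tests and demos use reduced configurations.
#'
#' @param windows Phase-window data frame, default [phase_windows()].
#' @param frame_rate Frames per second.
#' @param stim_kernel_span Stimulus-event kernel span after the event (s).
#' @param stim_repeat Include the repeated stimulus train 1 s after onset.
#' @param poke_kernel Port-poke kernel span `c(pre, post)` in seconds.
#' @param head_angle_bin_deg Head-angle bin width (degrees; 360 must be a
#'   multiple).
#' @param chest_bin_cm Chest-position bin side (cm).
#' @param arena_cm Arena size (cm).
#' @param n_video,n_motion Number of analog video / motion-energy components.
#' @param orthogonalize Orthogonalize analog components against the stimulus
#'   columns (QR), default `TRUE`.
#' @return List of class `"design_config"`.
#' @export
design_config <- function(windows = phase_windows(), frame_rate = 30,
                          stim_kernel_span = 0.5, stim_repeat = TRUE,
                          poke_kernel = c(-0.5, 1), head_angle_bin_deg = 6,
                          chest_bin_cm = 1.28, arena_cm = c(20, 20),
                          n_video = 200, n_motion = 200,
                          orthogonalize = TRUE) {
  stopifnot(360 %% head_angle_bin_deg == 0)
  structure(list(windows = windows, frame_rate = frame_rate,
                 stim_kernel_span = stim_kernel_span, stim_repeat = stim_repeat,
                 poke_kernel = poke_kernel,
                 head_angle_bin_deg = head_angle_bin_deg,
                 chest_bin_cm = chest_bin_cm, arena_cm = arena_cm,
                 n_video = n_video, n_motion = n_motion,
                 orthogonalize = orthogonalize),
            class = "design_config")
}

#' Column counts of every regressor group for a configuration
#' @param config [design_config()].
#' @return Named integer vector of group sizes, in design-matrix order.
#' @export
design_group_sizes <- function(config) {
  fr <- config$frame_rate
  n_tp <- sum(vapply(seq_len(nrow(config$windows)), function(i)
    window_timepoints(config$windows[i, ], fr), 1L))
  n_stim <- as.integer(round(config$stim_kernel_span * fr)) + 1L
  poke_shifts <- seq(as.integer(round(config$poke_kernel[1] * fr)),
                     as.integer(round(config$poke_kernel[2] * fr)))
  n_ha <- as.integer(360 / config$head_angle_bin_deg)
  n_chest <- as.integer(ceiling(config$arena_cm[1] / config$chest_bin_cm)) *
    as.integer(ceiling(config$arena_cm[2] / config$chest_bin_cm))
  sizes <- c(trial_time = n_tp, choice = n_tp, outcome = n_tp,
             stats::setNames(rep(n_tp, 4L), paste0("hist_", history_contexts())),
             stimulus = n_stim,
             poke_center = length(poke_shifts), poke_left = length(poke_shifts),
             poke_right = length(poke_shifts),
             head_yaw = n_ha, head_pitch = n_ha, head_roll = n_ha,
             chest = n_chest, video = config$n_video, motion = config$n_motion)
  sizes[sizes > 0L]
}

#' Default mapping from reported variables to design groups
#'
#' Variance partitioning shuffles or retains regressors at the level of task
#' variables: trial history spans its four context kernel groups, port pokes
#' span the three ports, and head angle spans the three orientation angles.
#' @param groups Character vector of group names present in a design matrix.
#' @return Named list mapping variable names to group-name vectors.
#' @export
variable_groups <- function(groups) {
  full <- list(
    choice = "choice", outcome = "outcome",
    trial_history = paste0("hist_", history_contexts()),
    stimulus = "stimulus",
    pokes = c("poke_center", "poke_left", "poke_right"),
    head_angle = c("head_yaw", "head_pitch", "head_roll"),
    chest = "chest", video = "video", motion = "motion"
  )
  out <- lapply(full, intersect, groups)
  out[vapply(out, length, 1L) > 0L]
}

#' Orthogonalize analog columns against stimulus columns
#'
#' Projects the analog regressors onto the orthogonal complement of the
#' column space of the stimulus regressors via QR decomposition, so the
#' returned columns carry no stimulus-locked signal. Rank-deficient stimulus
#' columns are dropped from the projection basis with a warning.
#'
#' @param analog Numeric matrix (rows x k).
#' @param stim Numeric matrix (rows x m) spanning the stimulus space.
#' @return Matrix of the same shape as `analog`, orthogonal to `stim`.
#' @export
orthogonalize_against <- function(analog, stim) {
  analog <- as.matrix(analog); stim <- as.matrix(stim)
  keep <- colSums(abs(stim)) > 0
  if (!all(keep)) stim <- stim[, keep, drop = FALSE]
  if (ncol(stim) == 0L) return(analog)
  qrd <- qr(stim)
  if (qrd$rank < ncol(stim))
    warning(sprintf("dropping %d linearly dependent stimulus column(s) before orthogonalization",
                    ncol(stim) - qrd$rank))
  Q <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
  analog - Q %*% (crossprod(Q, analog))
}

#' Assemble a design matrix from trials, neural frames and tracking
#'
#' Builds the encoding-model design matrix over the concatenated trial-time
#' grid (the four phase windows at the neural frame rate). Rows are
#' trial x timepoint samples for every trial with a defined trial-history
#' context whose windows lie within the recording. Column groups:
#'
#' * `trial_time`: one indicator per timepoint, shared across trials -- the
#'   time-varying intercept;
#' * `choice` / `outcome`: the same indicators gated by the current trial's
#'   right choice / correct outcome (full-trial-span kernels);
#' * `hist_*`: four full-span kernel groups, one per trial-history context;
#' * `stimulus`: time-shifted copies of the binary stimulus-event vector
#'   covering 0 to `stim_kernel_span` s after each event;
#' * `poke_center`/`poke_left`/`poke_right`: shifted event kernels around
#'   port pokes (`poke_kernel` span);
#' * `head_yaw`/`head_pitch`/`head_roll`: one-hot occupancy over angle bins;
#' * `chest`: one-hot occupancy over the spatial grid (row-major from the
#'   arena origin, half-open bins); frames with missing tracking give
#'   all-zero occupancy rows (counted and reported);
#' * `video` / `motion`: analog surrogate SVD component time courses,
#'   orthogonalized against the stimulus columns when configured.
#'
#' @param table Trial table.
#' @param session Neural session (for frame bounds; a list with `activity`
#'   and `frame_rate`).
#' @param tracking Tracking streams from [simulate_tracking()] (or `NULL`
#'   to omit occupancy and analog groups).
#' @param config [design_config()].
#' @return Object of class `"design_matrix"`: list with dense matrix `X`,
#'   `groups` (named list of column indices), `variables`
#'   (see [variable_groups()]), `trial_id`, `timepoint` and `frame` per row,
#'   `timepoint_phase`/`time_offsets` labels, `context` per included trial,
#'   and `n_zero_occupancy`.
#' @export
build_design_matrix <- function(table, session, tracking = NULL,
                                config = design_config()) {
  fr <- config$frame_rate
  n_frames <- ncol(session$activity)
  ctx <- derive_history_context(table)
  win <- config$windows
  n_tp_w <- vapply(seq_len(nrow(win)), function(i)
    window_timepoints(win[i, ], fr), 1L)
  n_tp <- sum(n_tp_w)

  # per-trial frame grid; drop trials with undefined context or out-of-bounds
  anchors <- lapply(win$anchor_event, function(a) .anchor_times(table, a))
  keep <- table$completed & ctx != "undefined"
  frames_tr <- vector("list", nrow(table))
  for (t in which(keep)) {
    fs <- integer(0); ok <- TRUE
    for (w in seq_len(nrow(win))) {
      a <- anchors[[w]][t]
      if (is.na(a)) { ok <- FALSE; break }
      f0 <- as.integer(round(a * fr) + round(win$pre[w] * fr))
      if (f0 < 0L || f0 + n_tp_w[w] > n_frames) { ok <- FALSE; break }
      fs <- c(fs, f0 + seq_len(n_tp_w[w]) - 1L)
    }
    if (ok) frames_tr[[t]] <- fs else keep[t] <- FALSE
  }
  trials <- which(keep)
  if (!length(trials)) stop("no trials usable for the design matrix")
  n_trials <- length(trials)
  rows <- n_trials * n_tp
  trial_id <- rep(table$trial_index[trials], each = n_tp)
  timepoint <- rep(seq_len(n_tp), times = n_trials)
  frame <- unlist(frames_tr[trials], use.names = FALSE)

  sizes <- design_group_sizes(config)
  if (is.null(tracking))
    sizes <- sizes[!names(sizes) %in%
                     c("head_yaw", "head_pitch", "head_roll", "chest",
                       "video", "motion")]
  p <- sum(sizes)
  starts <- cumsum(c(0L, sizes[-length(sizes)]))
  groups <- stats::setNames(
    lapply(seq_along(sizes), function(i) starts[i] + seq_len(sizes[i])),
    names(sizes))
  X <- matrix(0, rows, p)

  tp_ind <- function(gate) {
    # gate: logical per included trial; returns rows x n_tp indicator block
    M <- matrix(0, rows, n_tp)
    r <- which(rep(gate, each = n_tp))
    M[cbind(r, timepoint[r])] <- 1
    M
  }
  X[, groups$trial_time] <- tp_ind(rep(TRUE, n_trials))
  X[, groups$choice] <- tp_ind(table$choice[trials] == "right")
  X[, groups$outcome] <- tp_ind(table$outcome[trials] == "correct")
  for (cc in history_contexts())
    X[, groups[[paste0("hist_", cc)]]] <- tp_ind(as.character(ctx[trials]) == cc)

  # session-wide binary event streams
  ev_stream <- function(times) {
    v <- logical(n_frames)
    f <- as.integer(round(times * fr))
    f <- f[!is.na(f) & f >= 0L & f < n_frames]
    v[f + 1L] <- TRUE
    v
  }
  stim_times <- unlist(lapply(seq_len(nrow(table)), function(t) {
    ev <- table$stimulus_events[[t]]
    if (is.null(ev) || !length(ev)) return(numeric(0))
    on <- table$t_stim_onset[t] + ev
    if (config$stim_repeat) on <- c(on, table$t_stim_onset[t] + 1 + ev)
    on
  }), use.names = FALSE)
  stim_ev <- ev_stream(stim_times)
  shift_cols <- function(ev, shifts) {
    # column s: 1 if the event occurred s frames before the row's frame
    vapply(shifts, function(s) {
      f <- frame - s
      out <- numeric(rows)
      sel <- f >= 0L & f < n_frames
      out[sel] <- as.numeric(ev[f[sel] + 1L])
      out
    }, numeric(rows))
  }
  X[, groups$stimulus] <- shift_cols(stim_ev, 0:(sizes[["stimulus"]] - 1L))

  poke_shifts <- seq(as.integer(round(config$poke_kernel[1] * fr)),
                     as.integer(round(config$poke_kernel[2] * fr)))
  X[, groups$poke_center] <- shift_cols(ev_stream(table$t_init), poke_shifts)
  X[, groups$poke_left] <- shift_cols(
    ev_stream(table$t_choice_report[table$choice == "left"]), poke_shifts)
  X[, groups$poke_right] <- shift_cols(
    ev_stream(table$t_choice_report[table$choice == "right"]), poke_shifts)

  n_zero_occ <- 0L
  if (!is.null(tracking)) {
    n_ha <- as.integer(360 / config$head_angle_bin_deg)
    ha <- tracking$head_angles
    for (j in 1:3) {
      g <- groups[[c("head_yaw", "head_pitch", "head_roll")[j]]]
      ang <- ha[frame + 1L, j] %% 360
      bin <- pmin(floor(ang / config$head_angle_bin_deg) + 1L, n_ha)
      sel <- !is.na(bin)
      X[cbind(which(sel), g[bin[sel]])] <- 1
    }
    nx <- as.integer(ceiling(config$arena_cm[1] / config$chest_bin_cm))
    ny <- as.integer(ceiling(config$arena_cm[2] / config$chest_bin_cm))
    cx <- tracking$chest_xy[frame + 1L, 1]
    cy <- tracking$chest_xy[frame + 1L, 2]
    ix <- pmin(pmax(floor(cx / config$chest_bin_cm), 0L), nx - 1L)
    iy <- pmin(pmax(floor(cy / config$chest_bin_cm), 0L), ny - 1L)
    bin <- iy * nx + ix + 1L
    sel <- !is.na(bin)
    n_zero_occ <- sum(!sel)
    if (n_zero_occ > 0L)
      message(n_zero_occ, " row(s) with missing chest tracking: all-zero occupancy")
    X[cbind(which(sel), groups$chest[bin[sel]])] <- 1
    X[, groups$video] <- tracking$video_svd[frame + 1L, seq_len(config$n_video),
                                            drop = FALSE]
    X[, groups$motion] <- tracking$motion_svd[frame + 1L, seq_len(config$n_motion),
                                              drop = FALSE]
    if (config$orthogonalize) {
      ana <- c(groups$video, groups$motion)
      X[, ana] <- orthogonalize_against(X[, ana, drop = FALSE],
                                        X[, groups$stimulus, drop = FALSE])
    }
  }

  structure(list(
    X = X, groups = groups, variables = variable_groups(names(groups)),
    trial_id = trial_id, timepoint = timepoint, frame = frame,
    timepoint_phase = rep(win$phase, n_tp_w),
    time_offsets = unlist(lapply(seq_len(nrow(win)), function(i)
      win$pre[i] + (seq_len(n_tp_w[i]) - 1L) / fr)),
    context = factor(as.character(ctx[trials]), levels = history_contexts()),
    included_trial_indices = table$trial_index[trials],
    n_zero_occupancy = n_zero_occ, config = config
  ), class = "design_matrix")
}

#' Construct a design matrix from explicit parts
#'
#' Low-level constructor used for simulation studies and tests where the
#' regressor matrix is built directly rather than from a session.
#'
#' @param X Numeric matrix (rows = trial x timepoint samples).
#' @param groups Named list of column-index vectors covering `1:ncol(X)`.
#' @param trial_id Trial identifier per row.
#' @param timepoint Timepoint index per row.
#' @param variables Optional variable-to-group mapping; defaults to one
#'   variable per non-`trial_time` group.
#' @return `"design_matrix"` object.
#' @export
design_matrix_from_parts <- function(X, groups, trial_id, timepoint,
                                     variables = NULL) {
  stopifnot(is.matrix(X), length(trial_id) == nrow(X),
            length(timepoint) == nrow(X))
  if (is.null(variables)) {
    vn <- setdiff(names(groups), "trial_time")
    variables <- stats::setNames(as.list(vn), vn)
  }
  structure(list(X = X, groups = groups, variables = variables,
                 trial_id = trial_id, timepoint = timepoint,
                 frame = seq_len(nrow(X)) - 1L,
                 timepoint_phase = rep("all", max(timepoint)),
                 time_offsets = seq_len(max(timepoint)),
                 context = NULL,
                 included_trial_indices = unique(trial_id),
                 n_zero_occupancy = 0L, config = NULL),
            class = "design_matrix")
}
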