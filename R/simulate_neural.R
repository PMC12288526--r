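#' Random ground-truth tuning for a synthetic population
#'
#' Draws per-neuron weight sets over the same regressor groups as the
#' encoding-model design matrix, so that downstream encoding fits can be
#' validated against known ground truth. Each neuron is tuned to a random
#' subset of variables (`tuned_frac` per group); untuned groups get zero
#' weights. Trial-history weights can optionally be generated from a shared
#' low-rank set of context-time dynamics (`shared_history`), emulating
#' history coding that is conserved across sessions and subjects.
#'
#' @param config [design_config()] defining the group layout.
#' @param n_neurons Number of neurons.
#' @param tuned_frac Probability that a neuron carries nonzero weights for a
#'   given group.
#' @param weight_sd Weight scale (s.d. of nonzero weights).
#' @param noise_sd Additive Gaussian noise s.d. on the simulated rates.
#' @param tau Optional causal exponential decay (seconds) emulating calcium
#'   indicator dynamics; 0 disables.
#' @param shared_history Optional list with `dynamics` (a k x (4 * n_tp)
#'   matrix of shared context-time dynamics); per-neuron history weights are
#'   random loadings on these dynamics.
#' @param include_tracking Include occupancy/analog groups (must match the
#'   design matrix the session will be fitted with).
#' @param seed Optional RNG seed.
#' @return List of class `"ground_truth_tuning"`: `weights` (named list,
#'   one `size x n_neurons` matrix per group), `noise_sd`, `tau`.
#' @export
random_tuning <- function(config, n_neurons, tuned_frac = 0.4,
                          weight_sd = 0.5, noise_sd = 0.5, tau = 0,
                          shared_history = NULL, include_tracking = TRUE,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- design_group_sizes(config)
  if (!include_tracking)
    sizes <- sizes[!names(sizes) %in%
                     c("head_yaw", "head_pitch", "head_roll", "chest",
                       "video", "motion")]
  weights <- lapply(names(sizes), function(g) {
    W <- matrix(0, sizes[[g]], n_neurons)
    tuned <- stats::runif(n_neurons) < (if (g == "trial_time") 1 else tuned_frac)
    # smooth kernel weights over time-structured groups, iid over bins/analog
    W[, tuned] <- stats::rnorm(sizes[[g]] * sum(tuned), sd = weight_sd)
    if (g == "trial_time") W <- W * 0.3
    W
  })
  names(weights) <- names(sizes)
  if (!is.null(shared_history)) {
    dyn <- shared_history$dynamics  # k x (4 * n_tp)
    k <- nrow(dyn)
    n_tp <- sizes[["trial_time"]]
    stopifnot(ncol(dyn) == 4L * n_tp)
    load <- matrix(stats::rnorm(n_neurons * k, sd = 1), n_neurons, k)
    hw <- load %*% dyn  # n_neurons x (4 n_tp)
    for (j in 1:4) {
      g <- paste0("hist_", history_contexts()[j])
      weights[[g]] <- t(hw[, (j - 1L) * n_tp + seq_len(n_tp), drop = FALSE])
    }
  }
  structure(list(weights = weights, noise_sd = noise_sd, tau = tau),
            class = "ground_truth_tuning")
}

#' Simulate a neural session from ground-truth tuning
#'
#' Builds the encoding-model design matrix for the session and generates
#' neurons x frames activity as `design %*% weights` on the aligned
#' trial-time grid, plus Gaussian noise everywhere, optionally convolved
#' with a causal exponential kernel (calcium dynamics). Frames outside the
#' aligned grid carry noise only. The ground truth is returned alongside the
#' session so recovery can be tested.
#'
#' @param table Trial table.
#' @param tracking Tracking streams (or `NULL` for task-only tuning).
#' @param tuning [random_tuning()] result, or a compatible list whose
#'   `weights` match the design layout exactly.
#' @param config [design_config()].
#' @param seed Optional RNG seed.
#' @param keep_design Return the design matrix used for generation.
#' @return List with `session` (activity, frame_rate, trial_start_frames,
#'   neuron_ids), `tuning`, and optionally `design`.
#' @export
simulate_neural <- function(table, tracking, tuning, config = design_config(),
                            seed = NULL, keep_design = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  fr <- config$frame_rate
  n_frames <- as.integer(ceiling((max(table$t_outcome_end, na.rm = TRUE) + 2) * fr))
  n_neurons <- ncol(tuning$weights[[1]])
  shell <- list(activity = matrix(0, n_neurons, n_frames), frame_rate = fr)
  dm <- build_design_matrix(table, shell, tracking, config)
  sizes <- vapply(dm$groups, length, 1L)
  wsizes <- vapply(tuning$weights, nrow, 1L)
  if (!identical(names(sizes), names(wsizes)) || !all(sizes == wsizes[names(sizes)]))
    stop("tuning weight shapes do not match the design-matrix layout")
  W <- do.call(rbind, tuning$weights[names(sizes)])
  signal <- dm$X %*% W  # rows x neurons

  activity <- matrix(stats::rnorm(n_neurons * n_frames, sd = tuning$noise_sd),
                     n_neurons, n_frames)
  activity[, dm$frame + 1L] <- activity[, dm$frame + 1L] + t(signal)
  if (!is.null(tuning$tau) && tuning$tau > 0) {
    kl <- as.integer(ceiling(5 * tuning$tau * fr))
    k <- exp(-(0:kl) / (tuning$tau * fr)); k <- k / sum(k)
    for (i in seq_len(n_neurons)) {
      conv <- stats::convolve(activity[i, ], rev(k), type = "open")
      activity[i, ] <- conv[seq_len(n_frames)]
    }
  }
  session <- list(activity = activity, frame_rate = fr,
                  trial_start_frames = as.integer(round(table$t_init * fr)),
                  neuron_ids = seq_len(n_neurons))
  out <- list(session = session, tuning = tuning)
  if (keep_design) out$design <- dm
  out
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper chaining [simulate_behavior()], [simulate_tracking()]
#' and [simulate_neural()] with seeds derived from one master seed, returning
#' everything [write_session()] needs plus the ground truth.
#'
#' @param agent [agent_params()].
#' @param n_trials Number of trials.
#' @param n_neurons Number of neurons.
#' @param config [design_config()].
#' @param tuning Optional [random_tuning()]; drawn if `NULL`.
#' @param coupling Tracking/task coupling in `[0, 1]`.
#' @param noise_sd,tau Passed to [random_tuning()] when `tuning` is `NULL`.
#' @param shared_history Passed to [random_tuning()].
#' @param seed Master seed.
#' @return Session list (table, activity, tracking streams, frame_rate,
#'   trial_start_frames, meta) with attached `tuning`.
#' @export
simulate_session <- function(agent = agent_params(), n_trials = 300,
                             n_neurons = 40, config = design_config(),
                             tuning = NULL, coupling = 0.3, noise_sd = 0.5,
                             tau = 0, shared_history = NULL, seed = 1) {
  table <- simulate_behavior(agent, n_trials, seed = derive_seed(seed, "behavior"))
  fr <- config$frame_rate
  n_frames <- as.integer(ceiling((max(table$t_outcome_end, na.rm = TRUE) + 2) * fr))
  tracking <- simulate_tracking(table, n_frames, frame_rate = fr,
                                arena_cm = config$arena_cm,
                                n_components = max(config$n_video, config$n_motion),
                                coupling = coupling,
                                seed = derive_seed(seed, "tracking"))
  if (is.null(tuning))
    tuning <- random_tuning(config, n_neurons, noise_sd = noise_sd, tau = tau,
                            shared_history = shared_history,
                            seed = derive_seed(seed, "tuning"))
  neur <- simulate_neural(table, tracking, tuning, config,
                          seed = derive_seed(seed, "neural"))
  list(table = table, activity = neur$session$activity,
       chest_xy = tracking$chest_xy, head_angles = tracking$head_angles,
       video_svd = tracking$video_svd, motion_svd = tracking$motion_svd,
       frame_rate = fr,
       trial_start_frames = neur$session$trial_start_frames,
       tuning = tuning,
       meta = list(seed = seed, n_trials = n_trials, n_neurons = n_neurons,
                   agent = unclass(agent)))
}
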