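# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a compact two-phase trial-time grid that keeps encoding fits fast
compact_windows <- function() {
  data.frame(phase = c("early_iti", "stimulus"),
             anchor_event = c("prev_choice_report", "stim_onset"),
             pre = c(0, -0.2), post = c(0.5, 0.4),
             stringsAsFactors = FALSE)
}

compact_config <- function(...) {
  design_config(windows = compact_windows(), n_video = 4, n_motion = 4, ...)
}

small_session <- function() {
  cached("small_session", {
    tab <- simulate_behavior(agent_params(), 90, seed = 11)
    tracking <- simulate_tracking(tab, seed = 12, n_components = 4)
    tuning <- random_tuning(compact_config(), 5, noise_sd = 0.3, seed = 13)
    neur <- simulate_neural(tab, tracking, tuning, compact_config(),
                            seed = 14, keep_design = TRUE)
    list(table = tab, tracking = tracking, tuning = tuning,
         session = neur$session, design = neur$design)
  })
}

# aligned-activity stub with k Gaussian class clusters per timepoint
cluster_aligned <- function(n_trials, n_neurons, n_timepoints, separation,
                            seed, classes = history_contexts(),
                            means = NULL) {
  set.seed(seed)
  k <- length(classes)
  labs <- factor(rep(classes, length.out = n_trials), levels = classes)
  if (is.null(means))
    means <- matrix(stats::rnorm(k * n_neurons, sd = separation), k, n_neurons)
  tensor <- array(stats::rnorm(n_trials * n_neurons * n_timepoints),
                  c(n_trials, n_neurons, n_timepoints))
  for (t in seq_len(n_timepoints))
    tensor[, , t] <- tensor[, , t] + means[as.integer(labs), ]
  list(tensor = tensor, context = labs, means = means)
}

# minimal completed-trials table for behavioral fits generated straight from
# a psychometric model
psychometric_table <- function(p, n, seed) {
  set.seed(seed)
  x <- sample(stimulus_rates(), n, replace = TRUE)
  y <- stats::rbinom(n, 1, psychometric_eval(p, x))
  tab <- data.frame(
    trial_index = seq_len(n), stimulus_rate_hz = x,
    category = ifelse(x < 12, "low", "high"),
    choice = ifelse(y == 1, "right", "left"),
    completed = TRUE, stringsAsFactors = FALSE)
  tab$outcome <- ifelse((tab$category == "high") == (tab$choice == "right"),
                        "correct", "incorrect")
  tab
}

# orthogonal-by-construction design with a trial-time group and two kernel
# groups; group A drives the probe neuron
orthogonal_design <- function(n_trials = 120, n_tp = 12, seed = 5,
                              duplicate_a = FALSE) {
  set.seed(seed)
  rows <- n_trials * n_tp
  trial_id <- rep(seq_len(n_trials), each = n_tp)
  timepoint <- rep(seq_len(n_tp), n_trials)
  tt <- matrix(0, rows, n_tp); tt[cbind(seq_len(rows), timepoint)] <- 1
  gate_a <- rep(sample(c(-1, 1), n_trials, replace = TRUE), each = n_tp)
  gate_b <- rep(sample(c(-1, 1), n_trials, replace = TRUE), each = n_tp)
  # group A active in the first half of trial time, B in the second half:
  # columns of different groups never overlap, so the design is orthogonal
  a_cols <- tt[, seq_len(n_tp / 2), drop = FALSE] * gate_a
  b_cols <- tt[, n_tp / 2 + seq_len(n_tp / 2), drop = FALSE] * gate_b
  if (duplicate_a) b_cols <- a_cols  # collinearity construction
  X <- cbind(tt, a_cols, b_cols)
  groups <- list(trial_time = seq_len(n_tp),
                 group_a = n_tp + seq_len(ncol(a_cols)),
                 group_b = n_tp + ncol(a_cols) + seq_len(ncol(b_cols)))
  dm <- design_matrix_from_parts(X, groups, trial_id, timepoint)
  kern_a <- sin(seq_len(n_tp / 2))  # within-trial kernel shape
  signal <- as.numeric(a_cols %*% kern_a)
  list(dm = dm, signal = signal, gate_a = gate_a, kern_a = kern_a)
}
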