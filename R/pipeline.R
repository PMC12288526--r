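#' Derive a stage seed from a master seed
#'
#' Deterministically hashes a master seed with any number of string/number
#' qualifiers (stage name, subject, session) into a 31-bit seed, so every
#' stochastic stage gets an independent, reproducible stream without manual
#' bookkeeping.
#'
#' @param master Master seed (integer).
#' @param ... Stage qualifiers (coerced to character).
#' @return Integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master, ...) {
  s <- as.numeric(master) %% 2147483647
  for (tok in unlist(lapply(list(...), as.character))) {
    for (code in utf8ToInt(tok)) s <- (s * 131 + code) %% 2147483647
  }
  as.integer(s) + 1L
}

#' Default pipeline configuration
#'
#' One configuration object driving the full synthetic study:
#' session generation (subjects x sessions with per-subject agents and a
#' shared trial-history dynamic), the behavioral GLM, decoding, encoding
#' and geometry stages. Stage toggles allow partial runs. The configuration
#' round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param n_subjects,n_sessions_per_subject Study size.
#' @param n_trials,n_neurons Per-session size.
#' @param seed Master seed; all stage seeds derive from it.
#' @param coupling Movement/task coupling of the tracking generator.
#' @param noise_sd Neural noise s.d.
#' @param decode_phase Phase used by the decoding stage (one window keeps
#'   the demo tractable; `"all"` uses the full grid).
#' @param decode_rounds,decode_splits Decoder subsampling/split counts.
#' @param n_video Analog components included in the encoding design.
#' @param windows `"canonical"` (the four full phase windows) or
#'   `"compact"` (a reduced two-phase grid that keeps demo encoding fits
#'   fast).
#' @param stages Character vector of enabled stages.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_subjects = 3, n_sessions_per_subject = 3,
                            n_trials = 250, n_neurons = 30, seed = 1,
                            coupling = 0.3, noise_sd = 0.5,
                            decode_phase = "early_iti", decode_rounds = 5,
                            decode_splits = 4, n_video = 30,
                            windows = "canonical",
                            stages = c("simulate", "behavior", "decode",
                                       "encode", "geometry")) {
  stopifnot(windows %in% c("canonical", "compact"))
  structure(list(n_subjects = n_subjects,
                 n_sessions_per_subject = n_sessions_per_subject,
                 n_trials = n_trials, n_neurons = n_neurons, seed = seed,
                 coupling = coupling, noise_sd = noise_sd,
                 decode_phase = decode_phase, decode_rounds = decode_rounds,
                 decode_splits = decode_splits, n_video = n_video,
                 windows = windows, stages = stages),
            class = "pipeline_config")
}

.pipeline_windows <- function(which) {
  if (which == "compact")
    data.frame(phase = c("early_iti", "stimulus"),
               anchor_event = c("prev_choice_report", "stim_onset"),
               pre = c(0, -0.2), post = c(0.5, 0.4),
               stringsAsFactors = FALSE)
  else phase_windows()
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `"pipeline_config"` (write) / ignored (read).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[names(raw) %in% names(formals(pipeline_config))])
  cfg
}

#' Run the full synthetic trial-history study
#'
#' Orchestrates session generation, behavioral GLM fits, population
#' decoding, encoding-model variance partitioning and weight-geometry
#' comparison under one master seed, writing per-stage outputs and a
#' summary report. Identical configurations (and seeds) yield identical
#' numeric summaries.
#'
#' @param config [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Report list with one element per executed stage (skipped stages
#'   are noted), plus `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t_start <- Sys.time()
  report <- list(config = unclass(config), skipped = setdiff(
    c("simulate", "behavior", "decode", "encode", "geometry"), config$stages))
  dcfg <- design_config(windows = .pipeline_windows(config$windows),
                        n_video = config$n_video, n_motion = config$n_video)

  sizes <- design_group_sizes(dcfg)
  n_tp <- sizes[["trial_time"]]
  set.seed(derive_seed(config$seed, "shared-history"))
  shared <- list(dynamics = .smooth_dynamics(3, 4L * n_tp))

  sessions <- list(); subj_of <- character(0)
  if ("simulate" %in% config$stages) {
    for (su in seq_len(config$n_subjects)) {
      set.seed(derive_seed(config$seed, "agent", su))
      agent <- agent_params(
        beta0 = stats::rnorm(1, 0, 0.2), beta_stim = 2.0,
        beta_hist = c(-0.8, -0.2, 0.3, 0.9) + stats::rnorm(4, 0, 0.15))
      for (se in seq_len(config$n_sessions_per_subject)) {
        id <- sprintf("subj%02d_sess%02d", su, se)
        sessions[[id]] <- simulate_session(
          agent, n_trials = config$n_trials, n_neurons = config$n_neurons,
          config = dcfg, coupling = config$coupling,
          noise_sd = config$noise_sd, shared_history = shared,
          seed = derive_seed(config$seed, "session", id))
        subj_of[id] <- sprintf("subj%02d", su)
      }
    }
    report$simulate <- list(n_sessions = length(sessions),
                            n_trials = config$n_trials,
                            n_neurons = config$n_neurons)
    if (!is.null(out_dir)) {
      for (id in names(sessions))
        write_session(sessions[[id]], file.path(out_dir, "sessions", id))
    }
  } else {
    report$note <- "simulate disabled: downstream stages skipped"
    return(report)
  }

  if ("behavior" %in% config$stages) {
    fits <- lapply(names(sessions), function(id)
      fit_history_glm(sessions[[id]]$table,
                      seed = derive_seed(config$seed, "behavior", id)))
    accs <- vapply(sessions, function(s)
      mean(s$table$outcome[s$table$completed] == "correct"), numeric(1))
    weights <- t(vapply(fits, function(f)
      c(stim = f$stim_weight, f$hist_weights,
        strength = f$history_strength), numeric(6)))
    rownames(weights) <- names(sessions)
    corr <- history_performance_correlation(fits, accs)
    report$behavior <- list(weights = weights, accuracy = accs,
                            correlation_r = corr$r, correlation_p = corr$p_value)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(data.frame(session = names(sessions), weights,
                                  accuracy = accs),
                       file.path(out_dir, "behavior_weights.csv"),
                       row.names = FALSE)
    }
  }

  if ("decode" %in% config$stages) {
    id <- names(sessions)[1]
    s <- sessions[[id]]
    neural <- list(activity = smooth_rates(s$activity, 1),
                   frame_rate = s$frame_rate)
    win <- .pipeline_windows(config$windows)
    aligned <- if (config$decode_phase == "all")
      align_phases(neural, s$table, win)
    else align_activity(neural, s$table,
                        win[win$phase == config$decode_phase, ])
    spec <- decoder_spec(n_subsample_rounds = config$decode_rounds,
                         n_splits = config$decode_splits)
    dec <- train_decoders(aligned, spec = spec,
                          seed = derive_seed(config$seed, "decode", id))
    report$decode <- list(
      session = id,
      accuracy = dec$accuracy_overall,
      shuffled_accuracy = dec$shuffled$accuracy_overall,
      chance = 1 / length(dec$classes),
      marginal_choice = marginal_binary_accuracy(dec, "prev_choice"),
      marginal_outcome = marginal_binary_accuracy(dec, "prev_outcome"))
  }

  fits_enc <- list()
  if (any(c("encode", "geometry") %in% config$stages)) {
    for (id in names(sessions)) {
      s <- sessions[[id]]
      neural <- list(activity = s$activity, frame_rate = s$frame_rate)
      dm <- build_design_matrix(s$table, neural,
                                tracking = list(chest_xy = s$chest_xy,
                                                head_angles = s$head_angles,
                                                video_svd = s$video_svd,
                                                motion_svd = s$motion_svd),
                                config = dcfg)
      act <- activity_at_rows(neural, dm)
      fits_enc[[id]] <- list(
        dm = dm,
        fit = fit_ridge_cv(dm, act, seed = derive_seed(config$seed, "encode", id)))
      if (!"geometry" %in% config$stages || id == names(sessions)[1]) {
        if ("encode" %in% config$stages && id == names(sessions)[1]) {
          vp <- variance_partition(dm, act, fit = fits_enc[[id]]$fit,
                                   seed = derive_seed(config$seed, "vp", id),
                                   variables = c("trial_history", "choice",
                                                 "chest", "video"))
          report$encode <- list(
            session = id,
            r2_full_mean = mean(fits_enc[[id]]$fit$r2_full),
            max_ev_mean = rowMeans(vp$max_ev),
            unique_ev_mean = rowMeans(vp$unique_ev))
        }
      }
    }
  }

  if ("geometry" %in% config$stages) {
    geoms <- lapply(fits_enc, function(fe)
      encoding_geometry(fe$fit, fe$dm, "trial_history"))
    d90s <- vapply(geoms, `[[`, integer(1), "d90")
    md <- match_dimensions(geoms)
    pw <- pairwise_disparity(md$shapes, subj_of[names(fits_enc)])
    report$geometry <- list(
      d90_history = d90s,
      disparity = pw,
      mean_within = mean(pw$disparity[pw$grouping == "within_subject"]),
      mean_across = mean(pw$disparity[pw$grouping == "across_subject"]))
    if (!is.null(out_dir))
      utils::write.csv(pw, file.path(out_dir, "history_disparity.csv"),
                       row.names = FALSE)
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(.report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# smooth, equal-power latent dynamics (rows) over a time grid
.smooth_dynamics <- function(k, len) {
  D <- vapply(seq_len(k), function(i) {
    v <- stats::filter(stats::rnorm(len + 20), rep(1 / 8, 8), sides = 1)
    v <- v[!is.na(v)][seq_len(len)]
    as.numeric(scale(v))
  }, numeric(len))
  t(qr.Q(qr(D)) * sqrt(len))  # orthonormalized, equal power, k x len
}

.report_summary <- function(report) {
  # numeric-only flattening for the JSON report
  rapply(report, function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  }, how = "replace")
}
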