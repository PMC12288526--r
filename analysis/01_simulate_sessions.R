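#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Three subjects x three sessions of the self-initiated rate-discrimination
# task. Each subject gets its own trial-history bias vector (drawn around a
# common profile: rewarded choices tend to be repeated, incorrect choices
# have weaker influence), while all sessions share one low-rank set of
# trial-history context dynamics in their neural tuning -- the ground-truth
# analog of a history code conserved across subjects. Movement, posture and
# surrogate video streams are generated alongside.

suppressMessages(library(trialhist))

out_root <- "scratch/sessions"
master_seed <- 20260927

config <- pipeline_config(
  n_subjects = 3, n_sessions_per_subject = 3,
  n_trials = 250, n_neurons = 30, n_video = 30,
  windows = "compact", seed = master_seed)
dcfg <- design_config(windows = trialhist:::.pipeline_windows(config$windows),
                      n_video = config$n_video, n_motion = config$n_video)

n_tp <- design_group_sizes(dcfg)[["trial_time"]]
set.seed(derive_seed(master_seed, "shared-history"))
shared <- list(dynamics = trialhist:::.smooth_dynamics(3, 4L * n_tp))

manifest <- list()
for (su in seq_len(config$n_subjects)) {
  set.seed(derive_seed(master_seed, "agent", su))
  agent <- agent_params(beta0 = rnorm(1, 0, 0.2), beta_stim = 2.0,
                        beta_hist = c(-0.8, -0.2, 0.3, 0.9) + rnorm(4, 0, 0.15))
  for (se in seq_len(config$n_sessions_per_subject)) {
    id <- sprintf("subj%02d_sess%02d", su, se)
    sess <- simulate_session(agent, n_trials = config$n_trials,
                             n_neurons = config$n_neurons, config = dcfg,
                             shared_history = shared,
                             seed = derive_seed(master_seed, "session", id))
    write_session(sess, file.path(out_root, id))
    done <- sess$table$completed
    manifest[[id]] <- data.frame(
      session = id, subject = sprintf("subj%02d", su),
      n_trials = nrow(sess$table), n_completed = sum(done),
      frac_correct = mean(sess$table$outcome[done] == "correct"),
      agent_history_strength = sqrt(sum(unclass(agent)$beta_hist^2)))
    cat(sprintf("%s: %d/%d completed, %.1f%% correct\n", id, sum(done),
                nrow(sess$table),
                100 * mean(sess$table$outcome[done] == "correct")))
  }
}
manifest <- do.call(rbind, manifest)
dir.create("results", showWarnings = FALSE)
write.csv(manifest, "results/session_manifest.csv", row.names = FALSE)
cat("wrote", nrow(manifest), "sessions under", out_root, "\n")
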