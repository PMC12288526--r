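#!/usr/bin/env Rscript
# Stage 4: single-neuron encoding models.
#
# Per-neuron ridge regression of activity on task kernels (trial time,
# choice, outcome, four trial-history contexts, stimulus events, port
# pokes), posture occupancancy (head angles, chest position) and surrogate
# video/motion components, with 10-fold CV and a per-neuron penalty search.
# Variance is then partitioned into maximal EV (single-variable models
# vs the trial-time-only model) and unique EV (full vs one-removed models).
# Weight matrices are saved for the geometry stage.

suppressMessages(library(trialhist))

master_seed <- 20260927
sessions <- list.files("scratch/sessions", full.names = TRUE)
dcfg <- design_config(windows = trialhist:::.pipeline_windows("compact"),
                      n_video = 30, n_motion = 30)
dir.create("scratch/encoding", showWarnings = FALSE, recursive = TRUE)

vp_rows <- list()
for (dir in sessions) {
  id <- basename(dir)
  s <- read_session(dir)
  neural <- list(activity = s$activity, frame_rate = s$frame_rate)
  tracking <- list(chest_xy = s$chest_xy, head_angles = s$head_angles,
                   video_svd = s$video_svd, motion_svd = s$motion_svd)
  dm <- build_design_matrix(s$table, neural, tracking, dcfg)
  act <- activity_at_rows(neural, dm)
  fit <- fit_ridge_cv(dm, act, seed = derive_seed(master_seed, "encode", id))
  cat(sprintf("%s: held-out R^2 = %.3f +- %.3f (mean +- sd over %d neurons)\n",
              id, mean(fit$r2_full), sd(fit$r2_full), ncol(act)))

  # weights for the geometry stage (plain text, lossless)
  w <- matrix(sprintf("%.17g", fit$weights), nrow(fit$weights))
  data.table::fwrite(data.table::as.data.table(w),
                     file.path("scratch/encoding", paste0(id, "_weights.csv")),
                     quote = FALSE, col.names = FALSE)
  if (dir == sessions[1]) {
    jsonlite::write_json(lapply(dm$groups, as.integer),
                         "scratch/encoding/groups.json", digits = NA)
    # variance partition on the first session only (the slow stage)
    vp <- variance_partition(dm, act, fit = fit,
                             seed = derive_seed(master_seed, "vp", id),
                             variables = c("trial_history", "choice",
                                           "chest", "video"))
    for (v in vp$variables)
      vp_rows[[v]] <- data.frame(
        session = id, variable = v,
        max_ev_mean = mean(vp$max_ev[v, ]),
        unique_ev_mean = mean(vp$unique_ev[v, ]),
        r2_full_mean = mean(vp$r2_full))
    trr <- time_resolved_r2(fit, dm)
    write.csv(data.frame(timepoint = seq_len(nrow(trr)),
                         phase = dm$timepoint_phase,
                         offset_s = dm$time_offsets,
                         r2_mean = rowMeans(trr, na.rm = TRUE)),
              "results/encoding_time_resolved_r2.csv", row.names = FALSE)
  }
}
vp_tab <- do.call(rbind, vp_rows)
write.csv(vp_tab, "results/encoding_variance_partition.csv", row.names = FALSE)
cat("variance partition (session 1):\n")
print(vp_tab[, -1], row.names = FALSE, digits = 3)
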