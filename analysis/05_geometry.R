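#!/usr/bin/env Rscript
# Stage 5: geometry of the encoding weights.
#
# PCA across neurons of each session's weights for trial history, chest
# position, and the video components: how many dimensions capture 90% of
# the weight variance (d90), and how similar are the weight dynamics across
# sessions and subjects after optimal translation/rotation/scaling
# (Procrustes disparity, 0 = identical shapes)? With a shared ground-truth
# history dynamic, trial-history shapes should match far better across
# sessions than the session-specific movement loadings.

suppressMessages(library(trialhist))

groups <- jsonlite::read_json("scratch/encoding/groups.json",
                              simplifyVector = TRUE)
wfiles <- list.files("scratch/encoding", pattern = "_weights\\.csv$",
                     full.names = TRUE)
ids <- sub("_weights\\.csv$", "", basename(wfiles))
subject <- sub("_sess.*", "", ids)

vars <- list(trial_history = unlist(groups[paste0("hist_", history_contexts())]),
             chest = groups$chest, video = groups$video)
rows <- list(); disp <- list()
for (v in names(vars)) {
  geoms <- lapply(wfiles, function(f) {
    W <- as.matrix(data.table::fread(f, header = FALSE, colClasses = "numeric"))
    pca_dimensionality(t(W[vars[[v]], , drop = FALSE]))
  })
  d90 <- vapply(geoms, `[[`, integer(1), "d90")
  md <- match_dimensions(geoms)
  pw <- pairwise_disparity(md$shapes, subject)
  pw$variable <- v
  disp[[v]] <- pw
  rows[[v]] <- data.frame(variable = v, d90_mean = mean(d90),
                          d90_min = min(d90), d90_max = max(d90),
                          matched_dims = md$n_dims,
                          disparity_within = mean(
                            pw$disparity[pw$grouping == "within_subject"]),
                          disparity_across = mean(
                            pw$disparity[pw$grouping == "across_subject"]))
  cat(sprintf("%-14s d90 = %.1f (range %d-%d); disparity within %.3f / across %.3f\n",
              v, mean(d90), min(d90), max(d90),
              rows[[v]]$disparity_within, rows[[v]]$disparity_across))
}
summary <- do.call(rbind, rows)
write.csv(summary, "results/geometry_summary.csv", row.names = FALSE)
write.csv(do.call(rbind, disp), "results/geometry_disparities.csv",
          row.names = FALSE)

cat(sprintf("\ntrial-history dynamics are conserved: mean disparity %.3f vs %.3f (video)\n",
            mean(disp$trial_history$disparity), mean(disp$video$disparity)))
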