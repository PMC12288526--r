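#!/usr/bin/env Rscript
# Stage 3: population decoding of trial history.
#
# One-vs-all linear decoders of the four previous-choice-x-outcome contexts
# from smoothed population activity, per timepoint of the early-ITI phase:
# overall accuracy vs the label-shuffled control, per-context accuracy over
# time, confusion structure, marginal binary readouts (previous choice /
# previous outcome), and the cross-temporal generalization matrix.

suppressMessages(library(trialhist))

master_seed <- 20260927
dir <- list.files("scratch/sessions", full.names = TRUE)[1]
id <- basename(dir)
s <- read_session(dir)
neural <- list(activity = smooth_rates(s$activity, 1), frame_rate = s$frame_rate)

win <- data.frame(phase = "early_iti", anchor_event = "prev_choice_report",
                  pre = 0, post = 0.5)
aligned <- align_activity(neural, s$table, win)
cat(sprintf("%s: %d trials with defined context, %d neurons, %d timepoints\n",
            id, dim(aligned$tensor)[1], dim(aligned$tensor)[2],
            dim(aligned$tensor)[3]))

spec <- decoder_spec(n_subsample_rounds = 10, n_splits = 8)
res <- train_decoders(aligned, spec = spec,
                      seed = derive_seed(master_seed, "decode", id),
                      crosstemporal = TRUE)

cat(sprintf("4-class accuracy: %.1f%% (shuffled control %.1f%%, chance 25%%)\n",
            100 * res$accuracy_overall, 100 * res$shuffled$accuracy_overall))
cat(sprintf("marginal previous-choice readout: %.1f%%, previous-outcome: %.1f%%\n",
            100 * marginal_binary_accuracy(res, "prev_choice"),
            100 * marginal_binary_accuracy(res, "prev_outcome")))

acc_time <- data.frame(timepoint = seq_along(res$accuracy_by_timepoint),
                       offset_s = aligned$time_offsets,
                       accuracy = res$accuracy_by_timepoint,
                       shuffled = res$shuffled$accuracy_by_timepoint,
                       t(res$accuracy_by_time))
names(acc_time)[5:8] <- res$classes
write.csv(acc_time, "results/decoding_accuracy_by_time.csv", row.names = FALSE)

conf <- confusion_over_time(res)
mid <- ceiling(dim(conf)[1] / 2)
cat("confusion at mid-ITI (rows = true, cols = predicted):\n")
print(round(conf[mid, , ], 2))
write.csv(as.data.frame.table(conf), "results/decoding_confusion.csv",
          row.names = FALSE)

ct <- res$crosstemporal
write.csv(ct, "results/decoding_crosstemporal.csv", row.names = FALSE)
cat(sprintf("cross-temporal: diagonal mean %.1f%%, off-diagonal mean %.1f%%\n",
            100 * mean(diag(ct)), 100 * mean(ct[row(ct) != col(ct)])))
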