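test_that("history context labels follow the previous completed trial", {
  tab <- simulate_behavior(agent_params(), 200, seed = 1)
  ctx <- derive_history_context(tab)
  # first trial undefined; otherwise defined exactly when predecessor completed
  expect_equal(as.character(ctx[1]), "undefined")
  expect_equal(which(ctx != "undefined"),
               which(c(FALSE, tab$completed[-nrow(tab)])))
  # label matches the predecessor's choice/outcome
  for (t in which(ctx != "undefined")[1:20]) {
    expect_equal(as.character(ctx[t]),
                 paste0("prev_", tab$outcome[t - 1], "_", tab$choice[t - 1]))
  }
  # handmade checks of the definition
  mini <- tab[1:2, ]
  mini$choice[1] <- "right"; mini$outcome[1] <- "correct"
  mini$category[1] <- "high"; mini$stimulus_rate_hz[1] <- 16L
  mini$completed[1] <- TRUE
  expect_equal(as.character(derive_history_context(mini))[2],
               "prev_correct_right")
  mini$completed[1] <- FALSE
  expect_equal(as.character(derive_history_context(mini))[2], "undefined")
  expect_equal(as.character(derive_history_context(tab[5, , drop = FALSE])),
               "undefined")
  expect_error(derive_history_context(tab[0, ]), "empty")
})

test_that("trial-table validation enforces the outcome rule and schema", {
  tab <- simulate_behavior(agent_params(), 50, seed = 2)
  expect_silent(validate_trial_table(tab))
  bad <- tab
  i <- which(bad$completed)[1]
  bad$outcome[i] <- ifelse(bad$outcome[i] == "correct", "incorrect", "correct")
  expect_error(validate_trial_table(bad), "outcome rule")
  expect_error(validate_trial_table(tab[, -match("choice", names(tab))]),
               "choice")
  bad2 <- tab; bad2$trial_index <- rev(bad2$trial_index)
  expect_error(validate_trial_table(bad2), "increasing")
})

test_that("canonical phase windows produce the exact timepoint counts", {
  win <- phase_windows()
  counts <- vapply(seq_len(nrow(win)), function(i)
    window_timepoints(win[i, ], 30), 1L)
  expect_equal(counts, c(30L, 39L, 45L, 15L))
})

test_that("alignment extracts windows on the frame grid and drops bounded-out trials", {
  fx <- small_session()
  win <- phase_windows()
  al <- align_activity(fx$session, fx$table, win[win$phase == "early_iti", ])
  expect_equal(dim(al$tensor)[3], 30L)
  expect_equal(dim(al$tensor)[2], nrow(fx$session$activity))
  expect_true(all(al$context %in% history_contexts()))
  # frame-resolution identity: snippet equals the raw activity slice
  i <- 1L
  tr <- which(fx$table$trial_index == al$included_trial_indices[i])
  f0 <- round(fx$table$t_choice_report[tr - 1] * 30)
  expect_equal(al$tensor[i, , ],
               fx$session$activity[, (f0 + 1):(f0 + 30)])
  # a session truncated right after a trial's anchor drops that trial
  short <- fx$session
  short$activity <- short$activity[, seq_len(f0 + 10), drop = FALSE]
  expect_warning(
    al2 <- align_activity(short, fx$table, win[win$phase == "early_iti", ]),
    "bounds")
  expect_false(al$included_trial_indices[i] %in% al2$included_trial_indices)
  expect_error(
    align_activity(fx$session, fx$table,
                   list(phase = "x", anchor_event = "nope", pre = 0, post = 1)),
    "unknown anchor")
})

test_that("concatenated phase grid stacks 129 timepoints per trial", {
  fx <- small_session()
  al <- align_phases(fx$session, fx$table)
  expect_equal(dim(al$tensor)[3], 129L)
  expect_equal(table(al$timepoint_phase)[c("early_iti", "late_iti",
                                           "stimulus", "action")],
               table(factor(rep(c("early_iti", "late_iti", "stimulus", "action"),
                                c(30, 39, 45, 15))))[c("early_iti", "late_iti",
                                                       "stimulus", "action")])
})

test_that("Gaussian smoothing is unit-area and conserves interior signal", {
  x <- matrix(0, 1, 101); x[1, 51] <- 1
  sm <- smooth_rates(x, 1)
  expect_equal(sum(sm), 1, tolerance = 1e-10)
  expect_equal(which.max(sm[1, ]), 51L)
  # constant trace unchanged away from the edges
  cst <- matrix(2.5, 1, 60)
  smc <- smooth_rates(cst, 1)
  expect_equal(smc[1, 10:50], rep(2.5, 41), tolerance = 1e-10)
  # two far-apart impulses: each bump integrates to ~1 (direct-convolution oracle)
  x2 <- matrix(0, 1, 80); x2[1, c(30, 50)] <- 1
  sm2 <- smooth_rates(x2, 1)
  expect_equal(sum(sm2[1, 21:39]), 1, tolerance = 1e-10)
  expect_equal(sum(sm2[1, 41:59]), 1, tolerance = 1e-10)
  k <- dnorm(-4:4); k <- k / sum(k)
  oracle <- rep(0, 80)
  for (c0 in c(30, 50)) oracle[c0 + (-4:4)] <- oracle[c0 + (-4:4)] + k
  expect_equal(sm2[1, ], oracle, tolerance = 1e-12)
  # conservation across random interior-supported signals
  set.seed(8)
  for (i in 1:5) {
    y <- matrix(0, 1, 200); y[1, 31:170] <- rnorm(140)
    expect_equal(sum(smooth_rates(y, 1.7)), sum(y), tolerance = 1e-10)
  }
  expect_error(smooth_rates(matrix(c(1, NA), 1), 1), "non-finite")
})

test_that("sessions round-trip through the on-disk format bit-identically", {
  fx <- small_session()
  dir <- withr::local_tempdir()
  sd <- list(table = fx$table, activity = fx$session$activity,
             frame_rate = 30,
             trial_start_frames = fx$session$trial_start_frames,
             chest_xy = fx$tracking$chest_xy,
             head_angles = fx$tracking$head_angles,
             video_svd = fx$tracking$video_svd,
             motion_svd = fx$tracking$motion_svd,
             meta = list(seed = 11))
  write_session(sd, dir)
  back <- read_session(dir)
  expect_identical(back$activity, unname(fx$session$activity))
  expect_identical(back$chest_xy, unname(fx$tracking$chest_xy))
  expect_identical(back$video_svd, unname(fx$tracking$video_svd))
  expect_equal(back$table$t_choice_report, fx$table$t_choice_report)
  expect_identical(back$table$choice, fx$table$choice)
  expect_equal(back$table$stimulus_events, fx$table$stimulus_events)
  expect_equal(back$frame_rate, 30)

  # schema error names the missing column
  tab2 <- fx$table; tab2$stimulus_events <- NULL
  data.table::fwrite(tab2[, setdiff(names(tab2), "choice")],
                     file.path(dir, "trials.csv"))
  expect_error(read_session(dir), "choice")

  # absent sidecar: defaults with a warning
  dir2 <- withr::local_tempdir()
  write_session(sd, dir2)
  unlink(file.path(dir2, "meta.json"))
  expect_warning(back2 <- read_session(dir2), "sidecar")
  expect_equal(back2$frame_rate, 30)
})
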