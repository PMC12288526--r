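test_that("stimulus trains respect event spacing and feasibility", {
  tr <- generate_stimulus_train(20, seed = 1)
  expect_length(tr, 20)
  expect_true(all(diff(tr) >= 0.040 - 1e-12))
  expect_true(all(tr >= 0 & tr <= 1 - 0.015))
  expect_identical(generate_stimulus_train(0), numeric(0))
  # 25 events still fit (25*0.015 + 24*0.025 = 0.975); 26 do not
  expect_length(generate_stimulus_train(25, seed = 2), 25)
  expect_error(generate_stimulus_train(26), "infeasible")
})

test_that("generated trial tables satisfy the task invariants across seeds", {
  for (s in 1:4) {
    tab <- simulate_behavior(agent_params(), 150, seed = s)
    expect_silent(validate_trial_table(tab))
    expect_false(any(tab$stimulus_rate_hz == 12))
    done <- tab[tab$completed, ]
    expect_true(all(done$t_go_cue - done$t_stim_onset >= 1))
  }
})

test_that("deterministic and unbiased limiting policies behave as designed", {
  # near-infinite stimulus weight: the 12 Hz rule is followed exactly
  tab <- simulate_behavior(agent_params(beta_stim = 50, beta_hist = rep(0, 4)),
                           400, seed = 3)
  expect_equal(mean(tab$outcome[tab$completed] == "correct"), 1)
  # flat agent: choices are fair coin flips
  tab0 <- simulate_behavior(
    agent_params(beta0 = 0, beta_stim = 0, beta_hist = rep(0, 4),
                 p_early_withdrawal = 0),
    4000, seed = 4)
  pr <- mean(tab0$choice == "right")
  expect_lt(abs(pr - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("conditional choice probabilities match the generative logistic model", {
  agent <- agent_params(beta0 = 0.1, beta_stim = 2,
                        beta_hist = c(-0.8, -0.2, 0.3, 0.9),
                        p_early_withdrawal = 0)
  n <- 12000
  tab <- simulate_behavior(agent, n, seed = 5)
  ctx <- derive_history_context(tab)
  x <- scale_stimulus_rate(tab$stimulus_rate_hz)
  for (cc in history_contexts()) {
    sel <- as.character(ctx) == cc
    p_model <- plogis(agent$beta0 + agent$beta_stim * x[sel] +
                        agent$beta_hist[[cc]])
    obs <- mean(tab$choice[sel] == "right")
    expect_lt(abs(obs - mean(p_model)),
              4 * sqrt(mean(p_model * (1 - p_model)) / sum(sel)))
  }
})

test_that("context frequencies approach the Markov-chain stationary distribution", {
  agent <- agent_params(beta0 = 0, beta_stim = 1.5,
                        beta_hist = c(-0.6, -0.1, 0.1, 0.6),
                        p_early_withdrawal = 0)
  # transition oracle over the 4 context states, marginalizing the 8 rates
  rates <- stimulus_rates(); x <- scale_stimulus_rate(rates)
  high <- rates > 12
  P <- matrix(0, 4, 4, dimnames = list(history_contexts(), history_contexts()))
  for (ci in 1:4) {
    pr <- plogis(agent$beta0 + agent$beta_stim * x + agent$beta_hist[[ci]])
    # next context = (outcome, choice) of the current trial
    p_cr <- mean(pr * high)            # right & correct
    p_ir <- mean(pr * !high)           # right & incorrect
    p_cl <- mean((1 - pr) * !high)     # left & correct
    p_il <- mean((1 - pr) * high)      # left & incorrect
    P[ci, ] <- c(p_cl, p_il, p_ir, p_cr)
  }
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  tab <- simulate_behavior(agent, 20000, seed = 6)
  ctx <- derive_history_context(tab)
  emp <- as.numeric(table(ctx)[history_contexts()]) / sum(ctx != "undefined")
  expect_lt(max(abs(emp - stat)), 0.02)
})

test_that("chest trajectories stay in the arena and approach the chosen port", {
  fx <- small_session()
  chest <- fx$tracking$chest_xy
  expect_true(all(chest >= 0 & chest <= 20))
  ports <- port_locations()
  tab <- fx$table[fx$table$completed, ]
  d_at <- function(times, port_xy) {
    f <- pmin(round(times * 30) + 1, nrow(chest))
    sqrt(rowSums((chest[f, , drop = FALSE] -
                    matrix(port_xy, length(f), 2, byrow = TRUE))^2))
  }
  d_report <- mean(vapply(seq_len(nrow(tab)), function(i)
    d_at(tab$t_choice_report[i],
         ports[ifelse(tab$choice[i] == "right", "right", "left"), ]),
    numeric(1)))
  d_init <- mean(vapply(seq_len(nrow(tab)), function(i)
    d_at(tab$t_init[i],
         ports[ifelse(tab$choice[i] == "right", "right", "left"), ]),
    numeric(1)))
  expect_lt(d_report, d_init)
})

test_that("uncoupled latent factors are independent of task events", {
  tab <- simulate_behavior(agent_params(), 120, seed = 7)
  tr0 <- simulate_tracking(tab, seed = 8, n_components = 4, coupling = 0)
  speed <- c(0, sqrt(rowSums(diff(tr0$chest_xy)^2)))
  cors <- abs(cor(tr0$latent$factors, speed))
  expect_lt(max(cors), 0.1)
  expect_lt(max(abs(colMeans(tr0$latent$factors))), 1e-10)
})

test_that("simulated neurons reflect their ground-truth tuning", {
  cfg <- compact_config()
  tab <- simulate_behavior(agent_params(), 100, seed = 9)
  tracking <- simulate_tracking(tab, seed = 10, n_components = 4)
  # all-zero tuning, zero noise: silent population
  tun0 <- random_tuning(cfg, 3, tuned_frac = 0, noise_sd = 0, seed = 11)
  tun0$weights <- lapply(tun0$weights, function(w) w * 0)
  neur0 <- simulate_neural(tab, tracking, tun0, cfg)
  expect_equal(max(abs(neur0$session$activity)), 0)
  # a single prev_correct_right kernel drives activity only on those trials
  tun1 <- tun0
  tun1$weights$hist_prev_correct_right[, 1] <- 1
  neur1 <- simulate_neural(tab, tracking, tun1, cfg)
  al <- align_activity(neur1$session, tab,
                       compact_windows()[1, ])
  m_by_ctx <- tapply(rowMeans(al$tensor[, 1, ]), al$context, mean)
  expect_gt(m_by_ctx[["prev_correct_right"]], 0.5)
  expect_equal(max(abs(m_by_ctx[setdiff(history_contexts(),
                                        "prev_correct_right")])), 0)
  # mismatched shapes are rejected
  tun_bad <- tun0
  tun_bad$weights$chest <- tun_bad$weights$chest[-1, , drop = FALSE]
  expect_error(simulate_neural(tab, tracking, tun_bad, cfg), "shape")
})

test_that("generator parameters round-trip through the session format", {
  fx <- small_session()
  dir <- withr::local_tempdir()
  sd <- list(table = fx$table, activity = fx$session$activity,
             frame_rate = 30, trial_start_frames = fx$session$trial_start_frames,
             meta = list(seed = 11, agent = unclass(agent_params())))
  write_session(sd, dir)
  back <- read_session(dir)
  expect_equal(unlist(back$meta$agent$beta_hist),
               unname(unclass(agent_params())$beta_hist))
  expect_equal(back$meta$seed, 11)
})
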