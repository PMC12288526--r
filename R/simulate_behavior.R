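#' Parameters of a simulated decision-making agent
#'
#' The agent chooses the right port with probability
#' `sigmoid(beta0 + beta_stim * x + beta_hist[context])`, where
#' `x = (rate - 12) / 8` is the scaled stimulus rate (-1 at 4 Hz, +1 at
#' 20 Hz) and `context` is the previous completed trial's choice-outcome
#' combination. A context term is only applied when the immediately
#' preceding trial was completed.
#'
#' @param beta0 Log-odds intercept (right-side bias at 12 Hz).
#' @param beta_stim Weight on the scaled stimulus rate.
#' @param beta_hist Numeric 4-vector of context weights in the order of
#'   [history_contexts()].
#' @param p_early_withdrawal Per-trial probability of leaving the center
#'   port before the go cue (incomplete trial).
#' @return List of class `"agent_params"`.
#' @export
agent_params <- function(beta0 = 0, beta_stim = 2.0,
                         beta_hist = c(-0.8, -0.2, 0.3, 0.9),
                         p_early_withdrawal = 0.15) {
  stopifnot(length(beta_hist) == 4L,
            all(is.finite(c(beta0, beta_stim, beta_hist))),
            p_early_withdrawal >= 0, p_early_withdrawal <= 1)
  structure(list(beta0 = beta0, beta_stim = beta_stim,
                 beta_hist = stats::setNames(beta_hist, history_contexts()),
                 p_early_withdrawal = p_early_withdrawal),
            class = "agent_params")
}

#' Scale a stimulus rate to the regression coding
#' @param rate_hz Stimulus rate(s) in events/s.
#' @return `(rate_hz - 12) / 8`, so 4 Hz maps to -1 and 20 Hz to +1.
#' @export
scale_stimulus_rate <- function(rate_hz) (rate_hz - RATE_BOUNDARY) / 8

#' Generate one pseudo-random stimulus train
#'
#' Draws `n_events` event onsets uniformly among all configurations that fit
#' 15-ms events separated by at least 25 ms within a 1-s train (consecutive
#' onsets at least 40 ms apart, last onset by 0.985 s). Sampling uses the
#' order-statistics construction: sorted uniforms on the slack interval plus
#' the minimum spacings, which is exact-uniform over the feasible set.
#'
#' @param n_events Number of events; 0 returns an empty train. Feasibility
#'   requires `n_events * 0.015 + (n_events - 1) * 0.025 <= 1`.
#' @param seed Optional RNG seed.
#' @return Numeric vector of onset times (seconds from train start).
#' @export
generate_stimulus_train <- function(n_events, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_events <- as.integer(n_events)
  if (n_events == 0L) return(numeric(0))
  stopifnot(n_events > 0L)
  event_len <- 0.015; min_gap <- 0.025
  if (n_events * event_len + (n_events - 1L) * min_gap > 1)
    stop("infeasible stimulus train: ", n_events,
         " events of 15 ms with 25 ms gaps exceed 1 s")
  slack <- 1 - event_len - (n_events - 1L) * (event_len + min_gap)
  u <- sort(stats::runif(n_events, 0, slack))
  u + (seq_len(n_events) - 1L) * (event_len + min_gap)
}

#' Simulate a behavioral session
#'
#' Generates a trial table from the rate-discrimination task: stimulus rates
#' drawn uniformly from the 8 admissible values (12 Hz never presented),
#' choices from the agent's logistic policy with trial-history terms,
#' outcomes from the 12 Hz category rule, and early withdrawals drawn
#' independently. Event times follow the task structure: center poke, brief
#' delay, 1-s stimulus train, a wait of 1 s plus an exponential delay, go
#' cue, center-port exit, side-port choice report, and outcome end (reward
#' port exit after correct choices, end of the 2-s timeout after errors).
#'
#' @param agent [agent_params()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional RNG seed.
#' @param wait_delay_mean Mean of the exponential wait delay added to the
#'   1-s minimum center fixation (seconds).
#' @param iti_range Inter-trial interval range (uniform, seconds).
#' @return A validated trial table (see [validate_trial_table()]) with a
#'   `stimulus_events` list column.
#' @export
simulate_behavior <- function(agent, n_trials, seed = NULL,
                              wait_delay_mean = 0.2, iti_range = c(2, 4)) {
  stopifnot(inherits(agent, "agent_params"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  rates <- sample(stimulus_rates(), n_trials, replace = TRUE)
  x <- scale_stimulus_rate(rates)
  withdraw <- stats::runif(n_trials) < agent$p_early_withdrawal

  choice <- character(n_trials); outcome <- character(n_trials)
  t_init <- t_stim <- t_go <- t_exit <- t_report <- t_end <- rep(NA_real_, n_trials)
  events <- vector("list", n_trials)
  ctx_term <- 0; clock <- 5.0
  prev_completed <- FALSE; prev_choice <- NA; prev_outcome <- NA
  for (i in seq_len(n_trials)) {
    t_init[i] <- clock
    t_stim[i] <- clock + 0.05
    events[[i]] <- generate_stimulus_train(rates[i])
    if (withdraw[i]) {
      choice[i] <- "none"; outcome[i] <- "undefined"
      t_exit[i] <- t_stim[i] + stats::runif(1, 0.2, 0.95)
      t_end[i] <- t_exit[i] + 2.0  # white-noise timeout
      prev_completed <- FALSE
    } else {
      ctx_term <- if (prev_completed)
        agent$beta_hist[[paste0("prev_", prev_outcome, "_", prev_choice)]] else 0
      p_right <- stats::plogis(agent$beta0 + agent$beta_stim * x[i] + ctx_term)
      choice[i] <- if (stats::runif(1) < p_right) "right" else "left"
      high <- rates[i] > RATE_BOUNDARY
      outcome[i] <- if ((high && choice[i] == "right") ||
                        (!high && choice[i] == "left")) "correct" else "incorrect"
      t_go[i] <- t_stim[i] + 1 + stats::rexp(1, rate = 1 / wait_delay_mean)
      t_exit[i] <- t_go[i] + stats::runif(1, 0.25, 0.5)
      t_report[i] <- t_exit[i] + stats::runif(1, 0.35, 0.8)
      # outcome end: reward-port exit (correct) or end of 2-s timeout; both
      # kept >= 2 s after the report so the canonical phase windows never
      # overlap on the frame grid
      t_end[i] <- if (outcome[i] == "correct")
        t_report[i] + stats::runif(1, 2.0, 2.6) else t_report[i] + 2.0
      prev_completed <- TRUE; prev_choice <- choice[i]; prev_outcome <- outcome[i]
    }
    clock <- t_end[i] + stats::runif(1, iti_range[1], iti_range[2])
  }
  tab <- data.frame(
    trial_index = seq_len(n_trials),
    stimulus_rate_hz = rates,
    category = ifelse(rates < RATE_BOUNDARY, "low", "high"),
    choice = choice, outcome = outcome, completed = !withdraw,
    t_init = t_init, t_stim_onset = t_stim, t_go_cue = t_go,
    t_center_exit = t_exit, t_choice_report = t_report, t_outcome_end = t_end,
    stringsAsFactors = FALSE
  )
  tab$stimulus_events <- events
  validate_trial_table(tab)
  tab
}
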