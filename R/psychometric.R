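#' Psychometric function parameters
#'
#' Four-parameter cumulative-Gaussian psychometric model of the probability
#' of a rightward choice as a function of stimulus rate:
#' `P(right | x) = gamma + (1 - gamma - lambda) * Phi(beta * (x - alpha))`,
#' with perceptual bias `alpha` (Hz), sensitivity `beta` (1/Hz), and lower /
#' upper lapse rates `gamma`, `lambda`.
#'
#' @param alpha Bias (Hz; the rate of subjective equality absent lapses).
#' @param beta Sensitivity (> 0, 1/Hz).
#' @param gamma,lambda Lower and upper lapse rates in `[0, 1)`,
#'   `gamma + lambda < 1`.
#' @return List of class `"psychometric_params"`.
#' @export
psychometric_params <- function(alpha, beta, gamma = 0, lambda = 0) {
  stopifnot(beta > 0, gamma >= 0, lambda >= 0, gamma + lambda < 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
            class = "psychometric_params")
}

#' Evaluate the psychometric function
#'
#' The cumulative-Gaussian integral has the closed form
#' `Phi(beta * (x - alpha))` with `Phi` the standard normal CDF, so the
#' curve is bounded in `[gamma, 1 - lambda]` and monotone nondecreasing
#' in `x`.
#'
#' @param p [psychometric_params()].
#' @param x Stimulus rate(s) in Hz.
#' @return Probability of a rightward choice.
#' @export
psychometric_eval <- function(p, x) {
  p$gamma + (1 - p$gamma - p$lambda) * stats::pnorm(p$beta * (x - p$alpha))
}

#' Fit the psychometric function by maximum likelihood
#'
#' Bernoulli maximum-likelihood fit of the four parameters on completed
#' trials, with bounded L-BFGS-B optimization and a small multistart grid.
#' Optionally restricted to trials with a given trial-history context
#' (predecessor completed), which is how history-conditioned curves are
#' estimated.
#'
#' @param table Trial table.
#' @param context Optional context label from [history_contexts()].
#' @param min_trials Minimum trials required (default 20).
#' @return [psychometric_params()] with attributes `n_trials`,
#'   `log_likelihood` and `flagged` (TRUE when a lapse parameter sits at its
#'   bound, indicating a degenerate responder).
#' @export
fit_psychometric <- function(table, context = NULL, min_trials = 20) {
  keep <- table$completed
  if (!is.null(context)) {
    stopifnot(context %in% history_contexts())
    ctx <- derive_history_context(table)
    keep <- keep & as.character(ctx) == context
  }
  x <- table$stimulus_rate_hz[keep]
  y <- as.integer(table$choice[keep] == "right")
  if (length(x) < min_trials)
    stop("too few trials to fit a psychometric function (",
         length(x), " < ", min_trials, ")")
  if (length(unique(x)) < 2L)
    stop("need at least 2 distinct stimulus rates, got ", length(unique(x)))

  nll <- function(par) {
    pr <- par[3] + (1 - par[3] - par[4]) * stats::pnorm(par[2] * (x - par[1]))
    pr <- pmin(pmax(pr, 1e-9), 1 - 1e-9)
    -sum(y * log(pr) + (1 - y) * log(1 - pr))
  }
  lower <- c(min(x) - 8, 1e-3, 0, 0)
  upper <- c(max(x) + 8, 10, 0.499, 0.499)
  starts <- expand.grid(alpha = c(10, 12, 14), beta = c(0.1, 0.4, 1.5),
                        gamma = 0.02, lambda = 0.02)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                            lower = lower, upper = upper), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed from every start")
  p <- psychometric_params(best$par[1], best$par[2], best$par[3], best$par[4])
  attr(p, "n_trials") <- length(x)
  attr(p, "log_likelihood") <- -best$value
  attr(p, "flagged") <- best$par[3] > 0.45 || best$par[4] > 0.45 ||
    best$par[2] >= upper[2] - 1e-6
  p
}
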