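test_that("psychometric evaluation equals the closed-form cumulative Gaussian", {
  p <- psychometric_params(12, 0.3)
  # numeric integral of the Gaussian integrand equals Phi(beta * (x - alpha))
  for (x in c(6, 10, 12, 16, 20)) {
    num <- integrate(function(u) p$beta / sqrt(2 * pi) *
                       exp(-p$beta^2 * (u - p$alpha)^2 / 2),
                     -Inf, x, rel.tol = 1e-10)$value
    expect_equal(psychometric_eval(p, x), num, tolerance = 1e-8)
  }
  expect_equal(psychometric_eval(p, 12), 0.5)
  expect_equal(psychometric_eval(psychometric_params(12, 0.3, 0.1, 0.05), 1e6),
               0.95)
  expect_equal(psychometric_eval(psychometric_params(12, 0.3, 0.1, 0.05), -1e6),
               0.1)
})

test_that("psychometric curves are bounded and monotone for random parameters", {
  set.seed(21)
  x <- seq(0, 24, by = 0.5)
  for (i in 1:10) {
    p <- psychometric_params(runif(1, 8, 16), runif(1, 0.05, 2),
                             runif(1, 0, 0.3), runif(1, 0, 0.3))
    v <- psychometric_eval(p, x)
    expect_true(all(diff(v) >= 0))
    expect_true(all(v >= p$gamma - 1e-12 & v <= 1 - p$lambda + 1e-12))
  }
})

test_that("psychometric ML fit recovers generative parameters and flags degeneracy", {
  truth <- psychometric_params(12, 0.25, 0.05, 0.05)
  fit <- fit_psychometric(psychometric_table(truth, 5000, seed = 1))
  expect_lt(abs(fit$alpha - 12), 0.8)
  expect_lt(abs(fit$beta - 0.25), 0.08)
  expect_lt(abs(fit$gamma - 0.05), 0.05)
  expect_lt(abs(fit$lambda - 0.05), 0.05)
  # all-right responder pegs the lower lapse at its bound and is flagged
  tab <- psychometric_table(truth, 300, seed = 2)
  tab$choice <- "right"
  tab$outcome <- ifelse(tab$category == "high", "correct", "incorrect")
  fit2 <- fit_psychometric(tab)
  expect_true(attr(fit2, "flagged"))
  expect_gt(fit2$gamma, 0.4)
  # refusal diagnostics
  tab3 <- psychometric_table(truth, 100, seed = 3)
  tab3$stimulus_rate_hz <- 16L; tab3$category <- "high"
  expect_error(fit_psychometric(tab3), "distinct stimulus rates")
  expect_error(fit_psychometric(psychometric_table(truth, 10, seed = 4)),
               "too few trials")
})

test_that("ridge-penalized logistic matches a direct optimizer oracle", {
  set.seed(31)
  X <- matrix(rnorm(300 * 4), 300, 4)
  y <- rbinom(300, 1, plogis(X %*% c(1, -0.5, 0, 0.8)))
  for (pen in c(1, 10)) {
    co <- trialhist:::ridge_logistic(X, y, pen)[, 1]
    obj <- function(b) {
      eta <- b[1] + X %*% b[-1]
      -sum(y * eta - log1p(exp(eta))) + pen / 2 * sum(b[-1]^2)
    }
    oracle <- optim(rep(0, 5), obj, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))$par
    expect_lt(max(abs(co - oracle)), 2e-4)
  }
})

test_that("majority-class subsampling balances choices exactly", {
  set.seed(41)
  cls <- factor(sample(c("a", "b"), 500, replace = TRUE, prob = c(0.7, 0.3)))
  for (r in 1:5) {
    idx <- trialhist:::.balanced_subsample(cls, seed_round = r)
    expect_equal(unname(table(cls[idx])[["a"]]),
                 unname(table(cls[idx])[["b"]]))
    expect_equal(anyDuplicated(idx), 0L)
  }
})

test_that("history GLM recovers generative weights with a small penalty", {
  agent <- agent_params(beta0 = 0, beta_stim = 2,
                        beta_hist = c(-0.8, -0.2, 0.3, 0.9),
                        p_early_withdrawal = 0.05)
  tab <- simulate_behavior(agent, 8000, seed = 51)
  fit <- fit_history_glm(tab, penalty = 0.01, seed = 52)
  expect_equal(sign(fit$hist_weights), sign(agent$beta_hist))
  expect_equal(order(fit$hist_weights), order(agent$beta_hist))
  expect_gt(fit$stim_weight, max(abs(fit$hist_weights)))
  expect_equal(fit$history_strength, sqrt(sum(fit$hist_weights^2)))
  expect_gt(fit$cv_accuracy, 0.6)
  # the norm is invariant to context ordering
  expect_equal(sqrt(sum(rev(fit$hist_weights)^2)), fit$history_strength)
})

test_that("two-back model zeroes t-2 terms and reparameterizes the context model", {
  agent <- agent_params(beta0 = 0.2, beta_stim = 1.5,
                        beta_hist = c(-0.7, -0.1, 0.2, 0.8),
                        p_early_withdrawal = 0)
  tab <- simulate_behavior(agent, 10000, seed = 61)
  tb <- fit_twoback_glm(tab, penalty = 0.01, seed = 62)
  w2 <- tb$other_weights[c("choice_t2", "outcome_t2", "interaction_t2")]
  expect_lt(max(abs(w2)), 0.12)
  # the t-1 terms span the context dummies: weight differences agree
  hg <- fit_history_glm(tab, penalty = 0.01, seed = 63)
  hw <- hg$hist_weights
  w1 <- tb$other_weights[c("choice_t1", "outcome_t1", "interaction_t1")]
  base <- hw[["prev_incorrect_left"]]
  expect_equal(unname(hw[["prev_correct_left"]] - base),
               unname(w1[["outcome_t1"]]), tolerance = 0.12)
  expect_equal(unname(hw[["prev_incorrect_right"]] - base),
               unname(w1[["choice_t1"]]), tolerance = 0.12)
  expect_equal(unname(hw[["prev_correct_right"]] - base),
               unname(sum(w1)), tolerance = 0.15)
  # constant regressor (all previous outcomes correct) is dropped with warning
  tab_det <- simulate_behavior(agent_params(beta_stim = 50,
                                            beta_hist = rep(0, 4),
                                            p_early_withdrawal = 0),
                               400, seed = 64)
  expect_warning(fit_twoback_glm(tab_det, seed = 65), "constant")
})

test_that("history-performance correlation validates its inputs", {
  agent <- agent_params(p_early_withdrawal = 0)
  fits <- lapply(1:3, function(s)
    fit_history_glm(simulate_behavior(agent, 600, seed = 70 + s),
                    n_subsample_rounds = 3, seed = s))
  accs <- c(0.7, 0.75, 0.8)
  out <- history_performance_correlation(fits, accs)
  expect_true(is.finite(out$r))
  expect_error(history_performance_correlation(fits[1:2], accs[1:2]),
               "at least 3")
  expect_warning(out2 <- history_performance_correlation(
    fits[c(1, 1, 1)], rep(0.7, 3)), "constant")
  expect_true(out2$flagged)
})

test_that("performance declines as generative history strength grows", {
  accs <- vapply(c(0, 1.5, 3), function(h) {
    agent <- agent_params(beta0 = 0, beta_stim = 1.5,
                          beta_hist = h * c(-0.5, -0.5, 0.5, 0.5),
                          p_early_withdrawal = 0)
    tab <- simulate_behavior(agent, 4000, seed = 81)
    mean(tab$outcome == "correct")
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})
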