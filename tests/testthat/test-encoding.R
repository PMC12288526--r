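test_that("design-matrix group layout matches the configuration arithmetic", {
  sizes <- design_group_sizes(design_config())
  expect_equal(unname(sizes[c("head_yaw", "head_pitch", "head_roll")]),
               rep(60L, 3))  # 3 angles x 60 bins of 6 degrees
  expect_equal(unname(sizes[["chest"]]), 256L)  # ceil(20 / 1.28)^2
  expect_equal(unname(sizes[["trial_time"]]), 129L)
  expect_equal(unname(sizes[["poke_left"]]), 46L)  # -0.5 s .. +1 s at 30 fps
  expect_equal(unname(sizes[["stimulus"]]), 16L)   # 0 .. 0.5 s shifts
  expect_equal(unname(sizes[["video"]]), 200L)
})

test_that("built design matrices have indicator structure and orthogonal analogs", {
  fx <- small_session()
  dm <- fx$design
  n_trials <- length(dm$included_trial_indices)
  # each trial-time column is 1 exactly once per trial
  expect_equal(unname(colSums(dm$X[, dm$groups$trial_time])),
               rep(n_trials, length(dm$groups$trial_time)))
  # occupancy groups are one-hot per row
  for (g in c("head_yaw", "head_pitch", "head_roll", "chest"))
    expect_true(all(rowSums(dm$X[, dm$groups[[g]]]) <= 1))
  # kernel groups are binary
  expect_true(all(dm$X[, dm$groups$stimulus] %in% c(0, 1)))
  expect_true(all(dm$X[, dm$groups$poke_center] %in% c(0, 1)))
  # analog columns carry no stimulus-locked component
  cross <- crossprod(dm$X[, dm$groups$stimulus],
                     dm$X[, c(dm$groups$video, dm$groups$motion)])
  expect_lt(max(abs(cross)), 1e-8)
})

test_that("orthogonalization matches the least-squares projection oracle", {
  set.seed(2)
  S <- matrix(rnorm(10 * 3), 10, 3)
  A <- matrix(rnorm(10 * 2), 10, 2)
  out <- orthogonalize_against(A, S)
  oracle <- apply(A, 2, function(a) residuals(lm(a ~ S - 1)))
  expect_equal(out, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  # idempotent, preserves already-orthogonal input, annihilates copies
  expect_equal(orthogonalize_against(out, S), out, tolerance = 1e-10)
  expect_lt(max(abs(orthogonalize_against(S[, 1, drop = FALSE], S))), 1e-10)
  Sd <- cbind(S, S[, 1])  # rank-deficient stimulus block
  expect_warning(out2 <- orthogonalize_against(A, Sd), "dependent")
  expect_lt(max(abs(crossprod(S, out2))), 1e-8)
})

test_that("closed-form ridge agrees with the normal equations and OLS limit", {
  set.seed(3)
  X <- matrix(rnorm(200 * 10), 200, 10)
  Y <- matrix(rnorm(200 * 2), 200, 2)
  W <- ridge_solve(X, Y, 10)
  W_oracle <- solve(crossprod(X) + 10 * diag(10), crossprod(X, Y))
  expect_lt(max(abs(W - W_oracle)), 1e-8)
  W0 <- ridge_solve(X, Y[, 1], 1e-10)
  expect_lt(max(abs(W0 - coef(lm(Y[, 1] ~ X - 1)))), 1e-8)
  # the fast Gram-side factorization used by the CV fit matches too
  fac <- trialhist:::.ridge_factor(X)
  expect_lt(max(abs(trialhist:::.ridge_weights(fac, X, Y, 10) - W_oracle)),
            1e-8)
  Xw <- matrix(rnorm(20 * 50), 20, 50)  # p > n dual path
  expect_lt(max(abs(trialhist:::.ridge_weights(trialhist:::.ridge_factor(Xw),
                                               Xw, Y[1:20, ], 5) -
                      ridge_solve(Xw, Y[1:20, ], 5))), 1e-8)
})

test_that("adding regressors never decreases training fit (nesting)", {
  od <- orthogonal_design(seed = 4)
  y <- od$signal + rnorm(length(od$signal), sd = 0.5)
  sse <- function(cols) {
    X <- od$dm$X[, cols, drop = FALSE]
    sum((y - X %*% ridge_solve(X, y, 1e-8))^2)
  }
  g <- od$dm$groups
  expect_lte(sse(c(g$trial_time, g$group_a)), sse(g$trial_time) + 1e-8)
  expect_lte(sse(unlist(g)), sse(c(g$trial_time, g$group_a)) + 1e-8)
})

test_that("noiseless generative neurons are refit to R^2 ~ 1 held out", {
  fx <- small_session()
  tun <- random_tuning(compact_config(), 3, noise_sd = 0, seed = 21)
  neur <- simulate_neural(fx$table, fx$tracking, tun, compact_config(),
                          keep_design = TRUE)
  act <- activity_at_rows(neur$session, neur$design)
  fit <- fit_ridge_cv(neur$design, act, seed = 22)
  expect_true(all(fit$r2_full >= 0.999))
  trr <- time_resolved_r2(fit, neur$design)
  expect_gt(min(trr, na.rm = TRUE), 0.98)
})

test_that("time-resolved R^2 masks degenerate timepoints", {
  od <- orthogonal_design(n_trials = 30, n_tp = 6, seed = 5)
  y <- matrix(od$signal + rnorm(length(od$signal), sd = 0.3))
  fit <- fit_ridge_cv(od$dm, y, folds = 5, seed = 6, final_weights = FALSE)
  # constant activity at one timepoint: zero across-trial variance -> NA
  y2 <- y
  y2[od$dm$timepoint == 3] <- 7
  fit2 <- fit_ridge_cv(od$dm, y2, folds = 5, seed = 6, final_weights = FALSE)
  trr <- time_resolved_r2(fit2, od$dm)
  expect_true(is.na(trr[3, 1]))
  expect_false(anyNA(trr[-3, 1]))
})

test_that("orthogonal designs give matching unique and maximal EV", {
  od <- orthogonal_design(n_trials = 150, n_tp = 12, seed = 7)
  set.seed(8)
  y <- matrix(od$signal + rnorm(length(od$signal), sd = 0.3))
  vp <- variance_partition(od$dm, y, folds = 5, seed = 9)
  a <- "group_a"
  expect_lt(abs(vp$unique_ev[a, 1] - vp$max_ev[a, 1]), 0.02)
  # substantial variance attributed to the driving group (the trial-time
  # intercept captures the across-trial mean of the kernel, so maxEV is
  # bounded below R^2_full by construction)
  expect_gt(vp$max_ev[a, 1], 0.3)
  # the inert group explains nothing
  expect_lt(abs(vp$max_ev["group_b", 1]), 0.02)
  expect_lt(abs(vp$unique_ev["group_b", 1]), 0.02)
  # partition bound on an orthogonalized design
  expect_lte(sum(vp$unique_ev[, 1]), vp$r2_full[1] + 0.05)
  expect_error(variance_partition(od$dm, y, variables = "nonexistent"),
               "nonexistent")
})

test_that("a duplicated group removes unique but not maximal EV", {
  od <- orthogonal_design(n_trials = 150, n_tp = 12, seed = 10,
                          duplicate_a = TRUE)
  set.seed(11)
  y <- matrix(od$signal + rnorm(length(od$signal), sd = 0.3))
  vp <- variance_partition(od$dm, y, folds = 5, seed = 12)
  expect_lt(vp$unique_ev["group_a", 1], 0.01)
  expect_gt(vp$max_ev["group_a", 1], 0.2)
})

test_that("pure-noise neurons have near-zero EV everywhere", {
  od <- orthogonal_design(n_trials = 500, n_tp = 20, seed = 13)
  set.seed(14)
  y <- matrix(rnorm(nrow(od$dm$X)))
  vp <- variance_partition(od$dm, y, folds = 5, seed = 15)
  expect_lt(max(abs(vp$max_ev[, 1])), 0.01)
  expect_lt(max(abs(vp$unique_ev[, 1])), 0.01)
})
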