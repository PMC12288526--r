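#' Ridge-penalized logistic regression at fixed penalties
#'
#' Thin wrapper around glmnet (alpha = 0) parameterized by the penalty `c`
#' of the objective `-loglik(w) + c/2 * ||w||^2` (intercept unpenalized),
#' which maps to `lambda = c / n` in glmnet's per-observation scaling.
#' Columns are used as provided (no internal standardization).
#'
#' @param X Numeric predictor matrix.
#' @param y 0/1 response.
#' @param penalties One or more penalty values `c`.
#' @return Coefficient matrix `(1 + ncol(X)) x length(penalties)` (intercept
#'   first), columns in the order of `penalties`.
#' @keywords internal
ridge_logistic <- function(X, y, penalties) {
  n <- nrow(X)
  # lead with a few larger penalties so the path warm-starts cleanly, then
  # read the requested values off the fitted path (no interpolation)
  lam_fit <- sort(unique(c(penalties, max(penalties) * c(1000, 100, 10))),
                  decreasing = TRUE) / n
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lam_fit, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  co <- as.matrix(stats::coef(fit))
  if (ncol(co) < length(lam_fit))  # path stopped early: tail is converged
    co <- co[, c(seq_len(ncol(co)), rep(ncol(co), length(lam_fit) - ncol(co))),
             drop = FALSE]
  idx <- vapply(penalties / n, function(l) which.min(abs(lam_fit - l)), 1L)
  co[, idx, drop = FALSE]
}

.wrap_seed <- function(x) as.integer(as.numeric(x) %% 2147483647)

.balanced_subsample <- function(cls, seed_round) {
  # subsample every class (without replacement) to the minority count
  set.seed(.wrap_seed(seed_round))
  counts <- table(cls)
  m <- min(counts)
  unlist(lapply(names(counts), function(k) {
    idx <- which(cls == k)
    if (length(idx) > m) sample(idx, m) else idx
  }), use.names = FALSE)
}

#' Fit the trial-history logistic GLM
#'
#' Models the log odds of a rightward choice as
#' `beta0 + beta1 * x_stim + beta2 . x_history`, where `x_stim` is the
#' scaled stimulus rate (`(rate - 12) / 8`) and `x_history` is the one-hot
#' vector over the four trial-history contexts. Only completed trials with a
#' defined context are used. Left- and right-choice trials are balanced by
#' subsampling the majority class; the subsampling is repeated
#' `n_subsample_rounds` times, each followed by `n_folds`-fold
#' cross-validated fits at a fixed L2 penalty. Reported weights are
#' unweighted means over all rounds x folds; `history_strength` is the
#' Euclidean norm of the mean history-weight vector.
#'
#' @param table Trial table.
#' @param penalty L2 penalty (default 1; deliberately not optimized so that
#'   weights are comparable across sessions).
#' @param n_subsample_rounds Majority-class subsampling rounds (default 20).
#' @param n_folds Cross-validation folds (default 10; reduced with a warning
#'   when the minority class is smaller).
#' @param seed RNG seed.
#' @return List of class `"history_glm_fit"`: `intercept`, `stim_weight`,
#'   `hist_weights` (named 4-vector), `history_strength`, `cv_accuracy`,
#'   `weights_per_fit` (rounds*folds x 6 matrix) and `n_trials`.
#' @export
fit_history_glm <- function(table, penalty = 1, n_subsample_rounds = 20,
                            n_folds = 10, seed = 1) {
  ctx <- derive_history_context(table)
  keep <- table$completed & ctx != "undefined"
  dat <- table[keep, ]
  ctx <- factor(as.character(ctx[keep]), levels = history_contexts())
  X <- cbind(stim = scale_stimulus_rate(dat$stimulus_rate_hz),
             stats::model.matrix(~ ctx - 1))
  colnames(X) <- c("stim", history_contexts())
  y <- as.integer(dat$choice == "right")
  .subsampled_cv_glm(X, y, penalty, n_subsample_rounds, n_folds, seed,
                     hist_cols = history_contexts(), n_trials = nrow(dat))
}

.subsampled_cv_glm <- function(X, y, penalty, n_rounds, n_folds, seed,
                               hist_cols, n_trials) {
  minority <- min(sum(y == 1), sum(y == 0))
  if (minority < 2L) stop("one choice class is (nearly) absent")
  if (minority < n_folds) {
    warning("minority class (", minority, ") smaller than n_folds; reducing to ",
            minority, " folds")
    n_folds <- minority
  }
  keep_col <- apply(X, 2, function(v) stats::var(v) > 0)
  if (!all(keep_col))
    warning("dropping constant regressor(s): ",
            paste(colnames(X)[!keep_col], collapse = ", "))
  Xu <- X[, keep_col, drop = FALSE]

  W <- matrix(NA_real_, n_rounds * n_folds, 1L + ncol(Xu))
  acc <- numeric(n_rounds * n_folds)
  r <- 0L
  for (round in seq_len(n_rounds)) {
    idx <- .balanced_subsample(y, seed_round = as.numeric(seed) * 1000 + round)
    Xb <- Xu[idx, , drop = FALSE]; yb <- y[idx]
    fold <- sample(rep_len(seq_len(n_folds), length(idx)))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      co <- ridge_logistic(Xb[tr, , drop = FALSE], yb[tr], penalty)[, 1]
      r <- r + 1L
      W[r, ] <- co
      eta <- co[1] + Xb[!tr, , drop = FALSE] %*% co[-1]
      acc[r] <- mean((eta > 0) == (yb[!tr] == 1))
    }
  }
  W <- W[seq_len(r), , drop = FALSE]
  mw <- colMeans(W)
  names(mw) <- c("(intercept)", colnames(Xu))
  hw <- stats::setNames(rep(NA_real_, length(hist_cols)), hist_cols)
  hw[intersect(hist_cols, colnames(Xu))] <-
    mw[intersect(hist_cols, colnames(Xu))]
  structure(list(
    intercept = mw[["(intercept)"]],
    stim_weight = if ("stim" %in% colnames(Xu)) mw[["stim"]] else NA_real_,
    hist_weights = hw,
    other_weights = mw[setdiff(names(mw), c("(intercept)", "stim", hist_cols))],
    history_strength = sqrt(sum(hw^2, na.rm = TRUE)),
    cv_accuracy = mean(acc[seq_len(r)]),
    weights_per_fit = W, n_trials = n_trials, penalty = penalty
  ), class = "history_glm_fit")
}

#' Fit the two-back choice/outcome GLM
#'
#' Alternative parameterization looking two trials back: regressors for the
#' choice, the outcome and their interaction at trials `t - 1` and `t - 2`
#' (dummy coding right = 1, correct = 1, interaction = right AND correct),
#' plus the scaled stimulus rate. Only trials whose two predecessors were
#' both completed are used; the balancing/CV machinery matches
#' [fit_history_glm()]. Constant regressors (e.g. an all-left choice
#' history) are dropped with a warning.
#'
#' @inheritParams fit_history_glm
#' @return `"history_glm_fit"`-like list whose `other_weights` carry the six
#'   choice/outcome/interaction weights (`choice_t1`, `outcome_t1`,
#'   `interaction_t1`, and `_t2` counterparts).
#' @export
fit_twoback_glm <- function(table, penalty = 1, n_subsample_rounds = 20,
                            n_folds = 10, seed = 1) {
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 trials for the two-back model")
  prev <- function(x, k) c(rep(NA, k), x[seq_len(n - k)])
  ok <- table$completed & prev(table$completed, 1) & prev(table$completed, 2)
  ok[is.na(ok)] <- FALSE
  dat <- table[ok, ]
  ch1 <- as.integer(prev(table$choice, 1)[ok] == "right")
  oc1 <- as.integer(prev(table$outcome, 1)[ok] == "correct")
  ch2 <- as.integer(prev(table$choice, 2)[ok] == "right")
  oc2 <- as.integer(prev(table$outcome, 2)[ok] == "correct")
  X <- cbind(stim = scale_stimulus_rate(dat$stimulus_rate_hz),
             choice_t1 = ch1, outcome_t1 = oc1, interaction_t1 = ch1 * oc1,
             choice_t2 = ch2, outcome_t2 = oc2, interaction_t2 = ch2 * oc2)
  y <- as.integer(dat$choice == "right")
  .subsampled_cv_glm(X, y, penalty, n_subsample_rounds, n_folds, seed,
                     hist_cols = character(0), n_trials = nrow(dat))
}

#' Correlate (stimulus weight - history strength) with performance
#'
#' Across sessions, the difference between the stimulus weight and the
#' history strength is correlated with the fraction of correct completed
#' trials: sessions that weigh trial history more (relative to the
#' stimulus) perform worse in a task whose trial sequence is random.
#'
#' @param fits List of [fit_history_glm()] results (>= 3 sessions).
#' @param accuracies Fraction correct per session (same length).
#' @return List with `r`, `p_value`, `n`, `flagged` (TRUE when an input is
#'   constant and `r` is undefined).
#' @export
history_performance_correlation <- function(fits, accuracies) {
  stopifnot(length(fits) == length(accuracies))
  if (length(fits) < 3L)
    stop("need at least 3 sessions to correlate, got ", length(fits))
  d <- vapply(fits, function(f) f$stim_weight - f$history_strength, numeric(1))
  if (stats::sd(d) == 0 || stats::sd(accuracies) == 0) {
    warning("constant input: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(d), flagged = TRUE))
  }
  ct <- stats::cor.test(d, accuracies)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(d),
       flagged = FALSE)
}
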