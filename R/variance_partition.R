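#' Shuffle a variable's regressors across trials
#'
#' Destroys the alignment between a regressor group and the trial labels by
#' permuting whole-trial blocks of the targeted columns across trials: the
#' rows belonging to trial `i` receive the group's values from trial
#' `perm(i)` at the same timepoints. This preserves the within-trial kernel
#' structure and temporal autocorrelation of the regressors (a plain
#' row-wise permutation would destroy both and overstate unique variance).
#'
#' @param dm `"design_matrix"`.
#' @param cols Column indices to shuffle.
#' @param seed RNG seed for the trial permutation.
#' @return The design matrix `X` with the targeted columns shuffled.
#' @keywords internal
.shuffle_trial_blocks <- function(dm, cols, seed) {
  set.seed(.wrap_seed(seed))
  X <- dm$X
  trials <- unique(dm$trial_id)
  perm <- sample(seq_along(trials))
  # rows indexed by (trial, timepoint); rows of trial i get trial perm(i)
  row_of <- split(seq_len(nrow(X)), match(dm$trial_id, trials))
  for (i in seq_along(trials)) {
    src <- row_of[[perm[i]]][order(dm$timepoint[row_of[[perm[i]]]])]
    dst <- row_of[[i]][order(dm$timepoint[row_of[[i]]])]
    X[dst, cols] <- X[src, cols]
  }
  X
}

.variable_cols <- function(dm, variable) {
  gs <- dm$variables[[variable]]
  if (is.null(gs)) stop("variable not present in the design: ", variable)
  unlist(dm$groups[gs], use.names = FALSE)
}

#' Maximal and unique explained variance per variable
#'
#' Partitions each neuron's held-out explained variance over the task and
#' movement variables of the design:
#'
#' * single-variable models keep one variable (plus the trial-time
#'   intercept group) intact and shuffle all other variables across trials;
#' * the trial-time-only model shuffles everything except trial time;
#' * one-removed models shuffle only the targeted variable.
#'
#' Maximal explained variance of a variable is its single-variable `R^2`
#' minus the trial-time-only `R^2` (temporal fluctuations shared across
#' trials are not credited to the variable); unique explained variance is
#' the full-model `R^2` minus the one-removed `R^2`. Each model re-runs the
#' per-neuron penalty search on the same fold assignment as the full model.
#' Values may be negative and are reported as-is.
#'
#' @param dm `"design_matrix"`.
#' @param activity Rows x neurons matrix aligned with `dm$X`.
#' @param fit Optional full-model [fit_ridge_cv()] result to reuse.
#' @param folds,penalties,seed Passed to [fit_ridge_cv()] (the seed also
#'   fixes the fold assignment shared by all models).
#' @param variables Variables to partition; default all in `dm$variables`.
#' @return List of class `"variance_partition"`: matrices `max_ev` and
#'   `unique_ev` (variables x neurons), vectors `r2_full`, `r2_timeonly`,
#'   and matrices `r2_single`, `r2_oneremoved`.
#' @export
variance_partition <- function(dm, activity, fit = NULL, folds = 10,
                               penalties = 10^(-3:5), seed = 1,
                               variables = names(dm$variables)) {
  for (v in variables) .variable_cols(dm, v)  # validate upfront
  if (is.null(fit))
    fit <- fit_ridge_cv(dm, activity, folds, penalties, seed,
                        final_weights = FALSE)
  refit <- function(X) {
    dm2 <- dm; dm2$X <- X
    fit_ridge_cv(dm2, activity, folds, penalties, seed,
                 final_weights = FALSE)$r2_full
  }
  shuffle_vars <- function(vars, tag) {
    X <- dm$X
    for (i in seq_along(vars)) {
      cols <- .variable_cols(dm, vars[i])
      dm_tmp <- dm; dm_tmp$X <- X
      X <- .shuffle_trial_blocks(dm_tmp, cols,
                                 seed = as.numeric(seed) * 7919 + i * 101 + tag)
    }
    X
  }

  r2_timeonly <- refit(shuffle_vars(variables, tag = 0L))
  q <- length(fit$r2_full)
  r2_single <- matrix(NA_real_, length(variables), q,
                      dimnames = list(variables, NULL))
  r2_oneremoved <- r2_single
  for (vi in seq_along(variables)) {
    v <- variables[vi]
    r2_single[vi, ] <- refit(shuffle_vars(setdiff(variables, v),
                                          tag = vi * 1000L))
    r2_oneremoved[vi, ] <- refit(shuffle_vars(v, tag = vi * 1000L + 500L))
  }
  structure(list(
    max_ev = sweep(r2_single, 2, r2_timeonly),
    unique_ev = sweep(-r2_oneremoved, 2, fit$r2_full, "+"),
    r2_full = fit$r2_full, r2_timeonly = r2_timeonly,
    r2_single = r2_single, r2_oneremoved = r2_oneremoved,
    variables = variables
  ), class = "variance_partition")
}
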