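#' Closed-form ridge regression
#'
#' Solves `argmin_W ||Y - X W||^2 + lambda ||W||^2` for all response columns
#' at once via the thin SVD of `X`, which equals the normal-equations
#' solution `(X'X + lambda I)^-1 X'Y` and remains stable for `p > n` and
#' near-singular designs. No intercept is added; the encoding model's
#' trial-time indicator group plays that role.
#'
#' @param X Design matrix (n x p).
#' @param Y Response matrix (n x q) or vector.
#' @param lambda Ridge penalty (>= 0; 0 gives the least-squares solution
#'   through the pseudoinverse).
#' @return Weight matrix p x q.
#' @export
ridge_solve <- function(X, Y, lambda) {
  Y <- as.matrix(Y)
  sv <- svd(X)
  d <- sv$d
  shrink <- ifelse(d > 0, d / (d^2 + lambda), 0)
  sv$v %*% (shrink * crossprod(sv$u, Y))
}

# Eigendecomposition of the smaller Gram matrix: primal (X'X) when p <= n,
# dual (XX') otherwise. Equivalent to the SVD closed form but much faster on
# tall-and-wide design matrices.
.ridge_factor <- function(X) {
  if (ncol(X) <= nrow(X)) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    list(primal = TRUE, V = e$vectors, ev = pmax(e$values, 0))
  } else {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    list(primal = FALSE, V = e$vectors, ev = pmax(e$values, 0))
  }
}

.ridge_weights <- function(fac, X, Y, lambda) {
  inv <- ifelse(fac$ev + lambda > 0, 1 / (fac$ev + lambda), 0)
  if (fac$primal) {
    fac$V %*% (inv * crossprod(fac$V, crossprod(X, Y)))
  } else {
    crossprod(X, fac$V %*% (inv * crossprod(fac$V, Y)))
  }
}

#' Extract activity rows matching a design matrix
#'
#' @param session Neural session (activity neurons x frames).
#' @param dm `"design_matrix"`.
#' @return Matrix rows x neurons aligned with `dm$X`.
#' @export
activity_at_rows <- function(session, dm) {
  t(session$activity[, dm$frame + 1L, drop = FALSE])
}

.fold_by_timepoint <- function(dm, folds, seed) {
  # per timepoint, deal the trials into folds so every fold samples all
  # trial timepoints equally
  set.seed(seed)
  fold <- integer(nrow(dm$X))
  trials <- unique(dm$trial_id)
  for (t in sort(unique(dm$timepoint))) {
    rows <- which(dm$timepoint == t)
    fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  fold
}

.analog_cols <- function(dm) {
  unlist(dm$groups[intersect(c("video", "motion"), names(dm$groups))],
         use.names = FALSE)
}

#' Cross-validated ridge fit of the per-neuron encoding model
#'
#' Fits every neuron's activity as a linear function of the design matrix
#' with an L2 penalty chosen per neuron and per fold from an exponential
#' grid (default 1e-3 to 1e5) by held-out coefficient of determination.
#' Folds sample all trial timepoints equally. Analog regressor columns
#' (video / motion-energy components) and the activity are standardized
#' with training-fold statistics only. Held-out predictions are retained
#' for every row so that explained variance can be re-assessed per
#' timepoint; `R^2` values are not clamped at zero (negative values are
#' reported as-is).
#'
#' @param dm `"design_matrix"`.
#' @param activity Rows x neurons matrix aligned with `dm$X` (see
#'   [activity_at_rows()]).
#' @param folds Number of CV folds (default 10).
#' @param penalties Ridge penalty grid.
#' @param seed RNG seed (controls the fold assignment).
#' @param final_weights Refit on all rows at each neuron's modal penalty and
#'   return the weight matrix (needed for the geometry analyses).
#' @return List of class `"encoding_fit"`: `r2_full` (per neuron),
#'   `chosen_penalty` (folds x neurons), `predictions` (rows x neurons,
#'   held-out), `weights` (p x neurons or NULL), `fold` assignment, `groups`.
#' @export
fit_ridge_cv <- function(dm, activity, folds = 10, penalties = 10^(-3:5),
                         seed = 1, final_weights = TRUE) {
  X <- dm$X
  Y <- as.matrix(activity)
  if (any(!is.finite(Y))) stop("activity contains non-finite values")
  stopifnot(nrow(Y) == nrow(X))
  q <- ncol(Y)
  fold <- .fold_by_timepoint(dm, folds, seed)
  ana <- .analog_cols(dm)
  preds <- matrix(NA_real_, nrow(X), q)
  chosen <- matrix(NA_real_, folds, q)

  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (length(ana)) {
      st <- .standardize_train(Xtr[, ana, drop = FALSE],
                               Xte[, ana, drop = FALSE])
      Xtr[, ana] <- st$tr; Xte[, ana] <- st$te
    }
    ymu <- colMeans(Y[tr, , drop = FALSE])
    ysd <- apply(Y[tr, , drop = FALSE], 2, stats::sd)
    ysd[ysd == 0 | is.na(ysd)] <- 1
    Ytr <- sweep(sweep(Y[tr, , drop = FALSE], 2, ymu), 2, ysd, "/")

    fac <- .ridge_factor(Xtr)
    if (fac$primal) {
      B <- crossprod(fac$V, crossprod(Xtr, Ytr))   # p x q
      A <- Xte %*% fac$V                           # n_te x p
    } else {
      B <- crossprod(fac$V, Ytr)                   # n_tr x q
      A <- tcrossprod(Xte, Xtr) %*% fac$V          # n_te x n_tr
    }
    Yte <- Y[te, , drop = FALSE]
    best_sse <- rep(Inf, q)
    best_pred <- matrix(NA_real_, sum(te), q)
    for (li in order(penalties, decreasing = TRUE)) {  # ties -> larger penalty
      lam <- penalties[li]
      inv <- ifelse(fac$ev + lam > 0, 1 / (fac$ev + lam), 0)
      Yhat <- A %*% (inv * B)
      Yhat <- sweep(sweep(Yhat, 2, ysd, "*"), 2, ymu, "+")
      sse <- colSums((Yte - Yhat)^2)
      better <- sse < best_sse
      if (any(better)) {
        best_sse[better] <- sse[better]
        best_pred[, better] <- Yhat[, better]
        chosen[f, better] <- lam
      }
    }
    preds[te, ] <- best_pred
  }

  r2_full <- vapply(seq_len(q), function(j) {
    y <- Y[, j]
    1 - sum((y - preds[, j])^2) / sum((y - mean(y))^2)
  }, numeric(1))

  weights <- NULL
  if (final_weights) {
    Xs <- X
    if (length(ana)) {
      mu <- colMeans(X[, ana, drop = FALSE])
      sd <- apply(X[, ana, drop = FALSE], 2, stats::sd)
      sd[sd == 0 | is.na(sd)] <- 1
      Xs[, ana] <- sweep(sweep(X[, ana, drop = FALSE], 2, mu), 2, sd, "/")
    }
    ymu <- colMeans(Y); ysd <- apply(Y, 2, stats::sd)
    ysd[ysd == 0 | is.na(ysd)] <- 1
    Ys <- sweep(sweep(Y, 2, ymu), 2, ysd, "/")
    modal <- apply(chosen, 2, function(v) {
      tb <- table(v)
      as.numeric(names(tb)[which.max(tb)])
    })
    fac <- .ridge_factor(Xs)
    weights <- matrix(NA_real_, ncol(X), q)
    for (lam in unique(modal)) {
      j <- which(modal == lam)
      weights[, j] <- .ridge_weights(fac, Xs, Ys[, j, drop = FALSE], lam)
    }
  }

  structure(list(r2_full = r2_full, chosen_penalty = chosen,
                 predictions = preds, y = Y, weights = weights, fold = fold,
                 groups = dm$groups, penalties = penalties, seed = seed,
                 folds = folds),
            class = "encoding_fit")
}

#' Time-resolved held-out explained variance
#'
#' Re-orders the retained held-out predictions onto the trial-time grid and
#' computes the coefficient of determination separately at each timepoint
#' (across trials). Because the model is fitted and regularized to explain
#' variance across the whole trial, per-timepoint values are bounded above
#' by the full-model fit. Timepoints with fewer than 3 trials or zero
#' across-trial variance are masked (`NA`).
#'
#' @param fit `"encoding_fit"` with retained predictions.
#' @param dm The design matrix the fit was computed on.
#' @return Matrix timepoints x neurons of `R^2(t)`.
#' @export
time_resolved_r2 <- function(fit, dm) {
  stopifnot(!is.null(fit$predictions))
  q <- ncol(fit$predictions)
  tps <- sort(unique(dm$timepoint))
  out <- matrix(NA_real_, length(tps), q)
  for (ti in seq_along(tps)) {
    rows <- which(dm$timepoint == tps[ti])
    if (length(rows) < 3L) next
    for (j in seq_len(q)) {
      y <- fit$y[rows, j]
      ss_tot <- sum((y - mean(y))^2)
      if (ss_tot <= 0) next
      out[ti, j] <- 1 - sum((y - fit$predictions[rows, j])^2) / ss_tot
    }
  }
  out
}
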