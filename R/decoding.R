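#' Specification of the population decoding procedure
#'
#' One-versus-all linear logistic decoders trained per timepoint on
#' class-balanced, standardized population activity. The L2 penalty is
#' optimized on an exponential grid (powers of 10 from 1e-10 to 1e12) by
#' test-set accuracy within each split, ties broken toward the largest
#' penalty. Classes are balanced by majority-class subsampling
#' (`n_subsample_rounds` rounds), each round split `n_splits` times into
#' stratified 80/20 train/test partitions; reported accuracies are means
#' over all rounds and splits.
#'
#' @param penalties Penalty grid (strictly increasing).
#' @param n_subsample_rounds Subsampling rounds (default 20).
#' @param n_splits Random stratified train/test splits per round (default 8).
#' @param train_frac Training fraction per split (default 0.8).
#' @return List of class `"decoder_spec"`.
#' @export
decoder_spec <- function(penalties = 10^seq(-10, 12), n_subsample_rounds = 20,
                         n_splits = 8, train_frac = 0.8) {
  stopifnot(all(diff(penalties) > 0), train_frac > 0, train_frac < 1)
  structure(list(penalties = penalties,
                 n_subsample_rounds = n_subsample_rounds,
                 n_splits = n_splits, train_frac = train_frac),
            class = "decoder_spec")
}

.standardize_train <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  zv <- sd == 0 | is.na(sd)
  if (any(zv)) sd[zv] <- 1  # zero-variance neurons left uncentered in scale
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sd, "/"),
       te = sweep(sweep(Xte, 2, mu), 2, sd, "/"),
       mu = mu, sd = sd, n_zero_var = sum(zv))
}

#' Train trial-history population decoders
#'
#' Fits one-versus-all ridge-logistic decoders at every timepoint of an
#' aligned activity tensor, following [decoder_spec()]: per subsampling
#' round and stratified split, activity is standardized with training-set
#' statistics only, the penalty maximizing 4-class (or k-class) test
#' accuracy on the grid is selected, and held-out predictions are retained
#' per timepoint. A label-shuffled control is fitted in parallel with
#' identical subsamples and splits. Optionally every per-timepoint model is
#' applied to every other timepoint of the same held-out trials to build the
#' cross-temporal generalization matrix (prediction accuracies are averaged
#' over models; coefficients are never averaged).
#'
#' @param aligned `"aligned_activity"` object (or a list with `tensor`
#'   trials x neurons x timepoints).
#' @param labels Factor of class labels per trial; defaults to
#'   `aligned$context`.
#' @param spec [decoder_spec()].
#' @param seed RNG seed.
#' @param balance_by Factor used for balanced subsampling; defaults to
#'   `labels`. For binary previous-choice/outcome decoders pass the 4-class
#'   context here so the nuisance variable stays balanced within each class.
#' @param fit_real,fit_shuffled Toggle the real / label-shuffled fits.
#' @param crosstemporal Also compute the cross-temporal matrix (real labels).
#' @return List of class `"decoding_result"`; see Details. Key elements:
#'   `accuracy_overall` (unweighted mean over timepoints),
#'   `accuracy_by_timepoint`, `accuracy_by_time` (class x timepoint recall),
#'   `confusion_counts` (timepoint x true x predicted),
#'   `crosstemporal` (train time x test time) and `shuffled` (the same
#'   summaries for the control).
#' @export
train_decoders <- function(aligned, labels = NULL, spec = decoder_spec(),
                           seed = 1, balance_by = NULL,
                           fit_real = TRUE, fit_shuffled = TRUE,
                           crosstemporal = FALSE) {
  tensor <- aligned$tensor
  if (is.null(labels)) labels <- aligned$context
  labels <- droplevels(factor(labels))
  stopifnot(length(labels) == dim(tensor)[1])
  if (is.null(balance_by)) balance_by <- labels
  k <- nlevels(labels)
  Tn <- dim(tensor)[3]
  classes <- levels(labels)

  variants <- c(if (fit_real) "real", if (fit_shuffled) "shuffled")
  acc_tp <- stats::setNames(
    lapply(variants, function(v) matrix(0, spec$n_subsample_rounds * spec$n_splits, Tn)),
    variants)
  recall <- stats::setNames(
    lapply(variants, function(v) array(0, c(k, Tn))), variants)
  recall_n <- stats::setNames(
    lapply(variants, function(v) array(0, c(k, Tn))), variants)
  conf <- stats::setNames(
    lapply(variants, function(v) array(0, c(Tn, k, k),
                                       dimnames = list(NULL, classes, classes))),
    variants)
  preds_store <- list()
  ct_sum <- if (crosstemporal) matrix(0, Tn, Tn) else NULL
  ct_n <- 0L

  rs <- 0L
  n_balanced <- NULL
  for (round in seq_len(spec$n_subsample_rounds)) {
    sub <- .balanced_subsample(interaction(balance_by, drop = TRUE),
                               seed_round = as.numeric(seed) * 1000 + round)
    labs <- labels[sub]
    m <- min(table(labs))
    if (m < 8L)
      stop("class too small after balancing: ",
           paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                 collapse = ", "))
    n_balanced <- table(labs)
    set.seed(.wrap_seed(as.numeric(seed) * 1000 + 500 + round))
    labs_sh <- sample(labs)
    for (split in seq_len(spec$n_splits)) {
      set.seed(.wrap_seed(as.numeric(seed) * 100000 + round * 100 + split))
      test_idx <- unlist(lapply(classes, function(cl) {
        idx <- which(labs == cl)
        sample(idx, max(1L, round(length(idx) * (1 - spec$train_frac))))
      }), use.names = FALSE)
      tr_idx <- setdiff(seq_along(sub), test_idx)
      rs <- rs + 1L

      for (v in variants) {
        yl <- if (v == "real") labs else labs_sh
        y_tr <- yl[tr_idx]; y_te <- yl[test_idx]
        coefs <- if (crosstemporal && v == "real")
          array(NA_real_, c(dim(tensor)[2] + 1L, k, Tn)) else NULL
        Zte_all <- if (crosstemporal && v == "real")
          array(NA_real_, c(length(test_idx), dim(tensor)[2], Tn)) else NULL
        pred_mat <- matrix(NA_integer_, Tn, length(test_idx))
        for (t in seq_len(Tn)) {
          Xt <- tensor[sub, , t, drop = TRUE]
          if (is.null(dim(Xt))) Xt <- matrix(Xt, ncol = 1L)
          st <- .standardize_train(Xt[tr_idx, , drop = FALSE],
                                   Xt[test_idx, , drop = FALSE])
          sc <- .ova_scores(st$tr, y_tr, st$te, y_te, classes, spec$penalties)
          pred <- sc$pred
          pred_mat[t, ] <- pred
          acc_tp[[v]][rs, t] <- mean(classes[pred] == y_te)
          for (ci in seq_len(k)) {
            sel <- y_te == classes[ci]
            recall[[v]][ci, t] <- recall[[v]][ci, t] +
              sum(classes[pred[sel]] == classes[ci])
            recall_n[[v]][ci, t] <- recall_n[[v]][ci, t] + sum(sel)
            tb <- tabulate(pred[sel], nbins = k)
            conf[[v]][t, ci, ] <- conf[[v]][t, ci, ] + tb
          }
          if (!is.null(coefs)) {
            coefs[, , t] <- sc$coef
            Zte_all[, , t] <- st$te
          }
        }
        if (v == "real")
          preds_store[[rs]] <- list(true = as.integer(factor(y_te, levels = classes)),
                                    pred = pred_mat)
        if (!is.null(coefs)) {
          # cross-temporal: model at t applied to held-out activity at t2
          C <- matrix(coefs, nrow = dim(coefs)[1])  # (p+1) x (k*Tn)
          y_int <- as.integer(factor(y_te, levels = classes))
          for (t2 in seq_len(Tn)) {
            Z <- matrix(Zte_all[, , t2], nrow = length(test_idx))
            S <- cbind(1, Z) %*% C
            dim(S) <- c(length(test_idx), k, Tn)
            pr <- matrix(NA_integer_, length(test_idx), Tn)
            for (tm in seq_len(Tn))
              pr[, tm] <- max.col(matrix(S[, , tm], ncol = k),
                                  ties.method = "first")
            ct_sum[, t2] <- ct_sum[, t2] + colMeans(pr == y_int)
          }
          ct_n <- ct_n + 1L
        }
      }
    }
  }

  summarize <- function(v) {
    list(accuracy_by_timepoint = colMeans(acc_tp[[v]][seq_len(rs), , drop = FALSE]),
         accuracy_overall = mean(acc_tp[[v]][seq_len(rs), ]),
         accuracy_by_time = recall[[v]] / pmax(recall_n[[v]], 1),
         confusion_counts = conf[[v]])
  }
  out <- list(classes = classes, spec = spec, n_balanced = n_balanced,
              predictions = preds_store,
              crosstemporal = if (crosstemporal) ct_sum / ct_n else NULL)
  if (fit_real) out <- c(out, summarize("real"))
  if (fit_shuffled) out$shuffled <- summarize("shuffled")
  structure(out, class = "decoding_result")
}

# One-vs-all linear logistic scores with per-split penalty optimization.
# The penalty grid is traversed in decreasing order, so `which.max` on the
# accuracy vector breaks ties toward the largest penalty; the argmax over
# class scores breaks ties by fixed class order.
.ova_scores <- function(Xtr, ytr, Xte, yte, classes, penalties) {
  k <- length(classes)
  n <- nrow(Xtr)
  lam <- sort(penalties, decreasing = TRUE) / n
  nl <- length(lam)
  pad <- ncol(Xtr) == 1L  # glmnet needs >= 2 columns
  Xtr1 <- if (pad) cbind(Xtr, 0) else Xtr
  Xte1 <- if (pad) cbind(Xte, 0) else Xte
  scores <- array(NA_real_, c(nrow(Xte), k, nl))
  coef_all <- array(NA_real_, c(ncol(Xtr1) + 1L, k, nl))
  for (ci in seq_len(k)) {
    yb <- as.integer(ytr == classes[ci])
    # glmnet advises when a one-vs-all positive class is small (class sizes
    # are guarded upstream) and when the path stalls at the near-unpenalized
    # tail of the grid on separable data (the converged head of the path is
    # used; see the early-stop padding below) -- both are expected here
    fit <- withCallingHandlers(
      glmnet::glmnet(Xtr1, yb, family = "binomial", alpha = 0,
                     lambda = lam, standardize = FALSE, maxit = 1e5),
      warning = function(w) {
        if (grepl("fewer than 8|Convergence", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    co <- as.matrix(stats::coef(fit))
    if (ncol(co) < nl)  # path stopped early: tail is converged
      co <- co[, c(seq_len(ncol(co)), rep(ncol(co), nl - ncol(co))),
               drop = FALSE]
    scores[, ci, ] <- cbind(1, Xte1) %*% co
    coef_all[, ci, ] <- co
  }
  acc <- vapply(seq_len(nl), function(li) {
    pred <- max.col(matrix(scores[, , li], ncol = k), ties.method = "first")
    mean(classes[pred] == yte)
  }, numeric(1))
  best <- which.max(acc)
  pred <- max.col(matrix(scores[, , best], ncol = k), ties.method = "first")
  co <- coef_all[, , best, drop = TRUE]
  co <- matrix(co, ncol = k)
  if (pad) co <- co[-nrow(co), , drop = FALSE]
  list(pred = pred, coef = co, penalty = sort(penalties, decreasing = TRUE)[best])
}

#' Row-normalized confusion tensor over trial time
#'
#' Converts the aggregated confusion counts of a [train_decoders()] result
#' into per-timepoint confusion matrices normalized by the number of true
#' trials per class (rows sum to 1).
#'
#' @param result `"decoding_result"`.
#' @param shuffled Use the shuffled-control counts.
#' @return Array timepoints x true class x predicted class.
#' @export
confusion_over_time <- function(result, shuffled = FALSE) {
  counts <- if (shuffled) result$shuffled$confusion_counts
            else result$confusion_counts
  if (is.null(counts)) stop("no confusion counts in this result")
  out <- counts
  for (t in seq_len(dim(counts)[1])) {
    rs <- rowSums(counts[t, , , drop = TRUE])
    out[t, , ] <- counts[t, , ] / pmax(rs, 1)
  }
  out
}

#' Cross-temporal generalization matrix
#'
#' Trains per-timepoint decoders and tests every model on every other
#' timepoint of the corresponding held-out trials; entry `(t, t2)` is the
#' mean accuracy (over rounds and splits) of time-`t` models applied to
#' time-`t2` activity. The diagonal equals the per-timepoint decoding
#' accuracy. A stable population code yields a uniformly high matrix; a
#' code that reorganizes between phases yields block structure with
#' off-block entries near chance.
#'
#' @inheritParams train_decoders
#' @return Matrix train time x test time.
#' @export
cross_temporal_matrix <- function(aligned, labels = NULL,
                                  spec = decoder_spec(), seed = 1,
                                  balance_by = NULL) {
  res <- train_decoders(aligned, labels, spec, seed, balance_by = balance_by,
                        fit_real = TRUE, fit_shuffled = FALSE,
                        crosstemporal = TRUE)
  res$crosstemporal
}

#' Marginal binary accuracy of a multi-class history decoder
#'
#' Collapses 4-class trial-history predictions and truths onto previous
#' choice (left/right) or previous outcome (correct/incorrect) and scores
#' the fraction of held-out trials classified correctly with respect to
#' that variable alone, ignoring the irrelevant one.
#'
#' @param result `"decoding_result"` from a 4-class history decoder with
#'   retained predictions.
#' @param variable `"prev_choice"` or `"prev_outcome"`.
#' @return Mean binary accuracy over timepoints, rounds and splits.
#' @export
marginal_binary_accuracy <- function(result,
                                     variable = c("prev_choice", "prev_outcome")) {
  variable <- match.arg(variable)
  stopifnot(identical(result$classes, history_contexts()))
  collapse <- if (variable == "prev_choice") c(1L, 1L, 2L, 2L)
              else c(1L, 2L, 2L, 1L)
  accs <- vapply(result$predictions, function(p) {
    mean(collapse[p$pred] == rep(collapse[p$true], each = nrow(p$pred)))
  }, numeric(1))
  mean(accs)
}
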