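#' Dimensionality of a variable's encoding weights
#'
#' Applies principal component analysis across neurons to the encoding
#' weights of one variable (e.g. the four trial-history kernels, the chest
#' occupancy bins, or the video-component loadings) and reports the minimum
#' number of dimensions required to explain a given fraction (default 90%)
#' of the weight variance, together with the principal axes and the
#' projections of the weights into them.
#'
#' @param weights Neurons x features weight matrix.
#' @param threshold Cumulative explained-variance threshold (default 0.90).
#' @return List of class `"variable_geometry"`: `d90`, `evr`
#'   (explained-variance ratios), `axes` (features x components),
#'   `scores` (neurons x components), `center`, `threshold`.
#' @export
pca_dimensionality <- function(weights, threshold = 0.90) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) >= 2L, ncol(weights) >= 2L)
  if (all(apply(weights, 2, stats::var) == 0))
    stop("zero-variance weight matrix: no geometry to extract")
  pc <- stats::prcomp(weights, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  d90 <- which(cumsum(evr) >= threshold - 1e-12)[1]
  structure(list(d90 = as.integer(d90), evr = evr, axes = pc$rotation,
                 scores = pc$x, center = pc$center, threshold = threshold),
            class = "variable_geometry")
}

#' Express sessions' geometries in a common number of dimensions
#'
#' Determines the maximal dimensionality (`d90`) across sessions for one
#' variable and returns every session's principal-axis shape truncated (or
#' extended) to that number of top dimensions, as required before Procrustes
#' comparison.
#'
#' @param geometries List of [pca_dimensionality()] results (>= 1).
#' @return List with `n_dims` and `shapes` -- one features x `n_dims` matrix
#'   per session (rows are the timepoint/bin coordinates of the dynamics,
#'   columns the matched principal dimensions).
#' @export
match_dimensions <- function(geometries) {
  stopifnot(length(geometries) >= 1L)
  d <- max(vapply(geometries, `[[`, integer(1), "d90"))
  shapes <- lapply(geometries, function(g) {
    if (ncol(g$axes) < d)
      stop("session has fewer principal dimensions (", ncol(g$axes),
           ") than the matched dimensionality (", d, ")")
    g$axes[, seq_len(d), drop = FALSE]
  })
  list(n_dims = d, shapes = shapes)
}

#' Procrustes match between two shapes
#'
#' Finds the translation, orthogonal rotation (reflections allowed by
#' default) and scale minimizing the squared Euclidean distance
#' `||X2 - b * X1 %*% Gamma - 1 kappa'||^2`. Both shapes are standardized
#' first (column-centered, unit Frobenius norm) so the residual disparity is
#' bounded: 0 for identical shapes up to a similarity transform, 1 for
#' maximally dissimilar shapes.
#'
#' Rows are the matched points (timepoints of the dynamics, or spatial
#' bins), columns the matched principal dimensions; the rotation therefore
#' acts on the dimension axes and absorbs axis-order and sign mismatches
#' between sessions.
#'
#' @param X1 Shape being matched (n x m).
#' @param X2 Reference shape (same dimensions).
#' @param allow_reflection Permit improper rotations (default `TRUE`).
#' @return List of class `"procrustes_match"`: `scale` (b), `rotation`
#'   (Gamma, m x m orthogonal), `translation` (kappa), `disparity` in
#'   `[0, 1]`.
#' @export
procrustes_match <- function(X1, X2, allow_reflection = TRUE) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  stopifnot(identical(dim(X1), dim(X2)))
  std <- function(X) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    nf <- sqrt(sum(Xc^2))
    if (nf == 0) stop("degenerate (zero-norm) shape")
    list(X = Xc / nf, mu = mu, norm = nf)
  }
  s1 <- std(X1); s2 <- std(X2)
  M <- crossprod(s1$X, s2$X)        # m x m
  sv <- svd(M)
  rot <- sv$u %*% t(sv$v)
  d <- sv$d
  if (!allow_reflection && det(rot) < 0) {
    u <- sv$u; u[, ncol(u)] <- -u[, ncol(u)]
    rot <- u %*% t(sv$v)
    d[length(d)] <- -d[length(d)]
  }
  b <- sum(d)
  disparity <- max(0, 1 - b^2)
  # transform parameters on the standardized scale, mapped back to X1's units
  scale_raw <- b * s2$norm / s1$norm
  translation <- s2$mu - scale_raw * as.numeric(s1$mu %*% rot)
  structure(list(scale = scale_raw, rotation = rot,
                 translation = translation, disparity = disparity),
            class = "procrustes_match")
}

#' Pairwise Procrustes disparities within and across subjects
#'
#' Computes the Procrustes disparity for every unordered pair of sessions'
#' matched shapes and labels each pair as within- or across-subject.
#'
#' @param shapes List of shape matrices with common dimensions (see
#'   [match_dimensions()]).
#' @param subject Subject identifier per session.
#' @param allow_reflection Passed to [procrustes_match()].
#' @return Data frame with `session_i`, `session_j`, `subject_i`,
#'   `subject_j`, `grouping` (`"within_subject"` / `"across_subject"`) and
#'   `disparity`.
#' @export
pairwise_disparity <- function(shapes, subject, allow_reflection = TRUE) {
  stopifnot(length(shapes) == length(subject), length(shapes) >= 2L)
  n <- length(shapes)
  pairs <- utils::combn(n, 2)
  res <- lapply(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    data.frame(
      session_i = i, session_j = j,
      subject_i = subject[i], subject_j = subject[j],
      grouping = if (subject[i] == subject[j]) "within_subject"
                 else "across_subject",
      disparity = procrustes_match(shapes[[i]], shapes[[j]],
                                   allow_reflection)$disparity,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Geometry of a fitted encoding model's variable weights
#'
#' Convenience extractor: pulls one variable's weight block from an
#' [fit_ridge_cv()] result (neurons x features orientation) and runs
#' [pca_dimensionality()].
#'
#' @param fit `"encoding_fit"` with final weights.
#' @param dm The design matrix fitted.
#' @param variable Variable name in `dm$variables`.
#' @param threshold Cumulative variance threshold.
#' @return `"variable_geometry"`.
#' @export
encoding_geometry <- function(fit, dm, variable, threshold = 0.90) {
  stopifnot(!is.null(fit$weights))
  cols <- .variable_cols(dm, variable)
  pca_dimensionality(t(fit$weights[cols, , drop = FALSE]), threshold)
}
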