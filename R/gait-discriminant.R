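#' PCA-then-LDA discriminant mapping of gait parameters
#'
#' Maps a feature table (observations are animals locomoting at a given
#' speed; features are gait parameters) onto linear discriminant axes in
#' three steps: features are z-scored; principal components are obtained
#' by eigendecomposition of the data covariance matrix (descending
#' eigenvalues) and the first `n_pcs` retained, decorrelating the inputs
#' before the discriminant step; linear discriminant analysis is run on
#' the retained scores. The contribution of each original gait parameter
#' to each discriminant axis is recovered by back-projection: the PCA
#' mapping multiplied by the LDA mapping.
#'
#' @param features Numeric matrix or data frame, observations x gait
#'   parameters. Constant columns are dropped with a warning.
#' @param groups Group labels, one per observation (>= 2 groups).
#' @param n_pcs Number of principal components to retain (must be smaller
#'   than the number of observations).
#' @return An object of class `"gait_discriminant"`: `eigenvalues`,
#'   `rotation` (features x PCs), `scores` (obs x PCs), `lda`
#'   (the [MASS::lda()] fit), `projections` (obs x LD axes),
#'   `contributions` (features x LD axes), `var_explained`, `groups`,
#'   `dropped` (names of constant features).
#' @export
discriminant_map <- function(features, groups, n_pcs = 10) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stopf("`features` must be numeric")
  if (any(!is.finite(X))) stopf("features contain non-finite values")
  groups <- as.factor(groups)
  if (length(groups) != nrow(X)) stopf("one group label per observation")
  if (nlevels(droplevels(groups)) < 2L) stopf("need >= 2 groups")
  n_pcs <- assert_count(n_pcs, "n_pcs")
  if (n_pcs >= nrow(X))
    stopf("n_pcs (%d) must be smaller than the number of observations (%d)",
          n_pcs, nrow(X))
  if (is.null(colnames(X)))
    colnames(X) <- paste0("feature", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds < .Machine$double.eps]
  if (length(dropped)) {
    warnf("dropping constant feature(s): %s", paste(dropped, collapse = ", "))
    X <- X[, sds >= .Machine$double.eps, drop = FALSE]
  }
  if (ncol(X) < n_pcs)
    stopf("fewer usable features (%d) than n_pcs (%d)", ncol(X), n_pcs)
  Z <- scale(X)
  eig <- eigen(stats::cov(Z), symmetric = TRUE)
  ord <- order(eig$values, decreasing = TRUE)
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  rownames(vectors) <- colnames(X)
  colnames(vectors) <- paste0("PC", seq_len(ncol(vectors)))
  rot <- vectors[, seq_len(n_pcs), drop = FALSE]
  scores <- Z %*% rot
  fit <- MASS::lda(scores, grouping = droplevels(groups))
  proj <- scores %*% fit$scaling
  contrib <- rot %*% fit$scaling
  structure(list(
    eigenvalues = values, rotation = rot, scores = scores, lda = fit,
    projections = proj, contributions = contrib,
    var_explained = cumsum(values)[n_pcs] / sum(values),
    groups = droplevels(groups), dropped = dropped,
    z = Z), class = "gait_discriminant")
}

#' @export
print.gait_discriminant <- function(x, ...) {
  cat(sprintf(
    paste0("<gait_discriminant> %d obs x %d features -> %d PCs ",
           "(%.0f%% variance) -> %d LD axes; groups: %s\n"),
    nrow(x$scores), nrow(x$rotation), ncol(x$scores),
    100 * x$var_explained, ncol(x$contributions),
    paste(levels(x$groups), collapse = ", ")))
  invisible(x)
}
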