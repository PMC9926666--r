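#' Principal component analysis of unfolded spectra
#'
#' Mean-centered PCA (no variance scaling) via singular value
#' decomposition, with the explained-variance ratio of each component taken
#' against the total variance. Loadings follow a deterministic sign
#' convention: the largest-magnitude element of each loading is positive,
#' so scores are reproducible across platforms.
#'
#' @param X Numeric matrix, rows = observations (spectra).
#' @param n_pc Number of components to keep; at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return Object of class `eem_pca`: list with `n_pc`, `mean`, `loadings`
#'   (features x n_pc, orthonormal), `scores` (rows x n_pc),
#'   `explained_variance_ratio`.
#' @export
pca_fit <- function(X, n_pc) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("at least two rows are required")
  n_pc <- as.integer(n_pc)
  max_pc <- min(n - 1L, ncol(X))
  if (n_pc < 1L || n_pc > max_pc)
    stop("n_pc must lie in [1, ", max_pc, "]")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  for (k in seq_len(n_pc)) {
    imax <- which.max(abs(load[, k]))
    if (load[imax, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(n_pc = n_pc, mean = pc$center, loadings = load,
                 scores = scores,
                 explained_variance_ratio = evr[seq_len(n_pc)]),
            class = "eem_pca")
}

#' @export
print.eem_pca <- function(x, ...) {
  cat(sprintf("PCA: %d component(s); explained variance: %s\n", x$n_pc,
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Project new spectra onto fitted principal components
#' @param object An `eem_pca`.
#' @param newdata Matrix with the model's feature count.
#' @param ... Unused.
#' @return Score matrix (rows x n_pc).
#' @export
predict.eem_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$mean))
    stop("feature count mismatch")
  sweep(newdata, 2L, object$mean) %*% object$loadings
}
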