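#' SIMPLS partial least squares regression (PLS1)
#'
#' Fits a univariate-response PLS regression with de Jong's SIMPLS
#' algorithm: on mean-centered `X` and `y` (no variance scaling), weight
#' vectors maximizing covariance with the response are extracted one at a
#' time, deflating the cross-product vector against an orthonormal basis of
#' the x-loadings. Components are nested: a model fitted with `ncomp`
#' latent variables contains every smaller model.
#'
#' @param X Numeric matrix, rows = observations (spectra), columns =
#'   features.
#' @param y Numeric response vector, `length(y) == nrow(X)`.
#' @param ncomp Number of latent variables; at most `nrow(X) - 1` and at
#'   most the effective rank of centered `X`.
#' @return Object of class `simpls` with components `ncomp`, `x_mean`,
#'   `y_mean`, `weights` (features x ncomp, for scores `T = Xc W`),
#'   `x_loadings`, `y_loadings` (length ncomp), `scores` (training scores,
#'   orthonormal columns), `coefficients` (regression vector at the full
#'   `ncomp`), `fitted.values` and `residuals`.
#' @references de Jong, S. (1993) SIMPLS: an alternative approach to
#'   partial least squares regression. Chemometrics and Intelligent
#'   Laboratory Systems 18, 251-263.
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -2, 0.5) + rnorm(20, sd = 0.01)
#' fit <- simpls(X, y, ncomp = 3)
#' fit
#' max(abs(residuals(fit)))
#' @export
simpls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2L) stop("at least two observations are required")
  if (stats::var(y) == 0) stop("response has zero variance")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("ncomp must be >= 1")
  if (ncomp > n - 1L)
    stop("ncomp (", ncomp, ") exceeds nrow(X) - 1 = ", n - 1L)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  s <- drop(crossprod(Xc, yc))          # covariance direction
  W <- matrix(0, p, ncomp)              # weights (normalized so T is orthonormal)
  P <- matrix(0, p, ncomp)              # x-loadings
  q <- numeric(ncomp)                   # y-loadings
  Tt <- matrix(0, n, ncomp)             # scores
  V <- matrix(0, p, ncomp)              # orthonormal basis of x-loadings
  for (a in seq_len(ncomp)) {
    r <- s
    t_a <- drop(Xc %*% r)
    nt <- sqrt(sum(t_a^2))
    if (!is.finite(nt) || nt < 1e-12 * max(1, sqrt(sum(s^2))) || sum(s^2) == 0)
      stop("X is rank-deficient: at most ", a - 1L,
           " latent variables can be extracted (requested ", ncomp, ")")
    t_a <- t_a / nt
    r <- r / nt
    p_a <- drop(crossprod(Xc, t_a))
    q_a <- sum(yc * t_a)
    v <- p_a
    if (a > 1L) {
      prev <- seq_len(a - 1L)
      v <- v - V[, prev, drop = FALSE] %*%
        crossprod(V[, prev, drop = FALSE], p_a)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * sum(v * s)
    W[, a] <- r; P[, a] <- p_a; q[a] <- q_a
    Tt[, a] <- t_a; V[, a] <- v
  }
  coefs <- drop(W %*% q)
  fitted <- drop(Xc %*% coefs) + y_mean
  structure(list(ncomp = ncomp, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q,
                 scores = Tt, coefficients = coefs,
                 fitted.values = fitted, residuals = y - fitted,
                 y = y, call = match.call()),
            class = "simpls")
}

#' @export
print.simpls <- function(x, ...) {
  cat(sprintf("SIMPLS PLS1 model: %d latent variable(s), %d features, %d training spectra\n",
              x$ncomp, length(x$x_mean), length(x$y)))
  cat(sprintf("Training RMSE: %.6g\n", rmse(x$y, x$fitted.values)))
  invisible(x)
}

#' @export
summary.simpls <- function(object, ...) {
  yc <- object$y - object$y_mean
  expl <- vapply(seq_len(object$ncomp), function(a) {
    yhat <- pls_apply(object, NULL, ncomp = a, .fitted = TRUE)
    1 - sum((object$y - yhat)^2) / sum(yc^2)
  }, numeric(1))
  out <- data.frame(ncomp = seq_len(object$ncomp),
                    y_variance_explained = expl,
                    rmse_train = vapply(seq_len(object$ncomp), function(a)
                      rmse(object$y, pls_apply(object, NULL, ncomp = a,
                                               .fitted = TRUE)), numeric(1)))
  cat("SIMPLS PLS1 model\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Regression coefficients of a SIMPLS model
#' @param object A `simpls` model.
#' @param ncomp Number of latent variables to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric coefficient vector on centered data.
#' @export
coef.simpls <- function(object, ncomp = object$ncomp, ...) {
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  a <- seq_len(ncomp)
  drop(object$weights[, a, drop = FALSE] %*% object$y_loadings[a])
}

#' Apply a SIMPLS model to new spectra
#'
#' Computes `yhat = (X_new - x_mean) %*% coef + y_mean`. Predictions are
#' deliberately not clipped to physically plausible ranges; a PLS model
#' extrapolating outside its calibration span can legitimately return, for
#' example, negative concentrations, and seeing those is diagnostic.
#'
#' @param model A `simpls` model.
#' @param X_new Matrix with the model's feature count.
#' @param ncomp Number of latent variables to use.
#' @param .fitted Internal: return training fitted values.
#' @return Numeric vector of predictions.
#' @export
pls_apply <- function(model, X_new, ncomp = model$ncomp, .fitted = FALSE) {
  stopifnot(inherits(model, "simpls"))
  b <- coef(model, ncomp = ncomp)
  if (.fitted) {
    a <- seq_len(ncomp)
    return(drop(model$scores[, a, drop = FALSE] %*%
                  model$y_loadings[a]) + model$y_mean)
  }
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean))
    stop("X_new has ", ncol(X_new), " features; model expects ",
         length(model$x_mean))
  drop(sweep(X_new, 2L, model$x_mean) %*% b) + model$y_mean
}

#' @export
predict.simpls <- function(object, newdata = NULL, ncomp = object$ncomp, ...) {
  if (is.null(newdata)) return(pls_apply(object, NULL, ncomp, .fitted = TRUE))
  if (inherits(newdata, "regression_dataset")) newdata <- newdata$X
  pls_apply(object, newdata, ncomp = ncomp)
}

#' @export
fitted.simpls <- function(object, ...) object$fitted.values

#' @export
residuals.simpls <- function(object, ...) object$residuals
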