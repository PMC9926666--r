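# Independent oracles used by the tests. These deliberately share no code
# with the package implementation: plain loops and textbook algorithms.

# NIPALS PLS1: successive deflation of X and y; prediction at each
# component count via B = W (P'W)^{-1} q.
nipals_pls1_predict <- function(X, y, ncomp, X_new) {
  xm <- colMeans(X); ym <- mean(y)
  Xd <- sweep(X, 2, xm); yd <- y - ym
  W <- NULL; P <- NULL; qv <- numeric(0)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    p <- drop(crossprod(Xd, tt)) / t2
    q <- sum(yd * tt) / t2
    Xd <- Xd - tcrossprod(tt, p)
    yd <- yd - tt * q
    W <- cbind(W, w); P <- cbind(P, p); qv <- c(qv, q)
  }
  B <- W %*% solve(crossprod(P, W), qv)
  drop(sweep(X_new, 2, xm) %*% B) + ym
}

# minimum-norm least squares on centered data via SVD pseudoinverse
minnorm_ls_coef <- function(X, y, tol = 1e-10) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  sv <- svd(Xc)
  pos <- sv$d > tol * sv$d[1]
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos]))
}

# brute-force truncated moving average over valid pixels of one row
bf_moving_average <- function(vals, valid, window) {
  n <- length(vals)
  h <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (!valid[j]) next
    lo <- max(1, j - h); hi <- min(n, j + h)
    sel <- lo:hi
    sel <- sel[valid[sel]]
    out[j] <- mean(vals[sel])
  }
  out
}

# brute-force bin average of one emission row for downsampling
bf_bin_means <- function(em, vals, valid, step) {
  K <- floor((max(em) - min(em)) / step)
  centers <- min(em) + step * (0:K)
  out <- rep(NA_real_, K + 1)
  for (k in seq_along(centers)) {
    inbin <- em >= centers[k] - step / 2 & em < centers[k] + step / 2 & valid
    if (any(inbin)) out[k] <- mean(vals[inbin])
  }
  list(centers = centers, means = out)
}

# brute-force count of pixels inside an offset band for one measurement
bf_band_count <- function(grid, low, high) {
  n <- 0L
  for (i in seq_along(grid$excitation))
    for (j in seq_along(grid$emission)) {
      off <- grid$emission[j] - grid$excitation[i]
      if (off >= low && off <= high) n <- n + 1L
    }
  n
}

rmse_loop <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}
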