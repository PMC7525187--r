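#' Fit a thin-plate spline to scattered 2-D data
#'
#' Classic 2-D thin-plate spline with radial kernel `U(r) = r^2 log r`
#' (`U(0) = 0`) and an affine null space. The bordered linear system
#' `[[K + lambda I, P], [P', 0]]` is solved once per response column, so a
#' single fit smooths both displacement components. `lambda = 0` gives the
#' exact interpolant; any `lambda` reproduces affine data exactly because
#' affine functions live in the unpenalized null space.
#'
#' @param x numeric `n x 2` matrix of (row, col) sites; `n >= 3`, not
#'   collinear.
#' @param y numeric vector or `n x m` matrix of responses.
#' @param lambda smoothing parameter `>= 0` (dimensionless, on the scale of
#'   the kernel matrix), or `"gcv"` to select it by generalized
#'   cross-validation over `lambda_grid` (jointly across response columns).
#' @param lambda_grid candidate values used when `lambda = "gcv"`.
#' @return An object of class `tps_fit` with the chosen `lambda`, fitted
#'   values, and coefficients; evaluate elsewhere with [predict.tps_fit()].
#' @export
tps_fit <- function(x, y, lambda = 0,
                    lambda_grid = 10^seq(-4, 3, length.out = 8)) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stopf("x must be an n x 2 matrix of sites")
  y <- as.matrix(y)
  n <- nrow(x)
  if (n < 3L) stopf("thin-plate spline needs at least 3 sites")
  if (nrow(y) != n) stopf("x and y row counts differ")
  if (qr(cbind(1, x))$rank < 3L)
    stopf("sites are collinear; thin-plate spline fit is degenerate")

  K <- tps_kernel(x, x)
  P <- cbind(1, x)
  zero3 <- matrix(0, 3, 3)
  rhs <- rbind(y, matrix(0, 3, ncol(y)))

  solve_for <- function(lam) {
    M <- rbind(cbind(K + diag(lam, n), P), cbind(t(P), zero3))
    solve(M, rhs)
  }

  if (identical(lambda, "gcv")) {
    best <- NULL
    for (lam in lambda_grid) {
      M <- rbind(cbind(K + diag(lam, n), P), cbind(t(P), zero3))
      S <- solve(M, rbind(diag(n), matrix(0, 3, n)))
      Hhat <- cbind(K, P) %*% S
      res <- y - Hhat %*% y
      edf <- sum(diag(Hhat))
      denom <- max(n - edf, 1e-8)
      gcv <- n * sum(res^2) / denom^2
      if (is.null(best) || gcv < best$gcv)
        best <- list(gcv = gcv, lambda = lam)
    }
    lambda <- best$lambda
  }
  if (!is.numeric(lambda) || lambda < 0) stopf("lambda must be >= 0 or 'gcv'")

  coef <- solve_for(lambda)
  w <- coef[seq_len(n), , drop = FALSE]
  a <- coef[n + 1:3, , drop = FALSE]
  structure(list(x = x, w = w, a = a, lambda = lambda,
                 fitted = K %*% w + P %*% a),
            class = "tps_fit")
}

# U(r) = r^2 log r, written as 0.5 * r^2 * log(r^2); U(0) = 0.
tps_kernel <- function(a, b) {
  r2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  out <- 0.5 * r2 * log(pmax(r2, .Machine$double.xmin))
  out[r2 == 0] <- 0
  out
}

#' Evaluate a thin-plate spline at new sites
#'
#' @param object a [tps_fit()].
#' @param newx numeric `m x 2` matrix of (row, col) positions.
#' @param ... unused.
#' @return `m x k` matrix of spline values.
#' @export
predict.tps_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  tps_kernel(newx, object$x) %*% object$w + cbind(1, newx) %*% object$a
}
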