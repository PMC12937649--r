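#' Reduced-rank multivariate regression
#'
#' Minimises `||Y - X G H^T||_F^2` over a coefficient matrix `B = G H^T` of
#' rank at most `r`. Computed in closed form: the OLS fit is projected onto
#' its top `r` right singular directions (SVD of the fitted values), the
#' textbook least-squares solution. At `r = min(p, q)` this reduces to
#' ordinary least squares.
#'
#' @param Y n x p response matrix.
#' @param X n x q predictor matrix of full column rank.
#' @param r Target rank, `1 <= r <= min(p, q)`.
#' @return An object of class `rrr_fit`: list with `left_factor` (q x r),
#'   `right_factor` (p x r), `rank`, `coef` (q x p, the product), and
#'   `residual_sse`.
#' @export
reduced_rank_regression <- function(Y, X, r) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  p <- ncol(Y); q <- ncol(X)
  if (nrow(Y) != nrow(X)) stop("`Y` and `X` must have equal rows", call. = FALSE)
  if (r < 1 || r > min(p, q) || r != round(r)) {
    stop("`r` must be an integer in [1, min(p, q)]", call. = FALSE)
  }
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12) stop("`X` is rank deficient", call. = FALSE)
  b_ols <- solve(xtx, crossprod(X, Y))
  sv <- svd(X %*% b_ols)
  V_r <- sv$v[, seq_len(r), drop = FALSE]
  left <- b_ols %*% V_r
  coef <- left %*% t(V_r)
  res <- Y - X %*% coef
  structure(list(left_factor = left, right_factor = V_r, rank = as.integer(r),
                 coef = coef, residual_sse = sum(res^2)),
            class = "rrr_fit")
}

#' @export
print.rrr_fit <- function(x, ...) {
  cat(sprintf("<rrr_fit> rank %d, %d -> %d, residual SSE %.6g\n",
              x$rank, nrow(x$left_factor), nrow(x$right_factor), x$residual_sse))
  invisible(x)
}

#' Weighted rank-one projection of a mixing block
#'
#' Finds the rank-one matrix `B` minimising
#' `tr(solve(sigma) %*% (B - btilde) %*% gram %*% t(B - btilde))`,
#' the generalised-least-squares distance induced by the channel noise
#' covariance and the temporal regressor Gram matrix. Solved exactly by
#' whitening (`solve(sqrt(sigma)) %*% btilde %*% sqrt(gram)`), truncating
#' the SVD to the leading triplet (Eckart–Young), and unwhitening.
#'
#' @param btilde Unconstrained G x 2 block estimate.
#' @param sigma G x G symmetric positive-definite channel covariance (or a
#'   length-G vector of variances).
#' @param gram 2 x 2 symmetric positive-definite Gram matrix of the
#'   source's temporal regressors.
#' @return A G x 2 matrix of rank one.
#' @export
rank_one_project <- function(btilde, sigma, gram) {
  btilde <- check_block(btilde)
  G <- nrow(btilde)
  if (!is.matrix(sigma)) sigma <- diag(as.numeric(sigma), nrow = G)
  w1 <- inv_sqrt_spd(sigma)            # sigma^(-1/2)
  g_half <- sqrt_spd(gram)             # gram^(1/2)
  m <- w1 %*% btilde %*% g_half
  sv <- svd(m)
  m1 <- sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
  out <- solve(w1, m1) %*% solve(g_half)
  dimnames(out) <- dimnames(btilde)
  out
}

sqrt_spd <- function(S) {
  S <- as.matrix(S)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0) stop("matrix is not positive definite", call. = FALSE)
  ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
}

inv_sqrt_spd <- function(S) {
  S <- as.matrix(S)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0) stop("matrix is not positive definite", call. = FALSE)
  ev$vectors %*% ((1 / sqrt(ev$values)) * t(ev$vectors))
}
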