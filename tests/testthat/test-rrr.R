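# Brute-force oracles: direct numerical minimisation over the factor
# parametrisations, independent of the SVD-based closed forms they check.

brute_rank_one <- function(btilde, sigma, gram, starts = 3, seed = 1) {
  G <- nrow(btilde)
  sinv <- solve(sigma)
  obj <- function(par) {
    B <- par[1:G] %*% t(par[(G + 1):(G + 2)])
    D <- B - btilde
    sum(sinv * (D %*% gram %*% t(D)))
  }
  set.seed(seed)
  best <- Inf
  sv <- svd(btilde)
  inits <- c(list(c(sv$u[, 1] * sv$d[1], sv$v[, 1])),
             replicate(starts, rnorm(G + 2), simplify = FALSE))
  for (p0 in inits) {
    o <- optim(p0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

brute_rrr <- function(Y, X, r, starts = 3, seed = 1) {
  p <- ncol(Y); q <- ncol(X)
  obj <- function(par) {
    G <- matrix(par[seq_len(q * r)], q, r)
    H <- matrix(par[q * r + seq_len(p * r)], p, r)
    sum((Y - X %*% G %*% t(H))^2)
  }
  set.seed(seed)
  ols <- solve(crossprod(X), crossprod(X, Y))
  sv <- svd(ols)
  init0 <- c(sv$u[, 1:r] %*% diag(sv$d[1:r], r), sv$v[, 1:r])
  best <- Inf
  for (p0 in c(list(init0),
               replicate(starts, rnorm((p + q) * r), simplify = FALSE))) {
    o <- optim(p0, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

test_that("rank_one_project is idempotent and truncates correctly", {
  u <- c(2, -1, 0.5); v <- c(0.3, -0.9)
  blk <- u %*% t(v)
  expect_equal(rank_one_project(blk, diag(3), diag(2)), blk, tolerance = 1e-12)
  # hand-worked truncation: singular values 2 and 1, keep the top triplet
  b <- rbind(c(2, 0), c(0, 1), c(0, 0))
  pr <- rank_one_project(b, diag(3), diag(2))
  expect_equal(pr, rbind(c(2, 0), c(0, 0), c(0, 0)), tolerance = 1e-12)
  expect_equal(sum((pr - b)^2), 1)
  expect_error(rank_one_project(b, diag(c(1, -1, 1)), diag(2)),
               "positive definite")
})

test_that("rank_one_project equals the brute-force weighted minimiser", {
  for (seed in 1:25) {
    set.seed(seed)
    G <- sample(3:5, 1)
    btilde <- matrix(rnorm(G * 2), G, 2)
    gram <- crossprod(matrix(rnorm(8), 4, 2)) + 0.5 * diag(2)
    sigma <- diag(runif(G, 0.2, 2))
    if (seed %% 3 == 0) {  # occasionally a full (correlated) covariance
      A <- matrix(rnorm(G * G), G)
      sigma <- crossprod(A) / G + diag(G) * 0.3
    }
    ours <- rank_one_project(btilde, sigma, gram)
    sinv <- solve(sigma)
    D <- ours - btilde
    ours_obj <- sum(sinv * (D %*% gram %*% t(D)))
    oracle <- brute_rank_one(btilde, sigma, gram, seed = seed)
    expect_lt(abs(ours_obj - oracle), 1e-6 * max(abs(oracle), 1e-8))
    sv <- svd(ours)$d
    expect_lt(sv[2], 1e-10 * max(sv[1], 1e-12))
  }
  # unweighted truncation is NOT optimal under non-identity weights
  set.seed(99)
  btilde <- matrix(rnorm(8), 4, 2)
  sigma <- diag(c(10, 0.1, 1, 1))
  gram <- diag(c(3, 0.2))
  weighted <- rank_one_project(btilde, sigma, gram)
  plain <- rank_one_project(btilde, diag(4), diag(2))
  expect_gt(max(abs(weighted - plain)), 1e-6)
})

test_that("reduced_rank_regression recovers exact low-rank truth and OLS", {
  set.seed(5)
  X <- matrix(rnorm(40 * 3), 40, 3)
  G0 <- matrix(rnorm(3), 3, 1); H0 <- matrix(rnorm(4), 4, 1)
  Y <- X %*% G0 %*% t(H0)
  fit <- reduced_rank_regression(Y, X, 1)
  expect_lt(fit$residual_sse, 1e-18 * sum(Y^2))
  # full rank equals OLS fitted values
  Y2 <- Y + matrix(rnorm(160, sd = 0.3), 40, 4)
  full <- reduced_rank_regression(Y2, X, 3)
  ols_fit <- X %*% solve(crossprod(X), crossprod(X, Y2))
  expect_equal(X %*% full$coef, ols_fit, tolerance = 1e-10)
  # residual SSE non-increasing in rank
  sses <- vapply(1:3, function(r) reduced_rank_regression(Y2, X, r)$residual_sse,
                 numeric(1))
  expect_true(all(diff(sses) <= 1e-10))
  expect_error(reduced_rank_regression(Y2, X, 5), "r")
})

test_that("reduced_rank_regression matches the brute-force minimiser", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30; q <- 4; p <- 3; r <- 1
    X <- matrix(rnorm(n * q), n, q)
    Y <- matrix(rnorm(n * p), n, p)
    fit <- reduced_rank_regression(Y, X, r)
    oracle <- brute_rrr(Y, X, r, seed = seed)
    expect_lt(abs(fit$residual_sse - oracle), 1e-6 * oracle)
  }
})
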