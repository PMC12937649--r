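test_that("linear_update recovers exact linear truth and enforces rank", {
  set.seed(21)
  t <- time_grid(120)
  thetas <- data.frame(alpha = c(1.0, 4.5), omega = c(0.3, 0.7))
  H <- build_design(thetas, t)
  M0 <- rnorm(5)
  B0 <- matrix(rnorm(20), 5, 4)
  Y <- sweep(H %*% t(B0), 2, M0, `+`)
  up <- linear_update(Y, H, diag(5), modes = c("free", "free"))
  expect_equal(up$M, M0, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(do.call(cbind, up$blocks), B0, tolerance = 1e-9,
               ignore_attr = TRUE)
  # rank-one truth is recovered exactly under the fixed constraint
  B1 <- cbind(c(1, -2, 0.5, 3, 1)) %*% rbind(c(0.6, -0.8))
  Y1 <- sweep(H[, 1:2] %*% t(B1), 2, M0, `+`)
  up1 <- linear_update(Y1, H[, 1:2], diag(5), modes = "fixed")
  expect_equal(up1$blocks[[1]], B1, tolerance = 1e-9, ignore_attr = TRUE)
  # constrained fit can never beat the unconstrained one
  Yn <- Y + matrix(rnorm(length(Y), sd = 0.2), nrow(Y))
  free <- linear_update(Yn, H, diag(5), c("free", "free"))
  fixd <- linear_update(Yn, H, diag(5), c("fixed", "fixed"))
  sse <- function(up) {
    sum((Yn - sweep(H %*% t(do.call(cbind, up$blocks)), 2, up$M, `+`))^2)
  }
  expect_gte(sse(fixd), sse(free) - 1e-10)
  # rank-deficient design names the offending columns
  expect_error(linear_update(Yn, cbind(H, H[, 1:2]), diag(5),
                             c("free", "free", "free")),
               "rank deficient")
})

test_that("profile_theta_search finds on-grid truth and the sinusoid limit", {
  t <- time_grid(128)
  cfg <- fit_config(omega_grid = c(0.1, 0.25, 0.5, 1),
                    alpha_grid = time_grid(32), local_refine = FALSE)
  psi <- mobius_phase(t, alpha = time_grid(32)[9], omega = 0.25)
  Y <- outer(cos(psi), c(1, -0.5, 2)) + outer(sin(psi), c(0.3, 1, -1))
  th <- profile_theta_search(Y, diag(3), "free", cfg, t = t)
  expect_equal(th$alpha, time_grid(32)[9], tolerance = 1e-12)
  expect_equal(th$omega, 0.25, tolerance = 1e-12)
  # pure sinusoid: omega -> 1 with refinement on
  cfg2 <- fit_config(local_refine = TRUE)
  Ys <- matrix(cos(t - 2.17), ncol = 1)
  th2 <- profile_theta_search(Ys, diag(1), "free", cfg2, t = t)
  expect_lt(abs(th2$omega - 1), 0.02)
  # a superset grid can only improve the attained objective
  cfg_small <- fit_config(omega_grid = c(0.2, 0.6), alpha_grid = time_grid(8),
                          local_refine = FALSE)
  cfg_big <- fit_config(omega_grid = c(0.1, 0.2, 0.6, 0.9),
                        alpha_grid = time_grid(16), local_refine = FALSE)
  set.seed(3)
  Yr <- matrix(rnorm(128 * 2), 128, 2)
  o_small <- profile_theta_search(Yr, diag(2), "free", cfg_small, t = t)$objective
  o_big <- profile_theta_search(Yr, diag(2), "free", cfg_big, t = t)$objective
  expect_lte(o_big, o_small + 1e-12)
})

test_that("update_sigma floors, averages, and is permutation-equivariant", {
  z <- matrix(0, 10, 3)
  expect_equal(update_sigma(z, "diagonal", floor = 1e-4), diag(1e-4, 3))
  alt <- matrix(rep(c(1, -1), 5), ncol = 1)
  expect_equal(update_sigma(alt, "diagonal")[1, 1], 1)
  set.seed(31)
  X <- matrix(rnorm(60), 20, 3)
  full <- update_sigma(X, "full")
  perm <- c(3, 1, 2)
  expect_equal(unname(update_sigma(X[, perm], "full")),
               unname(full[perm, perm]), tolerance = 1e-12)
  expect_error(update_sigma(X[1, , drop = FALSE]), "2 time points")
})

test_that("log_likelihood matches closed forms and a density-sum oracle", {
  mon <- mk_montage(4, 71)
  sim <- simulate_erp(mk_source(9), mon, n_samples = 20, noise_cov = 0.3,
                      seed = 2)
  fit <- fit_fmm(sim$erp, K = 1)
  m <- fit$model
  # zero residuals, identity covariance: -(T G / 2) log(2 pi)
  T_n <- 20; G <- 4
  perfect <- m
  perfect$sigma <- diag(G)
  Yhat <- erp_tibble(sim$erp$t,
                     rrfmm:::predict_fmm(perfect, sim$erp$t), m$channels)
  expect_equal(log_likelihood(Yhat, perfect), -(T_n * G / 2) * log(2 * pi),
               tolerance = 1e-10)
  scaled <- perfect
  scaled$sigma <- 3.7 * diag(G)
  expect_equal(log_likelihood(Yhat, scaled),
               -(T_n * G / 2) * log(2 * pi) - (T_n * G / 2) * log(3.7),
               tolerance = 1e-10)
  # general case: per-timepoint multivariate normal density summation
  ll <- log_likelihood(sim$erp, m)
  E <- as.matrix(sim$erp[, -1]) - rrfmm:::predict_fmm(m, sim$erp$t)
  sinv <- solve(m$sigma)
  naive <- sum(apply(E, 1, function(e) {
    -0.5 * (G * log(2 * pi) + determinant(m$sigma)$modulus[1] +
              drop(e %*% sinv %*% e))
  }))
  expect_equal(ll, naive, tolerance = 1e-8)
})

test_that("fit_fmm recovers a noiseless fixed-orientation source", {
  mon <- example_montage(8)
  src <- dipole_source(0, 1, z = 0.2, basis = mk_basis(5),
                       position = c(0, 0, 0.2), alpha = 2.4, omega = 0.2,
                       beta = 0.9)
  sim <- simulate_erp(src, mon, n_samples = 128, noise_cov = 1e-10, seed = 3)
  fit <- fit_fmm(sim$erp, K = 1, modes = "fixed")
  expect_lt(circ_dist(fit$model$thetas$alpha, src$alpha), 0.02)
  expect_lt(abs(fit$model$thetas$omega - src$omega), 0.02)
  expect_true(all(fit$fit$r2 >= 0.999))
  # fitted + residuals reproduce the input exactly
  expect_equal(fit$fit$fitted + fit$fit$residuals,
               as.matrix(sim$erp[, -1]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # the fixed-mode block is numerically rank one
  sv <- svd(fit$model$blocks[[1]])$d
  expect_lt(sv[2] / sv[1], 1e-8)
})

test_that("fit_fmm is deterministic and its objective never decreases", {
  sim <- study_replicate(17, D = 2, G = 8, T_n = 96)
  f1 <- fit_fmm(sim$erp, K = 2, modes = "free")
  f2 <- fit_fmm(sim$erp, K = 2, modes = "free")
  expect_identical(f1$model, f2$model)
  expect_identical(f1$fit$loglik_trace, f2$fit$loglik_trace)
  for (modes in list("free", "fixed", c("free", "fixed"))) {
    f <- fit_fmm(sim$erp, K = length(modes) * ifelse(length(modes) == 1, 2, 1),
                 modes = modes)
    tr <- f$fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("free and fixed likelihoods are correctly nested", {
  sim <- study_replicate(23, D = 2, G = 8, T_n = 96)
  free <- fit_fmm(sim$erp, K = 2, modes = "free")
  # same thetas and sigma, constrained blocks: likelihood cannot increase
  t <- sim$erp$t
  Y <- as.matrix(sim$erp[, -1])
  H <- build_design(free$model$thetas, t)
  up_fix <- linear_update(Y, H, free$model$sigma, c("fixed", "fixed"))
  fixed_model <- free$model
  fixed_model$blocks <- up_fix$blocks
  fixed_model$baseline <- stats::setNames(up_fix$M, free$model$channels)
  fixed_model$modes <- c("fixed", "fixed")
  expect_gte(log_likelihood(sim$erp, free$model),
             log_likelihood(sim$erp, fixed_model) - 1e-8)
  # degenerate input guard
  bad <- sim$erp
  bad[[2]] <- 1
  cfg_full <- fit_config(sigma_structure = "full")
  expect_error(fit_fmm(bad, K = 1, config = cfg_full), "diagonal")
})
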