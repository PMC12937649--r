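test_that("mobius_phase matches closed-form values and handles the pole", {
  expect_equal(mobius_phase(1.2, alpha = 1.2, omega = 0.7), 0)
  expect_equal(mobius_phase(0.4 + 1.3, alpha = 0.4, omega = 1), 1.3)
  expect_equal(mobius_phase(pi / 2, alpha = 0, omega = 0.5), 2 * atan(0.5),
               tolerance = 1e-12)
  # half-period point: continuous limit, no singularity
  expect_equal(mobius_phase(0.25 + pi, alpha = 0.25, omega = 0.3), pi,
               tolerance = 1e-12)
  expect_error(mobius_phase(Inf, 0, 0.5), "finite")
  expect_error(mobius_phase(1, alpha = -0.1, omega = 0.5), "alpha")
  expect_error(mobius_phase(1, alpha = 0, omega = 1.5), "omega")
  expect_error(mobius_phase(1, alpha = 0, omega = 0), "omega")
})

test_that("mobius_phase is strictly monotone and agrees with the naive form", {
  set.seed(7)
  for (rep in 1:25) {
    alpha <- runif(1, 0, 2 * pi - 1e-9)
    omega <- runif(1, 0.02, 1)
    t <- sort(alpha + runif(200, -pi + 1e-6, pi - 1e-6))
    psi <- mobius_phase(t %% (2 * pi), alpha, omega)
    # psi strictly increasing in t over (alpha - pi, alpha + pi)
    expect_true(all(diff(2 * atan(omega * tan((t - alpha) / 2)) ) > 0))
    # pole-safe form equals the literal tan/arctan composition away from the pole
    keep <- abs(t - alpha - pi) > 1e-3 & abs(t - alpha + pi) > 1e-3
    naive <- 2 * atan(omega * tan((t - alpha) / 2))
    expect_lt(max(abs(psi[keep] - naive[keep])), 1e-10)
  }
  # identity limit at omega = 1
  set.seed(8)
  t <- runif(1000, 0, 2 * pi)
  alpha <- 2.2
  wrapped <- ((t - alpha + pi) %% (2 * pi)) - pi
  expect_lt(max(abs(mobius_phase(t, alpha, 1) - wrapped)), 1e-12)
})

test_that("build_design produces paired unit-circle regressors", {
  H <- build_design(data.frame(alpha = 0, omega = 1), time_grid(4))
  expect_equal(unname(H),
               cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)),
               tolerance = 1e-12)
  thetas <- data.frame(alpha = c(0.3, 4.0), omega = c(0.5, 0.12))
  H2 <- build_design(thetas, time_grid(256))
  expect_equal(dim(H2), c(256L, 4L))
  for (d in 1:2) {
    expect_lt(max(abs(H2[, 2 * d - 1]^2 + H2[, 2 * d]^2 - 1)), 1e-12)
  }
  expect_error(build_design(data.frame(alpha = numeric(), omega = numeric()),
                            time_grid(4)))
})

test_that("fmm_wave is a shifted cosine bounded by its amplitude", {
  t <- time_grid(64)
  expect_equal(fmm_wave(t, A = 0, delta = 1, alpha = 1, omega = 0.4), rep(0, 64))
  expect_equal(fmm_wave(t, A = 1, delta = 0, alpha = 0, omega = 1), cos(t),
               tolerance = 1e-12)
  expect_equal(fmm_wave(t, A = 2, delta = -pi / 2, alpha = 0, omega = 1),
               2 * sin(t), tolerance = 1e-12)
  expect_lte(max(abs(fmm_wave(t, 3, 0.7, 1.1, 0.2))), 3)
  expect_error(fmm_wave(t, A = -1, delta = 0, alpha = 0, omega = 1), "A")
})

test_that("block_to_amp_phase inverts the amplitude/phase parametrisation", {
  out <- block_to_amp_phase(rbind(c(1, 0), c(0, -1),
                                  c(3 * cos(0.4), -3 * sin(0.4))))
  expect_equal(out$amplitude, c(1, 1, 3), tolerance = 1e-12)
  expect_equal(out$delta, c(0, pi / 2, 0.4), tolerance = 1e-12)
  expect_error(block_to_amp_phase(matrix(1, 2, 3)), "2 columns")
  # round trip on random parameters
  set.seed(11)
  for (rep in 1:50) {
    A <- runif(4, 1e-6, 10)
    delta <- runif(4, -pi + 1e-9, pi)
    blk <- amp_phase_to_block(A, delta)
    rec <- block_to_amp_phase(blk)
    expect_equal(rec$amplitude, A, tolerance = 1e-12)
    expect_equal(rec$delta, delta, tolerance = 1e-12)
    expect_equal(amp_phase_to_block(rec$amplitude, rec$delta), blk,
                 tolerance = 1e-12)
  }
})

test_that("signed_amplitudes recovers signed rank-one weights", {
  u <- c(1, -2, 3) / sqrt(14)
  v <- c(1, 1)
  blk <- u %*% t(v)
  s <- signed_amplitudes(blk)
  expect_equal(sqrt(sum(s^2)), sqrt(2), tolerance = 1e-9)
  expect_gt(s[3], 0)  # largest-magnitude entry positive
  expect_equal(s / sqrt(sum(s^2)), u / sqrt(sum(u^2)) * sign(u[3]),
               tolerance = 1e-9)
  # global sign flip of the factorisation gives identical output
  expect_equal(signed_amplitudes(-blk), s, tolerance = 1e-12)
  # magnitudes agree with the amplitude parametrisation
  expect_equal(abs(s), block_to_amp_phase(blk)$amplitude, tolerance = 1e-9)
  expect_error(signed_amplitudes(diag(2)), "rank one")
})
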