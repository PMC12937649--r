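#' Möbius phase function
#'
#' Monotone phase reparametrisation of time used by Frequency-Modulated
#' Möbius (FMM) waves: `psi(t) = 2 atan(omega * tan((t - alpha) / 2))`,
#' evaluated in a pole-safe two-argument arctangent form so the nominal
#' tangent singularity at `t = alpha + pi` is crossed continuously.
#'
#' @param t Numeric vector of time points in radians (any finite values;
#'   the function is 2*pi-periodic in `t`).
#' @param alpha Peak latency parameter, radians in `[0, 2*pi)`.
#' @param omega Traversal-speed / sharpness parameter in `(0, 1]`. `omega = 1`
#'   gives the identity phase `t - alpha`; small `omega` concentrates the
#'   traversal near `t = alpha`.
#'
#' @return Numeric vector of phases in `(-pi, pi]`, with `psi(alpha) = 0` and
#'   `psi` strictly increasing on `(alpha - pi, alpha + pi]`.
#' @export
#' @examples
#' mobius_phase(pi / 2, alpha = 0, omega = 0.5)  # 2 * atan(0.5)
mobius_phase <- function(t, alpha, omega) {
  check_phase_params(alpha, omega)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  d <- wrap_pi(t - alpha)
  psi <- 2 * atan2(omega * sin(d / 2), cos(d / 2))
  wrap_pi(psi)
}

# Wrap angles to (-pi, pi].
wrap_pi <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  y[y <= -pi] <- pi  # boundary of the half-open wrap
  y
}

check_phase_params <- function(alpha, omega) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha >= 2 * pi) {
    stop("`alpha` must be a single value in [0, 2*pi)", call. = FALSE)
  }
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0 || omega > 1) {
    stop("`omega` must be a single value in (0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Uniform time grid on the circle
#'
#' Maps `n` sample indices to the half-open interval `[0, 2*pi)` via
#' `t_i = 2*pi*(i - 1)/n`, the package's native time domain.
#'
#' @param n Number of samples (positive integer).
#' @return Numeric vector of `n` strictly increasing values in `[0, 2*pi)`.
#' @export
time_grid <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  2 * pi * (seq_len(n) - 1) / n
}

check_time_grid <- function(t) {
  if (!is.numeric(t) || length(t) < 1L || anyNA(t) ||
      any(t < 0 | t >= 2 * pi) || is.unsorted(t, strictly = TRUE)) {
    stop("time grid must be strictly increasing within [0, 2*pi)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Temporal design matrix of FMM regressors
#'
#' Builds the T x 2D matrix whose columns `2d - 1` and `2d` hold
#' `cos(psi_d(t))` and `sin(psi_d(t))` for source `d`, where `psi_d` is the
#' Möbius phase with that source's `(alpha, omega)`.
#'
#' @param thetas Data frame with one row per source and numeric columns
#'   `alpha` and `omega` (see [mobius_phase()] for their domains).
#' @param t Time grid in radians (strictly increasing, within `[0, 2*pi)`).
#' @return A T x 2D numeric matrix; every row satisfies
#'   `cos^2 + sin^2 = 1` per source pair.
#' @export
build_design <- function(thetas, t) {
  thetas <- as_theta_df(thetas)
  check_time_grid(t)
  d_n <- nrow(thetas)
  out <- matrix(0, nrow = length(t), ncol = 2L * d_n)
  for (d in seq_len(d_n)) {
    psi <- mobius_phase(t, thetas$alpha[d], thetas$omega[d])
    out[, 2L * d - 1L] <- cos(psi)
    out[, 2L * d] <- sin(psi)
  }
  colnames(out) <- paste0(rep(c("cos", "sin"), d_n), rep(seq_len(d_n), each = 2))
  out
}

as_theta_df <- function(thetas) {
  if (is.null(dim(thetas))) {
    thetas <- as.data.frame(as.list(thetas))
  }
  thetas <- as.data.frame(thetas)
  if (nrow(thetas) < 1L || !all(c("alpha", "omega") %in% names(thetas))) {
    stop("`thetas` must have at least one row and columns `alpha`, `omega`",
         call. = FALSE)
  }
  for (d in seq_len(nrow(thetas))) check_phase_params(thetas$alpha[d], thetas$omega[d])
  thetas
}

#' Evaluate one FMM wave
#'
#' Computes `A * cos(psi(t) + delta)` on a time grid: the contribution of a
#' single latent source to one channel, with channel amplitude `A` and
#' channel phase offset `delta`.
#'
#' @param t Time grid in radians.
#' @param A Amplitude, `A >= 0`.
#' @param delta Channel phase offset in radians.
#' @inheritParams mobius_phase
#' @return Numeric vector of length `length(t)`; absolute values never
#'   exceed `A`.
#' @export
fmm_wave <- function(t, A, delta, alpha, omega) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A < 0) {
    stop("`A` must be a single non-negative value", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta)) {
    stop("`delta` must be a single finite value", call. = FALSE)
  }
  A * cos(mobius_phase(t, alpha, omega) + delta)
}
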