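#' Define an electrode montage
#'
#' @param channel_names Character vector of unique channel names.
#' @param positions G x 3 numeric matrix of electrode positions (same
#'   length units as dipole positions).
#' @param sigma Conductivity of the (homogeneous, infinite, isotropic)
#'   medium, `> 0`. The default `1/(4*pi)` makes the lead constant
#'   `C = 1/||R||^3`, a convenient abstract-unit convention.
#' @return An object of class `rrfmm_montage`.
#' @export
montage <- function(channel_names, positions, sigma = 1 / (4 * pi)) {
  positions <- as.matrix(positions)
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names)) stop("duplicate channel names", call. = FALSE)
  if (nrow(positions) != length(channel_names) || ncol(positions) != 3L) {
    stop("`positions` must be a G x 3 matrix matching `channel_names`", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  structure(list(channel_names = channel_names, positions = positions,
                 sigma = sigma),
            class = "rrfmm_montage")
}

#' @export
print.rrfmm_montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes, sigma = %.4g\n",
              length(x$channel_names), x$sigma))
  invisible(x)
}

# Coerce an ERP data frame (optional leading `t` column, one column per
# channel) to list(t, Y, channels). Matrices with a time attribute pass
# through unchanged.
as_erp_values <- function(data) {
  if (is.list(data) && all(c("t", "Y", "channels") %in% names(data))) {
    return(data)
  }
  df <- as.data.frame(data)
  if (ncol(df) < 1L) stop("ERP data has no columns", call. = FALSE)
  if (identical(names(df)[1], "t")) {
    t <- as.numeric(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else {
    t <- time_grid(nrow(df))
  }
  if (ncol(df) < 1L) stop("ERP data has no channel columns", call. = FALSE)
  Y <- as.matrix(df)
  if (!is.numeric(Y) || anyNA(Y) || any(!is.finite(Y))) {
    stop("ERP values must be finite numeric", call. = FALSE)
  }
  check_time_grid(t)
  list(t = t, Y = Y, channels = colnames(df))
}

erp_tibble <- function(t, Y, channels) {
  colnames(Y) <- channels
  dplyr::bind_cols(tibble::tibble(t = t), tibble::as_tibble(Y))
}

#' Simulate a multichannel ERP from dipole sources
#'
#' Forward-simulates the voltages a montage of electrodes would record from
#' a set of dipole sources in a homogeneous infinite medium. Per trial,
#' each source's latency `alpha` may be jittered (Gaussian, SD
#' `latency_jitter_sd`), channel signals are the superposition of all
#' source projections, and Gaussian noise with channel covariance
#' `noise_cov` is added independently at every time point. The returned ERP
#' is the across-trial average.
#'
#' @param sources A list of [dipole_source()] objects (or a single one).
#' @param montage A [montage()].
#' @param n_samples Number of time samples `T` (uniform grid on `[0, 2*pi)`).
#' @param noise_cov Channel noise covariance: a scalar (iid), a length-G
#'   vector of variances, or a G x G symmetric positive-semidefinite matrix.
#' @param n_trials Number of trials to average (1 = direct noisy ERP).
#' @param latency_jitter_sd Per-trial, per-source latency jitter SD in
#'   radians (`>= 0`). Non-zero jitter attenuates the averaged response,
#'   emulating trial-to-trial misalignment.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param keep_trials If `TRUE`, also return the T x G x n_trials stack.
#' @return An object of class `erp_sim`: a list with
#'   \describe{
#'     \item{`erp`}{tibble with column `t` (radians) and one column per channel,}
#'     \item{`trials`}{optional T x G x n_trials array,}
#'     \item{`truth`}{generating parameters: baseline `M`, mixing blocks
#'       (via the channel amplitudes and `delta = eta + beta`), `thetas`,
#'       noise covariance, and per-source trajectory rank (1 when a
#'       semiaxis vanishes, else 2).}
#'   }
#' @export
simulate_erp <- function(sources, montage, n_samples = 256,
                         noise_cov = 0, n_trials = 1,
                         latency_jitter_sd = 0, seed = 1,
                         keep_trials = FALSE) {
  if (inherits(sources, "dipole_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1, inherits(montage, "rrfmm_montage"))
  if (latency_jitter_sd < 0) stop("`latency_jitter_sd` must be >= 0", call. = FALSE)
  if (n_trials < 1 || n_trials != round(n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  G <- length(montage$channel_names)
  Sigma <- expand_noise_cov(noise_cov, G)
  t <- time_grid(n_samples)
  D <- length(sources)

  # noiseless per-channel closed forms, and ground-truth mixing blocks
  proj <- lapply(sources, project_dipole, montage = montage)
  M <- Reduce(`+`, lapply(proj, function(p) p$m))
  blocks <- vector("list", D)
  for (d in seq_len(D)) {
    delta <- wrap_pi(proj[[d]]$eta + sources[[d]]$beta)
    blocks[[d]] <- amp_phase_to_block(proj[[d]]$amplitude, delta)
    rownames(blocks[[d]]) <- montage$channel_names
  }
  thetas <- tibble::tibble(
    alpha = vapply(sources, `[[`, numeric(1), "alpha"),
    omega = vapply(sources, `[[`, numeric(1), "omega")
  )

  noise_chol <- chol_psd(Sigma)
  set.seed(as.integer(seed))
  trials <- array(0, dim = c(n_samples, G, n_trials))
  for (r in seq_len(n_trials)) {
    S <- matrix(rep(M, each = n_samples), nrow = n_samples)
    for (d in seq_len(D)) {
      src <- sources[[d]]
      a <- src$alpha
      if (latency_jitter_sd > 0) {
        a <- (a + stats::rnorm(1, 0, latency_jitter_sd)) %% (2 * pi)
      }
      phi <- src$beta + mobius_phase(t, a, src$omega)
      S <- S + cos(outer(phi, proj[[d]]$eta, `+`)) *
        rep(proj[[d]]$amplitude, each = n_samples)
    }
    if (any(Sigma != 0)) {
      S <- S + matrix(stats::rnorm(n_samples * G), n_samples, G) %*% noise_chol
    }
    trials[, , r] <- S
  }
  Ybar <- apply(trials, c(1, 2), mean)

  structure(list(
    erp = erp_tibble(t, Ybar, montage$channel_names),
    trials = if (keep_trials) trials else NULL,
    truth = list(
      M = stats::setNames(M, montage$channel_names),
      blocks = blocks,
      thetas = thetas,
      sigma = Sigma,
      ranks = vapply(sources, function(s) if (s$L1 == 0 || s$L2 == 0) 1L else 2L,
                     integer(1)),
      betas = vapply(sources, `[[`, numeric(1), "beta"),
      seed = seed
    )
  ), class = "erp_sim")
}

expand_noise_cov <- function(noise_cov, G) {
  if (is.matrix(noise_cov)) {
    if (!all(dim(noise_cov) == G) || max(abs(noise_cov - t(noise_cov))) > 1e-10) {
      stop("`noise_cov` matrix must be G x G symmetric", call. = FALSE)
    }
    ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) {
      stop("`noise_cov` must be positive semidefinite", call. = FALSE)
    }
    noise_cov
  } else {
    v <- as.numeric(noise_cov)
    if (length(v) == 1L) v <- rep(v, G)
    if (length(v) != G || any(v < 0)) {
      stop("`noise_cov` vector must be G non-negative variances", call. = FALSE)
    }
    diag(v, nrow = G)
  }
}

# Upper-triangular factor usable for PSD (possibly singular) covariances.
chol_psd <- function(Sigma) {
  ch <- suppressWarnings(tryCatch(chol(Sigma), error = function(e) NULL))
  if (!is.null(ch)) return(ch)
  ev <- eigen(Sigma, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  t(ev$vectors %*% diag(sqrt(d), nrow = length(d)))
}

#' @export
print.erp_sim <- function(x, ...) {
  cat(sprintf("<erp_sim> %d samples x %d channels, %d source(s)\n",
              nrow(x$erp), ncol(x$erp) - 1L, nrow(x$truth$thetas)))
  invisible(x)
}

#' Randomised study sources for simulation experiments
#'
#' Draws `D` dipole sources with randomised geometry emulating deep,
#' centrally located cortical generators whose fields reach most of an
#' overlying electrode array: random orthonormal trajectory bases, source
#' positions near the head centre at the given `depth`, semiaxes of order
#' one, sharp Möbius waves (`omega` in `[0.08, 0.35]`), and latencies
#' spread around the cycle (consecutive sources offset by `2*pi/D` plus
#' jitter) so components are temporally distinct. Deterministic given
#' `seed`.
#'
#' @param D Number of sources.
#' @param seed Integer RNG seed.
#' @param orientation `"elliptical"` (generic rank-two trajectories),
#'   `"fixed"` (`L1 = 0`: degenerate linear trajectories), or `"circular"`
#'   (`L1 = L2`: strongly elliptical).
#' @param depth Depth of the sources below the scalp centre (same length
#'   units as the montage; the default suits [example_montage()] with unit
#'   radius).
#' @return List of `D` [dipole_source()] objects.
#' @export
random_dipole_sources <- function(D = 2, seed = 1,
                                  orientation = c("elliptical", "fixed", "circular"),
                                  depth = 0.18) {
  orientation <- match.arg(orientation)
  set.seed(as.integer(seed))
  base_alpha <- stats::runif(1, 0, 2 * pi)
  lapply(seq_len(D), function(d) {
    basis <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(basis) < 0) basis[, 3] <- -basis[, 3]
    L2 <- stats::runif(1, 0.6, 1)
    L1 <- switch(orientation,
                 elliptical = stats::runif(1, 0.5, 1) * L2,
                 fixed = 0,
                 circular = L2)
    alpha <- (base_alpha + (d - 1) * 2 * pi / D +
                stats::runif(1, -0.3, 0.3)) %% (2 * pi)
    dipole_source(
      L1 = L1, L2 = L2, z = stats::runif(1, -0.2, 0.2), basis = basis,
      position = c(stats::runif(2, -0.08, 0.08),
                   depth + stats::runif(1, -0.04, 0.04)),
      alpha = alpha, omega = stats::runif(1, 0.08, 0.35),
      beta = stats::runif(1, 0, 2 * pi))
  })
}

#' Noise level scaled to the noiseless peak response
#'
#' Computes the channel noise SD equal to `fraction` of the peak absolute
#' deviation from channel baselines of the noiseless superposed signal —
#' the scale at which simulation noise levels are specified.
#'
#' @param sources List of [dipole_source()] objects.
#' @param montage A [montage()].
#' @param n_samples Number of time samples.
#' @param fraction Noise SD as a fraction of the peak (e.g. `0.05`).
#' @return A single numeric SD (voltage units).
#' @export
noise_sd_at_peak <- function(sources, montage, n_samples = 256,
                             fraction = 0.05) {
  sim <- simulate_erp(sources, montage, n_samples = n_samples, noise_cov = 0)
  Y <- as.matrix(sim$erp[, -1, drop = FALSE])
  fraction * max(abs(sweep(Y, 2, colMeans(Y))))
}

#' Example hemispheric montage
#'
#' G electrodes spread deterministically over the upper unit hemisphere
#' (golden-angle spiral), a convenient stand-in scalp layout for
#' simulations; conductivity defaults to `1/(4*pi)` so lead constants are
#' `1/||R||^3`.
#'
#' @param G Number of electrodes.
#' @param radius Scalp radius (length units).
#' @return A [montage()].
#' @export
example_montage <- function(G = 16, radius = 1) {
  i <- seq_len(G)
  zc <- (i - 0.5) / G              # heights in (0, 1): upper hemisphere
  phi <- 2 * pi * i * (3 - sqrt(5)) / 2
  r <- sqrt(pmax(1 - zc^2, 0))
  pos <- radius * cbind(r * cos(phi), r * sin(phi), zc)
  montage(sprintf("E%02d", i), pos)
}

#' Average a stack of trials into an ERP
#'
#' @param trials T x G x n_trials numeric array.
#' @param channels Optional channel names (defaults to the array's dimnames
#'   or `ch1..chG`).
#' @return Tibble with column `t` and one column per channel.
#' @export
epoch_average <- function(trials, channels = NULL) {
  if (!is.array(trials) || length(dim(trials)) != 3L || dim(trials)[3] < 1L) {
    stop("`trials` must be a T x G x n_trials array with n_trials >= 1",
         call. = FALSE)
  }
  Y <- apply(trials, c(1, 2), mean)
  if (is.null(channels)) {
    channels <- dimnames(trials)[[2]]
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(Y)))
  }
  erp_tibble(time_grid(nrow(Y)), Y, channels)
}
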