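# Shared fixture builders for the simulation-based suites.

# deterministic random orthonormal (right-handed) basis
mk_basis <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# random montage of G electrodes at distance >= 0.5 from the origin
mk_montage <- function(G, seed) {
  set.seed(seed)
  pos <- matrix(rnorm(3 * G), G, 3)
  pos <- pos / sqrt(rowSums(pos^2)) * runif(G, 0.7, 1.3)
  montage(paste0("ch", seq_len(G)), pos)
}

# random dipole source; orientation "fixed" collapses L1 to 0
mk_source <- function(seed, orientation = "elliptical") {
  set.seed(seed)
  dipole_source(
    L1 = if (orientation == "fixed") 0 else runif(1, 0.3, 1.5),
    L2 = runif(1, 0.3, 1.5),
    z = runif(1, -0.5, 0.5),
    basis = mk_basis(seed + 1000),
    position = runif(3, -0.2, 0.2),
    alpha = runif(1, 0, 2 * pi - 1e-9),
    omega = runif(1, 0.05, 1),
    beta = runif(1, 0, 2 * pi - 1e-9)
  )
}

# distance between angles on the circle
circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# align K estimated components to truth by best assignment on alpha distance;
# returns per-component absolute alpha and omega errors
match_components <- function(est, truth) {
  K <- nrow(truth)
  perms <- if (K == 1) list(1L) else if (K == 2) list(1:2, 2:1) else
    stop("match_components supports K <= 2")
  best <- NULL
  for (p in perms) {
    ae <- circ_dist(est$alpha[p], truth$alpha)
    oe <- abs(est$omega[p] - truth$omega)
    if (is.null(best) || sum(ae) < sum(best$ae)) best <- list(ae = ae, oe = oe)
  }
  best
}

# the canonical recovery-study replicate: D deep central sources over a
# 16-electrode hemispheric montage, noise SD at 5% of the noiseless peak
study_replicate <- function(seed, D = 2, G = 16, T_n = 256,
                            orientation = "elliptical",
                            noise_fraction = 0.05) {
  mon <- example_montage(G)
  src <- random_dipole_sources(D, seed = seed, orientation = orientation)
  sd_n <- noise_sd_at_peak(src, mon, n_samples = T_n,
                           fraction = noise_fraction)
  sim <- simulate_erp(src, mon, n_samples = T_n, noise_cov = sd_n^2,
                      seed = seed + 10000)
  sim
}
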