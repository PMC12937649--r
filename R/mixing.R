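#' Convert a mixing-matrix block to amplitudes and phase offsets
#'
#' A source's G x 2 mixing block stores, per channel `g`,
#' `b1 = A_g cos(delta_g)` and `b2 = -A_g sin(delta_g)`. This inverts that
#' map: `A_g = sqrt(b1^2 + b2^2)` and `delta_g = atan2(-b2, b1)`.
#'
#' @param block Numeric matrix with exactly 2 columns (channels in rows).
#' @return A tibble with columns `channel`, `amplitude` (`>= 0`) and
#'   `delta` (radians in `(-pi, pi]`).
#' @seealso [amp_phase_to_block()] for the forward map.
#' @export
block_to_amp_phase <- function(block) {
  block <- check_block(block)
  A <- sqrt(block[, 1]^2 + block[, 2]^2)
  delta <- atan2(-block[, 2], block[, 1])
  tibble::tibble(
    channel = if (is.null(rownames(block))) seq_len(nrow(block)) else rownames(block),
    amplitude = A,
    delta = delta
  )
}

#' Build a mixing-matrix block from amplitudes and phase offsets
#'
#' @param amplitude Numeric vector of channel amplitudes (`>= 0`).
#' @param delta Numeric vector of channel phase offsets (radians).
#' @return A G x 2 matrix with columns `A cos(delta)` and `-A sin(delta)`.
#' @export
amp_phase_to_block <- function(amplitude, delta) {
  if (length(amplitude) != length(delta)) {
    stop("`amplitude` and `delta` must have equal length", call. = FALSE)
  }
  if (any(amplitude < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  cbind(amplitude * cos(delta), -amplitude * sin(delta))
}

check_block <- function(block) {
  block <- as.matrix(block)
  if (ncol(block) != 2L) {
    stop("mixing block must have exactly 2 columns", call. = FALSE)
  }
  if (!is.numeric(block) || anyNA(block)) {
    stop("mixing block must be numeric without missing values", call. = FALSE)
  }
  block
}

#' Signed channel amplitudes of a rank-one mixing block
#'
#' Under the fixed-orientation (rank-one) restriction a source's block
#' factorises as `u v^T`: all channels share one temporal waveform and
#' differ only by a signed scalar. This extracts those signed amplitudes
#' `s_g = u_g * ||v||`, the quantities mapped in scalp topographies, with
#' the sign convention that the largest-magnitude entry of `u` is positive
#' (the factorisation's global sign is not identifiable).
#'
#' @param block Numeric G x 2 matrix of numerical rank one (second singular
#'   value at most `tol` times the first).
#' @param tol Rank tolerance; default `1e-6`.
#' @return Numeric vector of G signed amplitudes; `abs()` of it equals the
#'   `amplitude` column of [block_to_amp_phase()].
#' @export
signed_amplitudes <- function(block, tol = 1e-6) {
  block <- check_block(block)
  sv <- svd(block)
  if (sv$d[1] <= 0 || sv$d[2] / sv$d[1] > tol) {
    stop("block is not numerically rank one; fit the fixed-orientation model first",
         call. = FALSE)
  }
  u <- sv$u[, 1]
  s <- sv$d[1] * u
  flip <- sign(u[which.max(abs(u))])
  s <- s * flip
  names(s) <- rownames(block)
  s
}
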