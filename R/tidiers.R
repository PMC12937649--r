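#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted multichannel FMM model
#'
#' One row per component x channel: the phase parameters shared across
#' channels (`alpha`, `omega`), the orientation `mode`, and the
#' channel-specific `amplitude` and phase offset `delta` recovered from the
#' mixing block. For fixed-orientation components the `signed_amplitude`
#' column carries the rank-one factorisation's signed channel weights (the
#' quantity mapped in scalp topographies); it is `NA` for free components.
#'
#' @param x An `fmm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `mode`, `alpha`, `omega`,
#'   `channel`, `amplitude`, `delta`, `signed_amplitude`, `r2`.
#' @exportS3Method generics::tidy
tidy.fmm_fit <- function(x, ...) {
  m <- x$model
  purrr::map_dfr(seq_along(m$blocks), function(d) {
    ap <- block_to_amp_phase(m$blocks[[d]])
    sa <- if (m$modes[d] == "fixed") {
      tryCatch(signed_amplitudes(m$blocks[[d]], tol = 1e-4),
               error = function(e) rep(NA_real_, nrow(ap)))
    } else {
      rep(NA_real_, nrow(ap))
    }
    tibble::tibble(
      component = d,
      mode = m$modes[d],
      alpha = m$thetas$alpha[d],
      omega = m$thetas$omega[d],
      channel = as.character(ap$channel),
      amplitude = ap$amplitude,
      delta = ap$delta,
      signed_amplitude = as.numeric(sa),
      r2 = as.numeric(x$fit$r2)
    )
  })
}

#' One-row summary of a fitted multichannel FMM model
#'
#' @param x An `fmm_fit`.
#' @param ... Unused.
#' @return A tibble with `K`, `modes`, `loglik`, `n_iters`, `converged`,
#'   `mean_r2`, `p95_r2`, and `sigma_structure`.
#' @exportS3Method generics::glance
glance.fmm_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    modes = paste(x$model$modes, collapse = "/"),
    loglik = utils::tail(x$fit$loglik_trace, 1),
    n_iters = x$fit$n_iters,
    converged = x$fit$converged,
    mean_r2 = mean(x$fit$r2, na.rm = TRUE),
    p95_r2 = r2_quantile(x$fit$r2, 0.95),
    sigma_structure = x$model$sigma_structure
  )
}

#' Tidy a model-comparison report
#'
#' @param x An `fmm_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per channel: `channel`, `r2_free`,
#'   `r2_fixed`, and whether the channel is in the `selected` upper tail.
#' @exportS3Method generics::tidy
tidy.fmm_comparison <- function(x, ...) {
  G <- length(x$r2_free)
  tibble::tibble(
    channel = names(x$r2_free) %||% as.character(seq_len(G)),
    r2_free = as.numeric(x$r2_free),
    r2_fixed = as.numeric(x$r2_fixed),
    selected = seq_len(G) %in% x$selected_channels
  )
}

#' One-row summary of a model comparison
#'
#' @param x An `fmm_comparison`.
#' @param ... Unused.
#' @return A tibble with `p95_free`, `p95_fixed`, `dif_r2`, `K`, `q`, and
#'   `n_selected`.
#' @exportS3Method generics::glance
glance.fmm_comparison <- function(x, ...) {
  tibble::tibble(
    p95_free = x$p95_free, p95_fixed = x$p95_fixed, dif_r2 = x$dif_r2,
    K = x$K, q = x$q, n_selected = length(x$selected_channels)
  )
}

#' Plot observed and fitted channel time courses
#'
#' @param object An `fmm_fit`.
#' @param channels Channel names to show (default: up to 9 by decreasing
#'   R-squared).
#' @param ... Unused.
#' @return A ggplot object: observed (points/line) and fitted (line) per
#'   channel facet.
#' @exportS3Method ggplot2::autoplot
autoplot.fmm_fit <- function(object, channels = NULL, ...) {
  v <- object$data
  if (is.null(channels)) {
    ord <- order(object$fit$r2, decreasing = TRUE)
    channels <- v$channels[ord[seq_len(min(9, length(ord)))]]
  }
  obs <- erp_tibble(v$t, v$Y, v$channels) |>
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "observed")
  fitd <- erp_tibble(v$t, object$fit$fitted, v$channels) |>
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "fitted")
  df <- dplyr::inner_join(obs, fitd, by = c("t", "channel")) |>
    dplyr::filter(.data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d1495b") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (radians)", y = "voltage (a.u.)",
                  title = "Observed (grey) vs fitted (red) channel time courses") +
    ggplot2::theme_minimal()
}

#' Plot a free-vs-fixed model comparison
#'
#' @param object An `fmm_comparison`.
#' @param ... Unused.
#' @return A ggplot object: per-channel R-squared under the two fits, with
#'   upper-tail channels highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.fmm_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r2_free, y = .data$r2_fixed,
                                   colour = .data$selected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#d1495b"),
                                 name = "upper tail") +
    ggplot2::labs(x = "channel R², free orientation",
                  y = "channel R², fixed orientation",
                  title = sprintf("difR² = %+.4f (K = %d, q = %.2f)",
                                  object$dif_r2, object$K, object$q)) +
    ggplot2::theme_minimal()
}
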