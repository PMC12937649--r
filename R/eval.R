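#' Channel-wise coefficient of determination
#'
#' `R2_g = 1 - SSE_g / SST_g` per channel, comparing fitted to observed
#' time courses. Channels with zero sample variance have no defined R2 and
#' are returned as `NA` (they are excluded from quantile summaries and
#' channel selection, never silently coerced to 0).
#'
#' @param Y,fitted T x G matrices of equal shape, `T >= 2`.
#' @return Named numeric vector of G values, each `<= 1` (or `NA`).
#' @export
channel_r2 <- function(Y, fitted) {
  Y <- as.matrix(Y); fitted <- as.matrix(fitted)
  if (!all(dim(Y) == dim(fitted))) stop("shape mismatch", call. = FALSE)
  if (nrow(Y) < 2L) stop("need at least 2 time points", call. = FALSE)
  sse <- colSums((Y - fitted)^2)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(sst == 0, NA_real_, 1 - sse / sst)
  stats::setNames(r2, colnames(Y))
}

#' Quantile of a channel R-squared distribution
#'
#' Empirical quantile with linear interpolation between order statistics at
#' position `1 + q * (n - 1)` (the common statistical-software default);
#' undefined (`NA`) values are excluded.
#'
#' @param r2 Numeric vector of channel R-squared values (may contain `NA`).
#' @param q Quantile level in `(0, 1]`.
#' @return A single numeric value.
#' @export
r2_quantile <- function(r2, q = 0.95) {
  if (length(q) != 1L || q <= 0 || q > 1) stop("`q` must be in (0, 1]", call. = FALSE)
  r2 <- r2[!is.na(r2)]
  if (length(r2) == 0L) stop("no defined R-squared values", call. = FALSE)
  unname(stats::quantile(r2, q, type = 7))
}

#' Upper-tail channel selection
#'
#' Indices of channels whose R-squared reaches at least the level-`q`
#' quantile of the distribution. Model comparison is restricted to this
#' upper tail, computed under the complete (free-orientation) fit, so that
#' noise-dominated channels do not drive the comparison.
#'
#' @inheritParams r2_quantile
#' @return Integer vector of selected channel indices (never empty for a
#'   non-degenerate input).
#' @export
upper_tail_channels <- function(r2, q = 0.95) {
  thr <- r2_quantile(r2, q)
  which(!is.na(r2) & r2 >= thr)
}

#' Build a model-comparison report from two R-squared vectors
#'
#' @param r2_free,r2_fixed Channel R-squared vectors under the free
#'   (complete) and fixed-orientation (reduced-rank) fits.
#' @param K Number of components used by both fits.
#' @param q Quantile level for the upper-tail summary (default 0.95).
#' @param tail_mean If `TRUE`, `p95` summaries are the mean R-squared over
#'   the selected upper-tail channels instead of the quantile value
#'   (non-default reading of the summary).
#' @return An object of class `fmm_comparison`: list with `r2_free`,
#'   `r2_fixed`, `p95_free`, `p95_fixed`, `dif_r2 = p95_free - p95_fixed`,
#'   `selected_channels` (upper tail under the free fit), `K`, `q`.
#' @export
comparison_report <- function(r2_free, r2_fixed, K, q = 0.95,
                              tail_mean = FALSE) {
  if (length(r2_free) != length(r2_fixed)) {
    stop("R-squared vectors must have equal length", call. = FALSE)
  }
  sel <- upper_tail_channels(r2_free, q)
  if (tail_mean) {
    p_a <- mean(r2_free[sel])
    p_b <- mean(r2_fixed[upper_tail_channels(r2_fixed, q)])
  } else {
    p_a <- r2_quantile(r2_free, q)
    p_b <- r2_quantile(r2_fixed, q)
  }
  structure(list(r2_free = r2_free, r2_fixed = r2_fixed,
                 p95_free = p_a, p95_fixed = p_b,
                 dif_r2 = p_a - p_b,
                 selected_channels = sel,
                 K = as.integer(K), q = q),
            class = "fmm_comparison")
}

#' @export
print.fmm_comparison <- function(x, ...) {
  cat(sprintf(
    "<fmm_comparison> K = %d, q = %.2f | free %.5f vs fixed %.5f | difR2 %+.5f\n",
    x$K, x$q, x$p95_free, x$p95_fixed, x$dif_r2))
  cat(sprintf("  upper-tail channels (free fit): %s\n",
              paste(names(x$r2_free)[x$selected_channels] %||%
                      x$selected_channels, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare free- and fixed-orientation fits of the same ERP
#'
#' Fits the complete (all components free, "Model A") and reduced-rank
#' (all components fixed, "Model B") variants with identical K and
#' configuration, and summarises both by the level-`q` quantile of their
#' channel-wise R-squared distributions. `dif_r2` (free minus fixed) near
#' zero supports the fixed-orientation hypothesis; markedly positive
#' values indicate that the rank-one restriction loses real signal.
#'
#' @inheritParams fit_fmm
#' @param q Quantile level for the upper-tail summary.
#' @param tail_mean See [comparison_report()].
#' @return An `fmm_comparison` (see [comparison_report()]) with the two
#'   fits attached as attributes `fit_free` and `fit_fixed`.
#' @export
compare_models <- function(data, K = 3, config = fit_config(), q = 0.95,
                           tail_mean = FALSE) {
  fit_a <- fit_fmm(data, K = K, modes = "free", config = config)
  fit_b <- fit_fmm(data, K = K, modes = "fixed", config = config)
  rep <- comparison_report(fit_a$fit$r2, fit_b$fit$r2, K = K, q = q,
                           tail_mean = tail_mean)
  attr(rep, "fit_free") <- fit_a
  attr(rep, "fit_fixed") <- fit_b
  rep
}

#' Summarise per-recording model comparisons
#'
#' Given a table of upper-tail R-squared summaries per recording (one row
#' per participant/recording, columns `p95_free` and `p95_fixed`),
#' recomputes the per-row difference `dif_r2 = p95_free - p95_fixed` and
#' appends a `Total` row holding the column means — the arithmetic used to
#' aggregate a model-comparison study across participants.
#'
#' @param df Data frame with columns `participant` (optional), `p95_free`,
#'   `p95_fixed`.
#' @return A tibble with columns `participant`, `p95_free`, `p95_fixed`,
#'   `dif_r2`, ending in a `Total` mean row.
#' @export
summarize_comparisons <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("p95_free", "p95_fixed") %in% names(df))) {
    stop("`df` needs columns `p95_free` and `p95_fixed`", call. = FALSE)
  }
  out <- tibble::tibble(
    participant = if ("participant" %in% names(df)) as.character(df$participant)
                  else as.character(seq_len(nrow(df))),
    p95_free = df$p95_free,
    p95_fixed = df$p95_fixed,
    dif_r2 = df$p95_free - df$p95_fixed
  )
  dplyr::bind_rows(out, tibble::tibble(
    participant = "Total",
    p95_free = mean(out$p95_free),
    p95_fixed = mean(out$p95_fixed),
    dif_r2 = mean(out$dif_r2)
  ))
}
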