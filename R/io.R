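#' Read a multichannel ERP from delimited text
#'
#' Expects a comma-separated file with a header row. An optional leading
#' `t` column gives the time grid in radians on `[0, 2*pi)`; without it the
#' uniform grid `t_i = 2*pi*(i-1)/T` is synthesised. All remaining columns
#' are channels.
#'
#' @param path Path to a CSV file.
#' @return A tibble with column `t` and one numeric column per channel.
#' @export
read_erp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         comment.char = "#")
  if (ncol(raw) < 1L || nrow(raw) < 1L) stop("empty ERP file: ", path, call. = FALSE)
  chans <- names(raw)
  if (identical(chans[1], "t")) {
    if (ncol(raw) < 2L) stop("ERP file has a time column but no channels", call. = FALSE)
    if (anyDuplicated(chans[-1])) {
      stop("duplicate channel names: ",
           paste(unique(chans[-1][duplicated(chans[-1])]), collapse = ", "),
           call. = FALSE)
    }
  } else if (anyDuplicated(chans)) {
    stop("duplicate channel names: ",
         paste(unique(chans[duplicated(chans)]), collapse = ", "), call. = FALSE)
  }
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw), dimnames = list(NULL, chans))
  bad <- which(is.na(num) & !is.na(as.matrix(raw)), arr.ind = TRUE)
  if (nrow(bad) > 0 || anyNA(num)) {
    row <- if (nrow(bad) > 0) bad[1, 1] else which(is.na(num), arr.ind = TRUE)[1, 1]
    stop(sprintf("non-numeric or missing cell at line %d of %s",
                 row + 1L, path), call. = FALSE)
  }
  if (any(!is.finite(num))) stop("non-finite values in ", path, call. = FALSE)
  if (identical(chans[1], "t")) {
    t <- num[, 1]
    check_time_grid(t)
    erp_tibble(t, num[, -1, drop = FALSE], chans[-1])
  } else {
    erp_tibble(time_grid(nrow(num)), num, chans)
  }
}

#' Write a multichannel ERP to delimited text
#'
#' Writes a CSV with a leading `t` column (radians) and full-precision
#' (`%.17g`) values, so a read/write round trip is exact.
#'
#' @param erp Data frame with optional `t` column and channel columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_erp <- function(erp, path) {
  v <- as_erp_values(erp)
  if (ncol(v$Y) < 1L) stop("refusing to write an ERP with zero channels", call. = FALSE)
  header <- paste(vapply(c("t", v$channels), csv_quote, character(1)),
                  collapse = ",")
  body <- apply(cbind(v$t, v$Y), 1, function(r) {
    paste(sprintf("%.17g", r), collapse = ",")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

csv_quote <- function(x) {
  if (grepl('[",\n]', x)) paste0('"', gsub('"', '""', x), '"') else x
}

#' Read an electrode montage from delimited text
#'
#' Expects a CSV with header `name,x,y,z`. A leading comment line of the
#' form `# sigma=<value>` sets the medium conductivity (default
#' `1/(4*pi)`).
#'
#' @param path Path to a CSV file.
#' @return A [montage()].
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  sigma <- 1 / (4 * pi)
  meta <- grep("^#", lines, value = TRUE)
  sig_line <- grep("sigma\\s*=", meta, value = TRUE)
  if (length(sig_line) > 0) {
    sigma <- as.numeric(sub(".*sigma\\s*=\\s*", "", sig_line[1]))
    if (is.na(sigma)) stop("unparseable sigma metadata line", call. = FALSE)
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE)
  need <- c("name", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("montage file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate electrode names in montage", call. = FALSE)
  }
  montage(df$name, as.matrix(df[, c("x", "y", "z")]), sigma = sigma)
}

#' Write an electrode montage
#'
#' @param m A [montage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "rrfmm_montage"))
  body <- apply(cbind(m$channel_names,
                      matrix(sprintf("%.17g", m$positions), nrow = nrow(m$positions))),
                1, paste, collapse = ",")
  writeLines(c(sprintf("# sigma=%.17g", m$sigma), "name,x,y,z", body), path)
  invisible(path)
}

# md5 of the canonical JSON serialisation; stamps every output artifact.
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Serialise a fitted model to structured text
#'
#' JSON document with format tag, seed, config hash, baseline, per-component
#' phase parameters / mode / mixing-block rows by channel, the noise
#' covariance, and fit metadata (iteration count, convergence flag,
#' log-likelihood trace).
#'
#' @param fit An `fmm_fit` from [fit_fmm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "fmm_fit"))
  m <- fit$model
  doc <- list(
    format = "rrfmm-model/1",
    seed = fit$config$seed,
    config_hash = config_hash(unclass(fit$config)),
    channels = m$channels,
    baseline = as.numeric(m$baseline),
    components = lapply(seq_along(m$blocks), function(d) list(
      alpha = fit$model$thetas$alpha[d],
      omega = fit$model$thetas$omega[d],
      mode = m$modes[d],
      block = unname(apply(m$blocks[[d]], 1, function(r) as.numeric(r),
                           simplify = FALSE))
    )),
    sigma = list(structure = m$sigma_structure,
                 values = if (m$sigma_structure == "diagonal") diag(m$sigma)
                          else unname(apply(m$sigma, 1, as.numeric, simplify = FALSE))),
    fit = list(n_iters = fit$fit$n_iters, converged = fit$fit$converged,
               loglik_trace = fit$fit$loglik_trace,
               r2 = as.numeric(fit$fit$r2), notes = fit$fit$notes)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialised model
#'
#' @param path Path written by [write_model()].
#' @return An `fmm_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "rrfmm-model/1")) {
    stop("not an rrfmm model file: ", path, call. = FALSE)
  }
  G <- length(doc$channels)
  comp <- doc$components
  blocks <- lapply(seq_len(nrow(comp)), function(d) {
    b <- comp$block[[d]]
    blk <- if (is.matrix(b)) b else do.call(rbind, b)
    rownames(blk) <- doc$channels
    colnames(blk) <- NULL
    blk
  })
  sigma <- if (identical(doc$sigma$structure, "diagonal")) {
    diag(doc$sigma$values, nrow = G)
  } else {
    do.call(rbind, doc$sigma$values)
  }
  structure(list(
    baseline = stats::setNames(doc$baseline, doc$channels),
    blocks = blocks,
    thetas = tibble::tibble(alpha = comp$alpha, omega = comp$omega),
    sigma = sigma,
    sigma_structure = doc$sigma$structure,
    modes = comp$mode,
    channels = doc$channels
  ), class = "fmm_model")
}

#' Serialise a model-comparison report
#'
#' Writes the JSON report and, if `summary_path` is given, a one-row CSV
#' with columns `p95_A,p95_B,dif_r2,K,q`.
#'
#' @param report An `fmm_comparison`.
#' @param path Output JSON path.
#' @param summary_path Optional CSV summary path.
#' @param seed,hash Optional metadata stamped into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, summary_path = NULL, seed = NULL,
                         hash = NULL) {
  stopifnot(inherits(report, "fmm_comparison"))
  doc <- list(
    format = "rrfmm-report/1",
    seed = seed, config_hash = hash,
    K = report$K, q = report$q,
    p95_free = report$p95_free, p95_fixed = report$p95_fixed,
    dif_r2 = report$dif_r2,
    selected_channels = report$selected_channels,
    r2_free = as.numeric(report$r2_free),
    r2_fixed = as.numeric(report$r2_fixed),
    channels = names(report$r2_free)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(summary_path)) {
    writeLines(c("p95_A,p95_B,dif_r2,K,q",
                 sprintf("%.17g,%.17g,%.17g,%d,%.17g",
                         report$p95_free, report$p95_fixed, report$dif_r2,
                         report$K, report$q)),
               summary_path)
  }
  invisible(path)
}
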