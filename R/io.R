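# Container formats: numeric arrays as flat little-endian float64 binary
# files with a JSON sidecar carrying dimensions and metadata; tables as
# CSV with documented headers; models and reports as JSON.

write_array_bin <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
}

read_array_bin <- function(path, dim = NULL) {
  n <- file.info(path)$size / 8
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  if (!is.null(dim)) dim(x) <- dim
  x
}

#' Write / read an EEG recording
#'
#' `<prefix>.bin` holds the channels x samples matrix (column-major
#' float64); `<prefix>.json` holds `fs`, `channel_names`, `t0` and
#' optionally `block_bounds`.
#'
#' @param eeg an `eeg_recording`.
#' @param prefix file path prefix.
#' @param blocks optional block bounds data.frame stored in the sidecar.
#' @return `write_eeg` returns `prefix` invisibly; `read_eeg` returns a
#'   list with `eeg` and `blocks` (NULL if absent).
#' @export
write_eeg <- function(eeg, prefix, blocks = NULL) {
  write_array_bin(eeg$data, paste0(prefix, ".bin"))
  meta <- list(fs = eeg$fs, channel_names = eeg$channel_names, t0 = eeg$t0,
               n_channels = nrow(eeg$data), n_samples = ncol(eeg$data))
  if (!is.null(blocks)) meta$block_bounds <- blocks
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  data <- read_array_bin(paste0(prefix, ".bin"),
                         dim = c(meta$n_channels, meta$n_samples))
  eeg <- eeg_recording(data, meta$fs, meta$channel_names, meta$t0)
  blocks <- if (!is.null(meta$block_bounds)) as.data.frame(meta$block_bounds)
  list(eeg = eeg, blocks = blocks)
}

#' Write / read a PSD time series
#' @param psd a `psd_timeseries`.
#' @param prefix file path prefix.
#' @return `write_psd` returns `prefix` invisibly; `read_psd` a
#'   `psd_timeseries`.
#' @export
write_psd <- function(psd, prefix) {
  write_array_bin(psd$logpower, paste0(prefix, ".bin"))
  jsonlite::write_json(
    list(dim = dim(psd$logpower), freqs = psd$freqs,
         epoch_times = psd$epoch_times, channel_names = psd$channel_names,
         epoch_blocks = psd$epoch_blocks),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_psd
#' @export
read_psd <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  lp <- read_array_bin(paste0(prefix, ".bin"), dim = meta$dim)
  psd_timeseries(lp, meta$freqs, meta$epoch_times, meta$channel_names,
                 meta$epoch_blocks)
}

#' Write / read a behavior series as CSV
#'
#' Columns: `t_s`, `value`, `block_id`, `metric`.
#'
#' @param behavior a `behavior_series`.
#' @param path CSV path.
#' @return `write_behavior` returns `path` invisibly; `read_behavior` a
#'   `behavior_series`.
#' @export
write_behavior <- function(behavior, path) {
  write.csv(
    data.frame(t_s = behavior$times, value = behavior$values,
               block_id = behavior$blocks, metric = behavior$metric),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "value", "block_id", "metric")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop(sprintf("malformed behavior CSV %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  behavior_series(d$metric[1], d$t_s, d$value, d$block_id)
}

#' Write / read a fitted model bundle (JSON)
#' @param model a `spectral_model`.
#' @param path JSON path.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   `spectral_model`.
#' @export
write_model <- function(model, path) {
  b <- model$basis
  jsonlite::write_json(
    list(channels = model$channels, metric = model$metric,
         freqs = b$freqs, V = b$V, lambda = b$lambda, shares = b$shares,
         means = b$means, threshold = b$threshold,
         beta = model$beta, intercept = model$intercept),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(
    list(V = matrix(unlist(m$V), ncol = length(m$beta)), lambda = m$lambda,
         shares = m$shares, means = m$means, threshold = m$threshold,
         channels = m$channels, freqs = m$freqs),
    class = "spectral_basis"
  )
  structure(
    list(basis = basis, beta = m$beta, intercept = m$intercept,
         channels = m$channels, metric = m$metric),
    class = "spectral_model"
  )
}
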