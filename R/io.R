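#' Write an epoch_set to a flat on-disk container
#'
#' The container is a directory holding named arrays in open formats:
#' `header.json` (sampling rate, dimensions, channel labels, time axis),
#' `trials.tsv` (per-trial label, subject, RT) and `data.fdt`, the voltage
#' array as little-endian float32 in channel-major order per sample per trial
#' (the same payload layout EEGLAB uses for its companion `.fdt` files).
#' Everything but the voltage payload is plain text.
#'
#' @param x an `epoch_set`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epoch_set <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(
    format = "latstep-epochs-v1",
    srate = x$srate,
    n_trials = n_trials(x), n_channels = n_channels(x),
    n_samples = n_samples(x),
    times = x$times, channel_names = x$channel_names)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- data.frame(label = x$labels, subject = x$subjects,
                     rt_ms = if (is.null(x$rts)) NA_real_ else x$rts)
  utils::write.table(meta, file.path(path, "trials.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  # channel-major within sample, sample-major within trial
  con <- file(file.path(path, "data.fdt"), "wb")
  on.exit(close(con))
  payload <- aperm(x$data, c(2L, 3L, 1L))  # channels, samples, trials
  writeBin(as.numeric(payload), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an epoch_set written by [write_epoch_set()]
#'
#' @param path container directory.
#' @return an `epoch_set`. Voltages round-trip at float32 precision.
#' @export
read_epoch_set <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  if (!identical(header$format, "latstep-epochs-v1"))
    stop("not a latstep epochs container: ", path)
  meta <- utils::read.table(file.path(path, "trials.tsv"), sep = "\t",
                            header = TRUE, colClasses = c("character",
                                                          "character",
                                                          "numeric"))
  n <- header$n_trials * header$n_channels * header$n_samples
  con <- file(file.path(path, "data.fdt"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(raw) != n) stop("truncated data.fdt payload")
  payload <- array(raw, dim = c(header$n_channels, header$n_samples,
                                header$n_trials))
  rts <- meta$rt_ms
  if (all(is.na(rts))) rts <- NULL
  epoch_set(aperm(payload, c(3L, 1L, 2L)), srate = header$srate,
            times = header$times, channel_names = header$channel_names,
            labels = meta$label, subjects = meta$subject, rts = rts,
            check_reference = FALSE)
}
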