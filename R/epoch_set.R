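#' Epoched multi-channel EEG container
#'
#' An `epoch_set` holds single-trial voltages as a 3-D array
#' (trials x channels x samples, microvolts) together with the time axis
#' (milliseconds relative to target onset), the sampling rate, channel labels
#' and per-trial metadata: a two-level condition label, a subject identifier
#' and, when available, a reaction time in ms. All downstream operations
#' (decomposition, latency correction, decoding, attribution) consume this
#' container and nothing else.
#'
#' The time axis must be uniformly spaced with step `1000/srate` ms; data must
#' be finite. Voltages are expected to be average-referenced (mean over
#' channels approximately zero at every time point); construction warns when
#' that does not hold but does not re-reference.
#'
#' @param data numeric 3-D array, trials x channels x samples (microvolts).
#' @param srate sampling rate in Hz.
#' @param times numeric vector of per-sample latencies in ms. If `NULL`,
#'   constructed from `tmin` and `srate`.
#' @param tmin latency of the first sample in ms (used when `times` is `NULL`).
#' @param channel_names character vector of channel labels, one per channel.
#' @param labels per-trial condition tag (coerced to character).
#' @param subjects per-trial subject identifier (coerced to character).
#' @param rts per-trial reaction time in ms, `NA` allowed; may be `NULL` for
#'   simulated no-response data.
#' @param check_reference if `TRUE` (default) warn when the data are not
#'   average-referenced within tolerance `1e-6 * max(abs(data))`.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate, times = NULL, tmin = NULL,
                      channel_names = NULL, labels, subjects = NULL,
                      rts = NULL, check_reference = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trials x channels x samples)")
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("`data` contains non-finite values")
  n_trials <- dim(data)[1L]
  n_chan <- dim(data)[2L]
  n_samp <- dim(data)[3L]
  if (n_chan < 1L || n_samp < 1L || n_trials < 1L)
    stop("empty epoch_set")
  if (is.null(times)) {
    if (is.null(tmin)) stop("supply either `times` or `tmin`")
    times <- tmin + (seq_len(n_samp) - 1L) * 1000 / srate
  }
  if (length(times) != n_samp)
    stop("length(times) must equal the number of samples")
  step <- 1000 / srate
  if (n_samp > 1L) {
    d <- diff(times)
    if (any(d <= 0) || max(abs(d - step)) > 1e-6 * step)
      stop("`times` must be strictly increasing with step 1000/srate ms")
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(n_chan))
  if (length(channel_names) != n_chan)
    stop("length(channel_names) must equal the number of channels")
  labels <- as.character(labels)
  if (length(labels) != n_trials)
    stop("length(labels) must equal the number of trials")
  if (is.null(subjects)) subjects <- rep("s01", n_trials)
  subjects <- as.character(subjects)
  if (length(subjects) != n_trials)
    stop("length(subjects) must equal the number of trials")
  if (!is.null(rts)) {
    rts <- as.numeric(rts)
    if (length(rts) != n_trials)
      stop("length(rts) must equal the number of trials")
  }
  if (check_reference && n_chan >= 2L) {
    scale <- max(abs(data))
    if (scale > 0) {
      # channel mean at every (trial, time); apply() over margins 1 and 3
      chan_mean <- apply(data, c(1L, 3L), mean)
      if (max(abs(chan_mean)) > 1e-6 * scale)
        warning("data do not appear to be average-referenced ",
                "(max |channel mean| = ", signif(max(abs(chan_mean)), 3),
                " uV); proceeding without re-referencing")
    }
  }
  structure(
    list(data = data, times = as.numeric(times), srate = srate,
         channel_names = as.character(channel_names),
         labels = labels, subjects = subjects, rts = rts),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$srate))
  cat(sprintf("  time span: [%g, %g] ms; conditions: %s; subjects: %d\n",
              x$times[1L], x$times[length(x$times)],
              paste(sort(unique(x$labels)), collapse = "/"),
              length(unique(x$subjects))))
  if (!is.null(x$rts))
    cat(sprintf("  RTs: median %g ms (%d missing)\n",
                stats::median(x$rts, na.rm = TRUE), sum(is.na(x$rts))))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1L]
n_channels <- function(x) dim(x$data)[2L]
n_samples <- function(x) dim(x$data)[3L]

#' Subset an epoch_set by trial index
#'
#' @param x an `epoch_set`.
#' @param trials integer or logical trial index.
#' @return an `epoch_set` with the selected trials; metadata subset in step.
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "epoch_set"))
  data <- x$data[trials, , , drop = FALSE]
  if (dim(data)[1L] == 0L) stop("trial subset is empty")
  epoch_set(data, srate = x$srate, times = x$times,
            channel_names = x$channel_names,
            labels = x$labels[trials], subjects = x$subjects[trials],
            rts = if (is.null(x$rts)) NULL else x$rts[trials],
            check_reference = FALSE)
}

#' Replace the voltage array of an epoch_set, keeping metadata
#' @noRd
replace_data <- function(x, data, times = x$times) {
  epoch_set(data, srate = x$srate, times = times,
            channel_names = x$channel_names, labels = x$labels,
            subjects = x$subjects, rts = x$rts, check_reference = FALSE)
}

#' Round half away from zero
#'
#' Used for every ms-to-sample conversion so that a +50 ms lag at 250 Hz maps
#' to 13 samples (not 12 as under banker's rounding).
#' @param x numeric.
#' @return integer vector.
#' @export
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Convert milliseconds to integer samples
#' @param ms numeric vector of durations in ms.
#' @param srate sampling rate in Hz.
#' @return integer sample counts, rounded half away from zero.
#' @export
ms_to_samples <- function(ms, srate) round_half_away(ms * srate / 1000)

#' Global field power
#'
#' GFP at a time point is the population standard deviation (divide by the
#' number of channels, not N-1) of the voltages across all electrodes. For a
#' channels x samples matrix a value per time point is returned; for an
#' `epoch_set` a trials x samples matrix.
#'
#' @param x numeric vector (one snapshot), channels x samples matrix, or
#'   `epoch_set`.
#' @return scalar, vector, or trials x samples matrix of nonnegative values.
#' @export
gfp <- function(x) UseMethod("gfp")

#' @export
gfp.default <- function(x) {
  v <- as.numeric(x)
  if (length(v) < 2L) stop("GFP requires at least 2 channels")
  if (any(!is.finite(v))) stop("GFP input must be finite")
  sqrt(mean((v - mean(v))^2))
}

#' @export
gfp.matrix <- function(x) {
  if (nrow(x) < 2L) stop("GFP requires at least 2 channels")
  if (any(!is.finite(x))) stop("GFP input must be finite")
  m <- colMeans(x)
  sqrt(colMeans(x^2) - m^2)
}

#' @export
gfp.epoch_set <- function(x) {
  if (n_channels(x) < 2L) stop("GFP requires at least 2 channels")
  # population variance across channels for every (trial, sample)
  m <- apply(x$data, c(1L, 3L), mean)
  m2 <- apply(x$data^2, c(1L, 3L), mean)
  out <- sqrt(pmax(m2 - m^2, 0))
  dimnames(out) <- NULL
  out
}

#' Shift one trial along the time axis
#'
#' Positive `lag` moves the content later in time; vacated samples are filled
#' with zeros (the same zero padding later excluded from the analysis window).
#'
#' @param trial channels x samples numeric matrix.
#' @param lag integer shift in samples; `abs(lag)` must be smaller than the
#'   sample count.
#' @return shifted matrix of identical shape.
#' @export
shift_trial <- function(trial, lag) {
  stopifnot(is.matrix(trial))
  lag <- as.integer(lag)
  n <- ncol(trial)
  if (abs(lag) >= n)
    stop("|lag| (", abs(lag), ") must be < sample count (", n, ")")
  if (lag == 0L) return(trial)
  out <- matrix(0, nrow(trial), n)
  if (lag > 0L) {
    out[, (lag + 1L):n] <- trial[, 1L:(n - lag)]
  } else {
    out[, 1L:(n + lag)] <- trial[, (1L - lag):n]
  }
  out
}

#' Shift every trial of an epoch_set by per-trial lags
#' @param x an `epoch_set`.
#' @param lags integer vector, one lag (samples) per trial.
#' @return an `epoch_set` with shifted data.
#' @export
shift_epochs <- function(x, lags) {
  stopifnot(inherits(x, "epoch_set"), length(lags) == n_trials(x))
  data <- x$data
  for (i in seq_len(n_trials(x)))
    data[i, , ] <- shift_trial(data[i, , , drop = TRUE], lags[i])
  replace_data(x, data)
}

#' Crop an epoch_set to a half-open time window
#'
#' Retains samples with `start_ms <= t < end_ms`. The half-open convention
#' makes a 1-second window at 250 Hz exactly 250 samples.
#'
#' @param x an `epoch_set`.
#' @param start_ms,end_ms window bounds in ms.
#' @return cropped `epoch_set`.
#' @export
crop_epochs <- function(x, start_ms, end_ms) {
  stopifnot(inherits(x, "epoch_set"), end_ms > start_ms)
  keep <- x$times >= start_ms & x$times < end_ms
  if (!any(keep)) stop("crop window [", start_ms, ", ", end_ms,
                       ") contains no samples")
  replace_data(x, x$data[, , keep, drop = FALSE], times = x$times[keep])
}

#' Per-condition averaged ERP and difference wave
#'
#' @param x an `epoch_set`.
#' @param conditions which condition labels to average; default all present.
#' @return list with `erp` (named list of channels x samples matrices),
#'   `difference` (first minus second condition when exactly two), and `times`.
#' @export
average_erp <- function(x, conditions = NULL) {
  stopifnot(inherits(x, "epoch_set"))
  if (is.null(conditions)) conditions <- sort(unique(x$labels))
  erp <- list()
  for (cond in conditions) {
    idx <- which(x$labels == cond)
    if (length(idx) == 0L) stop("condition '", cond, "' has no trials")
    m <- apply(x$data[idx, , , drop = FALSE], c(2L, 3L), mean)
    dimnames(m) <- list(x$channel_names, NULL)
    erp[[cond]] <- m
  }
  out <- list(erp = erp, times = x$times)
  if (length(conditions) == 2L)
    out$difference <- erp[[conditions[1L]]] - erp[[conditions[2L]]]
  out
}

#' Reaction-time trial exclusion (minimum RT + Tukey fences)
#'
#' Drops trials with missing RT, RT below `min_rt_ms`, or RT outside the Tukey
#' fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` computed separately for every
#' subject x condition cell (so a condition-wise RT difference cannot
#' masquerade as outliers). The fences are re-applied until no further trial
#' is removed, which makes the filter a projection: running it on its own
#' output changes nothing.
#'
#' @param x an `epoch_set` with RTs.
#' @param min_rt_ms minimum admissible RT in ms (default 200).
#' @param k fence multiplier (default 1.5).
#' @return filtered `epoch_set`; attribute `"kept"` holds the retained trial
#'   indices relative to the input.
#' @export
tukey_rt_filter <- function(x, min_rt_ms = 200, k = 1.5) {
  stopifnot(inherits(x, "epoch_set"))
  if (is.null(x$rts)) stop("tukey_rt_filter requires reaction times")
  rts <- x$rts
  keep <- !is.na(rts) & rts >= min_rt_ms
  cell <- interaction(x$subjects, x$labels, drop = TRUE)
  repeat {
    removed <- FALSE
    for (cl in levels(cell)) {
      idx <- which(cell == cl & keep)
      if (length(idx) == 0L) next
      q <- stats::quantile(rts[idx], c(0.25, 0.75), names = FALSE)
      iqr <- q[2L] - q[1L]
      bad <- rts[idx] < q[1L] - k * iqr | rts[idx] > q[2L] + k * iqr
      if (any(bad)) removed <- TRUE
      keep[idx[bad]] <- FALSE
    }
    if (!removed) break
  }
  dropped_cells <- setdiff(levels(cell), levels(droplevels(cell[keep])))
  if (length(dropped_cells))
    warning("all trials removed for cell(s): ",
            paste(dropped_cells, collapse = ", "))
  if (!any(keep)) stop("no trials survive the RT filter")
  out <- subset_trials(x, which(keep))
  attr(out, "kept") <- which(keep)
  out
}

#' Per-channel covariance between a trial and a component template
#'
#' For every channel, the population covariance (divide by the number of
#' samples) between the trial and the template over the template's window.
#' Used as the per-trial amplitude-variability measure when sorting trials
#' against their component template.
#'
#' @param trial channels x samples matrix on the template's grid.
#' @param template an `erp_template`.
#' @return named numeric vector, one covariance per channel.
#' @export
amplitude_variability <- function(trial, template) {
  stopifnot(is.matrix(trial), inherits(template, "erp_template"))
  idx <- template_window_idx(template)
  if (length(idx) == 0L) stop("template window contains no samples")
  if (ncol(trial) != length(template$times))
    stop("trial and template are not on the same time grid")
  x <- trial[, idx, drop = FALSE]
  y <- template$values[, idx, drop = FALSE]
  cv <- rowMeans(x * y) - rowMeans(x) * rowMeans(y)
  names(cv) <- rownames(template$values)
  cv
}

#' Component template
#'
#' A channels x samples waveform defined inside a time window and zero
#' outside it, on the same grid as its parent `epoch_set`.
#'
#' @param values channels x samples matrix (zero outside `window`).
#' @param times ms axis matching the parent epochs.
#' @param window numeric length-2, `[start, end)` ms of the defined region.
#' @return an object of class `erp_template`.
#' @export
erp_template <- function(values, times, window) {
  stopifnot(is.matrix(values), length(times) == ncol(values),
            length(window) == 2L, window[2L] > window[1L])
  structure(list(values = values, times = as.numeric(times),
                 window = as.numeric(window)),
            class = "erp_template")
}

template_window_idx <- function(template) {
  which(template$times >= template$window[1L] &
          template$times < template$window[2L])
}

#' @export
print.erp_template <- function(x, ...) {
  cat(sprintf("<erp_template> %d channels, window [%g, %g) ms, peak |v| %.3g uV\n",
              nrow(x$values), x$window[1L], x$window[2L], max(abs(x$values))))
  invisible(x)
}
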