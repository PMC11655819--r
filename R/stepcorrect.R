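#' Step 2: remove within-condition latency jitter
#'
#' Each C-component trial is shifted by the negative of its estimated latency
#' lag (a trial whose pattern occurs 50 ms late is moved 50 ms forward),
#' zero-padding the vacated samples. Only the per-trial jitter is removed;
#' overall latency differences between conditions and participants are
#' preserved because lags are relative to each cell's own template.
#'
#' @param step1 an `epoch_set` of C-component trials (see
#'   [extract_c_trials()]).
#' @param c_lags integer per-trial lags in samples from the same
#'   decomposition; defaults to the `"c_lags"` attribute of `step1`.
#' @return an `epoch_set` with jitter-corrected trials; attribute
#'   `"applied_shifts"` holds the per-trial shifts in samples.
#' @export
correct_within_condition <- function(step1, c_lags = attr(step1, "c_lags")) {
  stopifnot(inherits(step1, "epoch_set"))
  if (is.null(c_lags)) stop("no c_lags supplied or attached to `step1`")
  stopifnot(length(c_lags) == n_trials(step1))
  out <- shift_epochs(step1, -as.integer(c_lags))
  attr(out, "applied_shifts") <- -as.integer(c_lags)
  out
}

#' Peak latency of a template at one electrode
#'
#' The latency of the maximum absolute value (or of the maximum/minimum when a
#' polarity is requested) at the given electrode inside a search window; exact
#' ties resolve to the earliest sample.
#'
#' @param template an `erp_template`, or a channels x samples matrix with a
#'   `times` argument.
#' @param electrode channel label.
#' @param window search window in ms (default: the template window).
#' @param polarity "abs" (default), "pos" or "neg".
#' @param channel_names,times required when `template` is a bare matrix.
#' @return peak latency in ms (on the sample grid).
#' @export
template_peak_latency <- function(template, electrode, window = NULL,
                                  polarity = c("abs", "pos", "neg"),
                                  channel_names = NULL, times = NULL) {
  polarity <- match.arg(polarity)
  if (inherits(template, "erp_template")) {
    values <- template$values
    times <- template$times
    if (is.null(window)) window <- template$window
    if (is.null(channel_names)) channel_names <- rownames(values)
  } else values <- template
  if (is.null(channel_names) || is.null(times))
    stop("bare-matrix input needs `channel_names` and `times`")
  ch <- match(electrode, channel_names)
  if (is.na(ch)) stop("electrode '", electrode, "' not found")
  idx <- which(times >= window[1L] & times < window[2L])
  if (length(idx) == 0L) stop("empty search window")
  v <- values[ch, idx]
  score <- switch(polarity, abs = abs(v), pos = v, neg = -v)
  if (max(score) == min(score))
    stop("template is flat at electrode '", electrode, "' in the window")
  times[idx[which.max(score)]]
}

condition_templates <- function(epochs, window) {
  avg <- average_erp(epochs)
  lapply(avg$erp, function(m) erp_template(m, epochs$times, window))
}

#' Step 3: synchronize peak latencies between conditions
#'
#' Per subject, each condition's C template (the average of its
#' jitter-corrected trials) is reduced to its peak latency at the reference
#' electrode inside the C window; the median of the two condition peaks (their
#' midpoint) becomes the subject's target latency, and all trials of each
#' condition are shifted uniformly to it. This removes the between-condition
#' latency shift while leaving within-condition structure untouched.
#'
#' @param step2 an `epoch_set` with exactly two conditions.
#' @param c_window search window in ms for the template peak.
#' @param reference_electrode channel used for synchronization (default 'Pz').
#' @param polarity peak polarity convention, see [template_peak_latency()].
#' @return an `epoch_set`; attributes `"applied_shifts"` (per-trial samples),
#'   `"peak_latencies"` (data.frame subject x condition peaks and shifts) and
#'   `"target_ms"` (per-subject target latency).
#' @export
correct_between_conditions <- function(step2, c_window = c(200, 900),
                                       reference_electrode = "Pz",
                                       polarity = "abs") {
  stopifnot(inherits(step2, "epoch_set"))
  conds <- sort(unique(step2$labels))
  if (length(conds) != 2L)
    stop("between-condition synchronization needs exactly two conditions")
  data <- step2$data
  shifts <- integer(n_trials(step2))
  rows <- list()
  for (sid in unique(step2$subjects)) {
    s_idx <- which(step2$subjects == sid)
    sub <- subset_trials(step2, s_idx)
    if (!all(conds %in% sub$labels))
      stop("subject ", sid, " is missing a condition")
    tpl <- condition_templates(sub, c_window)
    peaks <- vapply(conds, function(cond)
      template_peak_latency(tpl[[cond]], reference_electrode,
                            window = c_window, polarity = polarity,
                            channel_names = step2$channel_names),
      numeric(1))
    target <- stats::median(peaks)
    # round the first condition's shift to the grid, then derive the second
    # from the exact peak difference in samples: what Step 3 must equalize is
    # the relative latency, and independent rounding could leave the two
    # conditions one sample apart
    shift1 <- ms_to_samples(target - peaks[[1L]], step2$srate)
    dpk <- ms_to_samples(peaks[[2L]] - peaks[[1L]], step2$srate)
    shift_of <- stats::setNames(c(shift1, shift1 - dpk), conds)
    for (cond in conds) {
      shift_samp <- shift_of[[cond]]
      idx <- s_idx[sub$labels == cond]
      for (i in idx)
        data[i, , ] <- shift_trial(step2$data[i, , , drop = TRUE], shift_samp)
      shifts[idx] <- shift_samp
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, condition = cond, peak_ms = peaks[[cond]],
        target_ms = target, shift_samples = shift_samp)
    }
  }
  out <- replace_data(step2, data)
  attr(out, "applied_shifts") <- shifts
  attr(out, "peak_latencies") <- do.call(rbind, rows)
  out
}

#' Step 4a: synchronize peak latencies between subjects
#'
#' After the between-condition step every subject has one common peak latency;
#' the median of these across subjects becomes the global benchmark and each
#' subject's trials are shifted uniformly onto it.
#'
#' @param step3 an `epoch_set` (both conditions already synchronized within
#'   subject).
#' @param c_window peak search window in ms.
#' @param reference_electrode channel used for synchronization (default 'Pz').
#' @param polarity peak polarity convention.
#' @return an `epoch_set`; attributes `"applied_shifts"`, `"peak_latencies"`
#'   (per-subject peaks/shifts) and `"target_ms"` (the global benchmark).
#' @export
correct_between_subjects <- function(step3, c_window = c(200, 900),
                                     reference_electrode = "Pz",
                                     polarity = "abs") {
  stopifnot(inherits(step3, "epoch_set"))
  subjects <- unique(step3$subjects)
  peaks <- vapply(subjects, function(sid) {
    sub <- subset_trials(step3, which(step3$subjects == sid))
    m <- apply(sub$data, c(2L, 3L), mean)  # condition-common template
    template_peak_latency(m, reference_electrode, window = c_window,
                          polarity = polarity,
                          channel_names = step3$channel_names,
                          times = step3$times)
  }, numeric(1))
  target <- stats::median(peaks)
  data <- step3$data
  shifts <- integer(n_trials(step3))
  for (k in seq_along(subjects)) {
    shift_samp <- ms_to_samples(target - peaks[k], step3$srate)
    idx <- which(step3$subjects == subjects[k])
    if (shift_samp != 0L)
      for (i in idx)
        data[i, , ] <- shift_trial(step3$data[i, , , drop = TRUE], shift_samp)
    shifts[idx] <- shift_samp
  }
  out <- replace_data(step3, data)
  attr(out, "applied_shifts") <- shifts
  attr(out, "peak_latencies") <- data.frame(subject = subjects,
                                            peak_ms = peaks,
                                            target_ms = target,
                                            shift_samples = shifts[match(subjects, step3$subjects)])
  attr(out, "target_ms") <- target
  out
}

#' Step 4b: moment-by-moment global field power normalization
#'
#' Every trial's channel vector is divided, time point by time point, by its
#' own GFP, equating overall activation while preserving the topography (the
#' relations between electrodes). Time points with GFP below `eps` are set to
#' zero.
#'
#' @param epochs an `epoch_set` (average-referenced).
#' @param eps degenerate-GFP guard in microvolts (default 1e-12).
#' @return an `epoch_set` whose per-trial GFP is 1 at every non-degenerate
#'   time point.
#' @export
gfp_normalize <- function(epochs, eps = 1e-12) {
  stopifnot(inherits(epochs, "epoch_set"))
  data <- epochs$data
  for (i in seq_len(n_trials(epochs))) {
    tr <- data[i, , , drop = TRUE]
    g <- gfp(tr)
    scale <- ifelse(g < eps, 0, 1 / pmax(g, eps))
    data[i, , ] <- sweep(tr, 2L, scale, `*`)
  }
  replace_data(epochs, data)
}

#' One stage of the correction pipeline
#' @noRd
correction_result <- function(stage, epochs, applied_shifts,
                              reference_electrode = NA_character_,
                              peak_latencies = NULL,
                              normalization = "none") {
  structure(list(stage = stage, epochs = epochs,
                 applied_shifts = applied_shifts,
                 reference_electrode = reference_electrode,
                 peak_latencies = peak_latencies,
                 normalization = normalization),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> stage %s (%s normalization)\n",
              x$stage, x$normalization))
  cat(sprintf("  shifts: [%d, %d] samples\n",
              min(x$applied_shifts), max(x$applied_shifts)))
  print(x$epochs)
  invisible(x)
}

#' Run the full stepwise latency-correction pipeline
#'
#' Materializes the five datasets the assessment protocol compares:
#' \describe{
#'   \item{Original}{the raw epochs;}
#'   \item{Step1}{C-component single trials after removing the S and R
#'     clusters (residue-iteration decomposition per subject x condition);}
#'   \item{Step2}{within-condition jitter correction (per-trial lag removal);}
#'   \item{Step3}{between-condition peak-latency synchronization at the
#'     reference electrode;}
#'   \item{Step4}{between-subject synchronization plus, optionally,
#'     moment-by-moment GFP normalization.}
#' }
#' All shifting happens on the full decomposition epoch; every stage is then
#' cropped to the analysis window so the zero padding introduced by
#' synchronization stays outside the data handed to classifiers.
#'
#' @param epochs an `epoch_set` with two conditions (and RTs, for the R
#'   stream).
#' @param windows a `ride_windows`.
#' @param reference_electrode synchronization electrode (default 'Pz').
#' @param analysis_window half-open crop window in ms (default [100, 1100)).
#' @param gfp if `TRUE` (default) Step4 includes GFP normalization.
#' @param stages subset of stages to materialize (all five by default; later
#'   stages always compute their prerequisites).
#' @param ... passed to [ride_decompose_all()] (`max_iter`, `tol`,
#'   `estimator`, `max_lag_ms`, `taper`).
#' @return named list of `correction_result`s; attribute `"provenance"` is a
#'   per-trial data.frame of cumulative shifts per stage.
#' @export
run_stepwise_pipeline <- function(epochs, windows = ride_windows(),
                                  reference_electrode = "Pz",
                                  analysis_window = c(100, 1100),
                                  gfp = TRUE,
                                  stages = c("original", "step1", "step2",
                                             "step3", "step4"), ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  stages <- match.arg(stages, several.ok = TRUE)
  crop <- function(x) crop_epochs(x, analysis_window[1L], analysis_window[2L])
  zero <- integer(n_trials(epochs))
  res <- list()
  prov <- data.frame(trial = seq_len(n_trials(epochs)),
                     subject = epochs$subjects, condition = epochs$labels)

  res$original <- correction_result("Original", crop(epochs), zero)
  prov$original <- zero

  need <- function(s) s %in% stages
  if (any(vapply(c("step1", "step2", "step3", "step4"), need, logical(1)))) {
    decomp <- ride_decompose_all(epochs, windows, ...)
    step1 <- extract_c_trials(decomp)
    res$step1 <- correction_result("Step1", crop(step1), zero)
    prov$step1 <- zero
    prov$c_lag <- decomp$c_lags
  }
  if (any(vapply(c("step2", "step3", "step4"), need, logical(1)))) {
    step2 <- correct_within_condition(step1)
    sh2 <- attr(step2, "applied_shifts")
    res$step2 <- correction_result("Step2", crop(step2), sh2)
    prov$step2 <- sh2
  }
  if (any(vapply(c("step3", "step4"), need, logical(1)))) {
    step3 <- correct_between_conditions(step2, c_window = windows$c,
                                        reference_electrode = reference_electrode)
    sh3 <- sh2 + attr(step3, "applied_shifts")
    res$step3 <- correction_result("Step3", crop(step3), sh3,
                                   reference_electrode,
                                   attr(step3, "peak_latencies"))
    prov$step3 <- sh3
  }
  if (need("step4")) {
    step4 <- correct_between_subjects(step3, c_window = windows$c,
                                      reference_electrode = reference_electrode)
    sh4 <- sh3 + attr(step4, "applied_shifts")
    peaks4 <- attr(step4, "peak_latencies")
    ep4 <- crop(step4)
    if (gfp) ep4 <- gfp_normalize(ep4)
    res$step4 <- correction_result("Step4", ep4, sh4, reference_electrode,
                                   peaks4,
                                   normalization = if (gfp) "gfp" else "none")
    prov$step4 <- sh4
  }
  res <- res[intersect(c("original", "step1", "step2", "step3", "step4"),
                       stages)]
  attr(res, "provenance") <- prov
  res
}
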