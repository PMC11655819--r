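#' Decomposition windows for the S, C and R component clusters
#'
#' S and C windows are in ms post-stimulus; the R window is relative to the
#' response (reaction time). Defaults are the settings used for face priming
#' target epochs: S in [0, 300) ms, C in [200, 900) ms, R in [-300, 300) ms
#' around the response.
#'
#' @param s_window,c_window numeric length-2, ms post-stimulus.
#' @param r_window numeric length-2, ms relative to the response.
#' @return an object of class `ride_windows`.
#' @export
ride_windows <- function(s_window = c(0, 300), c_window = c(200, 900),
                         r_window = c(-300, 300)) {
  chk <- function(w, nm) if (length(w) != 2L || w[2L] <= w[1L])
    stop("`", nm, "` must be an increasing length-2 window")
  chk(s_window, "s_window"); chk(c_window, "c_window"); chk(r_window, "r_window")
  structure(list(s = as.numeric(s_window), c = as.numeric(c_window),
                 r = as.numeric(r_window)), class = "ride_windows")
}

# column medians via a single vectorized within-column sort
col_medians <- function(m) {
  n <- nrow(m)
  s <- matrix(m[order(col(m), m)], n)
  if (n %% 2L) s[(n + 1L) %/% 2L, ] else (s[n %/% 2L, ] + s[n %/% 2L + 1L, ]) / 2
}

# leave-one-out column statistics: row i of the result is the column statistic
# computed over all rows except i. Used for self-match-free latency templates.
loo_col_means <- function(m) {
  n <- nrow(m)
  sweep(-m, 2L, colSums(m), `+`) / (n - 1L)
}

loo_col_medians <- function(m) {
  n <- nrow(m); p <- ncol(m)
  o <- order(col(m), m)
  s <- matrix(m[o], n)
  rk <- integer(n * p); rk[o] <- rep(seq_len(n), p)
  rk <- matrix(rk, n)
  if (n %% 2L == 0L) {
    h <- n %/% 2L
    rows <- h + (rk <= h)                 # s-row holding the LOO median
    cols <- rep(seq_len(p), each = n)
    matrix(s[cbind(as.vector(rows), cols)], n)
  } else {
    h <- (n - 1L) %/% 2L
    a <- matrix(s[h, ], n, p, byrow = TRUE)       # rank h
    b <- matrix(s[h + 1L, ], n, p, byrow = TRUE)  # rank h+1 (the median)
    d <- matrix(s[h + 2L, ], n, p, byrow = TRUE)  # rank h+2
    out <- (a + b) / 2
    out[rk <= h] <- ((b + d) / 2)[rk <= h]
    out[rk == h + 1L] <- ((a + d) / 2)[rk == h + 1L]
    out
  }
}

cosine_taper <- function(n, frac = 0.1) {
  w <- rep(1, n)
  k <- floor(frac * n)
  if (k > 0L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(k) / (k + 1)))
    w[seq_len(k)] <- ramp
    w[n + 1L - seq_len(k)] <- ramp
  }
  w
}

#' Estimate a latency-locked spatiotemporal component template
#'
#' Trials are re-aligned by subtracting each trial's latency lag, combined
#' pointwise (median by default; mean optional), windowed, and tapered with a
#' raised-cosine ramp over the first and last 10% of the window so that later
#' template subtractions do not introduce edge artifacts.
#'
#' @param trials trials x channels x samples array (or list of matrices).
#' @param lags integer per-trial lags in samples; a trial with lag L has its
#'   component L samples later than the template position.
#' @param window length-2 ms window within which the template is defined.
#' @param times ms axis of the trials.
#' @param estimator "median" (default) or "mean".
#' @param taper fraction of the window tapered at each edge (default 0.1).
#' @return an `erp_template`, zero outside `window`.
#' @export
estimate_template <- function(trials, lags, window, times,
                              estimator = c("median", "mean"), taper = 0.1) {
  estimator <- match.arg(estimator)
  if (is.list(trials))
    trials <- aperm(simplify2array(trials), c(3L, 1L, 2L))
  stopifnot(length(dim(trials)) == 3L, dim(trials)[1L] == length(lags))
  if (dim(trials)[1L] < 2L) stop("need at least 2 trials for a template")
  idx <- which(times >= window[1L] & times < window[2L])
  if (length(idx) == 0L) stop("template window outside the time grid")
  n <- dim(trials)[1L]
  flat <- aligned_window_rows(trials, lags, idx)  # n x (channels*|idx|)
  avg <- matrix(if (estimator == "median") col_medians(flat)
                else colMeans(flat),
                dim(trials)[2L], length(idx))
  values <- matrix(0, dim(trials)[2L], dim(trials)[3L])
  w <- cosine_taper(length(idx), taper)
  values[, idx] <- sweep(avg, 2L, w, `*`)
  erp_template(values, times, window)
}

# rows of latency-aligned trials restricted to the window columns: row i is
# trial i's channels x |idx| segment taken at idx + lag_i, zero where the
# displaced index leaves the grid (identical to shift-then-window).
aligned_window_rows <- function(trials, lags, idx) {
  n <- dim(trials)[1L]; nch <- dim(trials)[2L]; nts <- dim(trials)[3L]
  flat <- matrix(0, n, nch * length(idx))
  for (i in seq_len(n)) {
    src <- idx + as.integer(lags[i])
    ok <- src >= 1L & src <= nts
    seg <- matrix(0, nch, length(idx))
    seg[, ok] <- trials[i, , src[ok], drop = TRUE]
    flat[i, ] <- seg
  }
  flat
}

#' Estimate a trial's C latency by time-lagged template matching
#'
#' The matching score at lag L is the sum over channels of the inner products
#' between the mean-centered template (inside its window) and the mean-centered
#' trial segment displaced by L samples; the returned lag maximizes this
#' cross-correlation score. A positive lag means the trial's pattern occurs
#' later than the template's. Exact score ties are broken toward the smallest
#' absolute lag, then the earlier lag.
#'
#' @param trial channels x samples matrix on the template grid.
#' @param template an `erp_template` with nonzero content in its window.
#' @param max_lag maximum |lag| in samples to scan (clipped so the displaced
#'   window stays on the grid).
#' @return integer lag in samples; attribute `"score"` holds the winning score.
#' @export
estimate_c_latency <- function(trial, template, max_lag) {
  stopifnot(is.matrix(trial), inherits(template, "erp_template"))
  idx <- template_window_idx(template)
  tw <- template$values[, idx, drop = FALSE]
  if (max(abs(tw)) == 0) stop("template is all zero inside its window")
  tw <- tw - rowMeans(tw)
  n <- ncol(trial)
  lo <- max(-max_lag, 1L - min(idx))
  hi <- min(max_lag, n - max(idx))
  if (lo > hi) stop("no admissible lag: window too close to the epoch edge")
  scan_lags(trial, tw, idx, lo, hi)
}

# exhaustive lag scan of the matching score; tw must be row mean-centered.
# The template rows being mean-centered, centering each lag-shifted trial
# segment contributes exactly zero to the inner product and is skipped. The
# score at every lag is assembled from one cross-product matrix: with
# M[t, s] = sum_ch tw[ch, t] * Xext[ch, s], score(L) is the sum of the
# corresponding diagonal band of M.
scan_lags <- function(trial, tw, idx, lo, hi) {
  lags <- lo:hi
  W <- length(idx)
  ext <- (idx[1L] + lo):(idx[W] + hi)
  M <- crossprod(tw, trial[, ext, drop = FALSE])   # W x |ext|
  tt <- seq_len(W)
  scores <- vapply(seq_along(lags), function(j)
    sum(M[cbind(tt, tt + (j - 1L))]), numeric(1))
  if (all(!is.finite(scores))) stop("all matching scores are non-finite")
  best <- which(scores == max(scores, na.rm = TRUE))
  if (length(best) > 1L)
    best <- best[order(abs(lags[best]), lags[best])][1L]
  out <- as.integer(lags[best])
  attr(out, "score") <- scores[best]
  out
}

place_template <- function(template, lag) shift_trial(template$values, lag)

# re-estimate every trial's C lag against a leave-one-out template: the trial
# being matched is excluded from its own template so its noise cannot create a
# self-match score spike at the current lag (which would lock the iteration
# onto noise at low SNR).
update_c_lags <- function(residC, c_lags, idx, max_lag, estimator, taper) {
  nt <- dim(residC)[1L]; nch <- dim(residC)[2L]; nts <- dim(residC)[3L]
  flat <- aligned_window_rows(residC, c_lags, idx)
  loo <- if (estimator == "median") loo_col_medians(flat) else loo_col_means(flat)
  w <- cosine_taper(length(idx), taper)
  lo <- max(-max_lag, 1L - min(idx))
  hi <- min(max_lag, nts - max(idx))
  if (lo > hi) stop("no admissible lag: C window too close to the epoch edge")
  new_lags <- c_lags
  for (i in seq_len(nt)) {
    tw <- sweep(matrix(loo[i, ], nch, length(idx)), 2L, w, `*`)
    if (max(abs(tw)) == 0) next
    tw <- tw - rowMeans(tw)
    new_lags[i] <- scan_lags(residC[i, , , drop = TRUE], tw, idx, lo, hi)
  }
  as.integer(new_lags)
}

#' Residue-iteration decomposition of one subject x condition cell
#'
#' Iteratively separates single trials into a stimulus-locked cluster S, a
#' latency-variable central cluster C and a response-locked cluster R. Each
#' pass (i) re-estimates, for every component in turn, its latency-locked
#' template from the residuals left after subtracting the other two components
#' placed at their current latencies (S: stimulus onset, lag 0; R: the trial's
#' reaction time; C: the current latency lags), and (ii) re-estimates the
#' per-trial C lags by time-lagged template matching on the C residuals.
#' Iteration stops when every template's relative Frobenius change falls below
#' `tol`, or after `max_iter` passes (then `converged = FALSE` with a warning).
#'
#' When RTs are absent the R stream is skipped and a two-component (S + C)
#' decomposition is returned.
#'
#' @param epochs an `epoch_set`, conventionally one subject x condition cell
#'   (the decomposition is estimated per cell; see [ride_decompose_all()]).
#' @param windows a `ride_windows`.
#' @param max_iter maximum iterations (default 30; the alternating
#'   template subtraction trades content between overlapping windows and
#'   needs a few tens of passes to settle).
#' @param tol relative Frobenius template-change threshold (default 1e-3).
#' @param estimator template estimator, "median" (default) or "mean".
#' @param max_lag_ms half-width of the C lag search range (default 200 ms),
#'   clipped so the displaced C window stays inside the epoch.
#' @param taper template edge taper fraction (default 0.1).
#' @return an object of class `ride_decomposition`: per-trial component
#'   estimates `s_trials`/`c_trials`/`r_trials` (trials x channels x samples,
#'   each zero outside its displaced window), `residual`, templates
#'   `s_template`/`c_template`/`r_template`, integer `c_lags`, the per-trial
#'   response lags `r_lags`, `iterations_run`, `converged`, and
#'   `residual_norms` (mean per-trial reconstruction residual by iteration).
#' @export
ride_decompose <- function(epochs, windows = ride_windows(), max_iter = 30,
                           tol = 1e-3, estimator = c("median", "mean"),
                           max_lag_ms = 200, taper = 0.1) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(windows, "ride_windows"))
  estimator <- match.arg(estimator)
  times <- epochs$times
  srate <- epochs$srate
  nt <- n_trials(epochs)
  nts <- n_samples(epochs)
  if (nt < 2L) stop("decomposition needs at least 2 trials")
  data <- epochs$data

  have_r <- !is.null(epochs$rts) && !any(is.na(epochs$rts))
  if (!is.null(epochs$rts) && any(is.na(epochs$rts)) && !all(is.na(epochs$rts)))
    stop("mixed missing/present RTs in one decomposition cell")
  if (!have_r) {
    if (!is.null(epochs$rts)) warning("RTs missing: skipping the R stream")
  }
  # R stream: template on the stimulus grid at the median RT; per-trial lag =
  # each trial's RT offset from that anchor, so placement is response-locked.
  r_lags <- rep(0L, nt)
  r_window_abs <- NULL
  if (have_r) {
    rt_ref <- stats::median(epochs$rts)
    r_lags <- ms_to_samples(epochs$rts, srate) - ms_to_samples(rt_ref, srate)
    r_window_abs <- windows$r + rt_ref
    r_window_abs[1L] <- max(r_window_abs[1L], times[1L])
    r_window_abs[2L] <- min(r_window_abs[2L], times[length(times)] + 1000 / srate)
  }
  comp_names <- c("S", "C", if (have_r) "R")
  win_ms <- list(S = windows$s, C = windows$c, R = r_window_abs)
  lag_of <- function(comp) switch(comp, S = rep(0L, nt), C = c_lags, R = r_lags)

  c_idx <- which(times >= windows$c[1L] & times < windows$c[2L])
  if (length(c_idx) == 0L) stop("C window outside the epoch")
  max_lag <- ms_to_samples(max_lag_ms, srate)

  c_lags <- rep(0L, nt)
  nch <- n_channels(epochs)
  data_flat <- matrix(data, nrow = nt)       # nt x (channels*samples)
  # one row per trial of the component template placed at that trial's lag;
  # built once per unique lag and broadcast by row indexing
  placed_rows <- function(template, lags) {
    ul <- sort(unique(lags))
    pm <- matrix(0, length(ul), nch * nts)
    for (j in seq_along(ul))
      pm[j, ] <- as.numeric(place_template(template, ul[j]))
    pm[match(lags, ul), , drop = FALSE]
  }
  resid_for <- function(comp) {
    resid <- data_flat
    for (o in setdiff(comp_names, comp))
      resid <- resid - placed_rows(templates[[o]], lag_of(o))
    resid
  }
  templates <- list()
  # sequential-residual initialization: each template is estimated after
  # subtracting the components already initialized, so the C template does not
  # start out owning the stimulus-locked content of its window overlap
  for (comp in comp_names) {
    resid <- data_flat
    for (o in names(templates))
      resid <- resid - placed_rows(templates[[o]], lag_of(o))
    templates[[comp]] <- estimate_template(array(resid, dim = dim(data)),
                                           lag_of(comp), win_ms[[comp]],
                                           times, estimator, taper)
  }
  residual_norms <- numeric(0)
  converged <- FALSE
  iter <- 0L
  lag_stable <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    old <- templates
    lags_before <- c_lags
    for (comp in comp_names) {
      resid <- resid_for(comp)
      templates[[comp]] <- estimate_template(
        array(resid, dim = dim(data)), lag_of(comp), win_ms[[comp]],
        times, estimator, taper)
      if (comp == "C")
        c_lags <- update_c_lags(array(resid, dim = dim(data)), c_lags, c_idx,
                                max_lag, estimator, taper)
    }
    # mean reconstruction defect of the template model
    rec <- matrix(0, nt, nch * nts)
    for (comp in comp_names)
      rec <- rec + placed_rows(templates[[comp]], lag_of(comp))
    residual_norms <- c(residual_norms,
                        mean(sqrt(rowSums((data_flat - rec)^2))))
    rel_change <- vapply(comp_names, function(comp) {
      denom <- sqrt(sum(old[[comp]]$values^2))
      if (denom == 0) return(0)
      sqrt(sum((templates[[comp]]$values - old[[comp]]$values)^2)) / denom
    }, numeric(1))
    if (all(rel_change < tol)) { converged <- TRUE; break }
    # secondary stop: once the integer lags have been stable for three
    # consecutive passes, further passes only polish the templates
    lag_stable <- if (identical(c_lags, lags_before)) lag_stable + 1L else 0L
    if (lag_stable >= 3L && all(rel_change < 100 * tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("decomposition did not converge in ", max_iter, " iterations")

  # per-trial component estimates. The windowed arrays restrict each trial's
  # residual (after subtracting the other two templates) to the component's
  # displaced window; the C stream additionally keeps the full-epoch residual
  # (`c_full`), because hard window edges would travel with the
  # condition-specific synchronization shifts later in the pipeline and hand
  # classifiers a spurious support cue.
  win_idx <- lapply(win_ms[comp_names], function(w)
    which(times >= w[1L] & times < w[2L]))
  comp_trials <- list()
  c_full <- NULL
  for (comp in comp_names) {
    resid <- resid_for(comp)
    if (comp == "C") c_full <- array(resid, dim = dim(data))
    lc <- lag_of(comp)
    keep <- matrix(0, nt, nch * nts)
    for (i in seq_len(nt)) {
      sel <- win_idx[[comp]] + lc[i]
      sel_ok <- sel[sel >= 1L & sel <= nts]
      cols <- rep((sel_ok - 1L) * nch, each = nch) + seq_len(nch)
      keep[i, cols] <- resid[i, cols]
    }
    comp_trials[[comp]] <- array(keep, dim = dim(data))
  }
  residual <- data
  for (comp in comp_names) residual <- residual - comp_trials[[comp]]

  structure(list(
    s_trials = comp_trials$S, c_trials = comp_trials$C,
    r_trials = comp_trials$R, c_full = c_full, residual = residual,
    s_template = templates$S, c_template = templates$C,
    r_template = templates$R,
    c_lags = as.integer(c_lags), r_lags = as.integer(r_lags),
    have_r = have_r, iterations_run = iter, converged = converged,
    residual_norms = residual_norms, times = times, srate = srate,
    channel_names = epochs$channel_names, labels = epochs$labels,
    subjects = epochs$subjects, rts = epochs$rts),
    class = "ride_decomposition")
}

#' @export
print.ride_decomposition <- function(x, ...) {
  cat(sprintf("<ride_decomposition> %d trials, %s components, %d iteration(s), %s\n",
              dim(x$c_trials)[1L],
              if (x$have_r) "S+C+R" else "S+C",
              x$iterations_run,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  c_lags: [%d, %d] samples (SD %.1f)\n",
              min(x$c_lags), max(x$c_lags), stats::sd(x$c_lags)))
  invisible(x)
}

#' Run the decomposition for every subject x condition cell
#'
#' Templates and latencies are estimated per cell (the template is unique to
#' each subject and condition); results are recombined in the original trial
#' order.
#'
#' @inheritParams ride_decompose
#' @param epochs an `epoch_set` with any number of subjects/conditions.
#' @return an object of class `ride_set`: `cells` (named list of
#'   `ride_decomposition`s), `cell_of` / `index_of` bookkeeping, `c_lags` in
#'   original trial order, and the input metadata.
#' @export
ride_decompose_all <- function(epochs, windows = ride_windows(), ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  cell <- paste(epochs$subjects, epochs$labels, sep = "|")
  cells <- list()
  c_lags <- integer(n_trials(epochs))
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    dec <- ride_decompose(subset_trials(epochs, idx), windows, ...)
    dec$orig_index <- idx
    cells[[cl]] <- dec
    c_lags[idx] <- dec$c_lags
  }
  structure(list(cells = cells, cell_of = cell, c_lags = c_lags,
                 times = epochs$times, srate = epochs$srate,
                 channel_names = epochs$channel_names,
                 labels = epochs$labels, subjects = epochs$subjects,
                 rts = epochs$rts),
            class = "ride_set")
}

#' Extract the C-component single trials
#'
#' Returns the per-trial C-component estimates — each trial minus the placed
#' S and R templates — at their original (uncorrected) latencies as a new
#' `epoch_set`, with all trial metadata carried over: the dataset on which the
#' latency-correction steps operate after the stimulus- and response-locked
#' clusters have been removed. The full-epoch residual is kept (no hard
#' windowing) so that later synchronization shifts cannot imprint
#' condition-specific support edges on the data. The per-trial C latency lags
#' are attached as attribute `"c_lags"`.
#'
#' @param decomp a `ride_decomposition` or `ride_set`.
#' @return an `epoch_set` of C-component trials.
#' @export
extract_c_trials <- function(decomp) {
  if (inherits(decomp, "ride_decomposition")) {
    out <- epoch_set(decomp$c_full, srate = decomp$srate,
                     times = decomp$times, channel_names = decomp$channel_names,
                     labels = decomp$labels, subjects = decomp$subjects,
                     rts = decomp$rts, check_reference = FALSE)
    attr(out, "c_lags") <- decomp$c_lags
    return(out)
  }
  stopifnot(inherits(decomp, "ride_set"))
  nt <- length(decomp$cell_of)
  data <- NULL
  for (cl in names(decomp$cells)) {
    dec <- decomp$cells[[cl]]
    if (is.null(data))
      data <- array(0, dim = c(nt, dim(dec$c_full)[2L], dim(dec$c_full)[3L]))
    data[dec$orig_index, , ] <- dec$c_full
  }
  out <- epoch_set(data, srate = decomp$srate, times = decomp$times,
                   channel_names = decomp$channel_names,
                   labels = decomp$labels, subjects = decomp$subjects,
                   rts = decomp$rts, check_reference = FALSE)
  attr(out, "c_lags") <- decomp$c_lags
  out
}
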