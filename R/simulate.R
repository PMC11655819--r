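#' A 41-channel montage with a midline parietal reference electrode
#'
#' Channel labels used by the simulator defaults; includes 'Pz', the
#' synchronization reference electrode for the between-condition and
#' between-subject correction steps.
#'
#' @return character vector of 41 labels.
#' @export
montage_41 <- function() {
  c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2",
    "TP9", "TP10", "FT9", "FT10", "AFz", "FCz")
}

#' Smooth zero-mean topography peaking at a named channel
#'
#' A Gaussian profile over channel index distance, mean-centered across
#' channels (average-reference consistent) and rescaled to peak value 1 at the
#' center channel. Channel-index distance is a crude stand-in for scalp
#' distance but yields smooth, sign-mixed maps of the kind average-referenced
#' scalp data show.
#'
#' @param channel_names montage labels.
#' @param center channel at which the map peaks.
#' @param spread Gaussian width in channel-index units.
#' @return numeric weight vector summing to ~0 with max 1 at `center`.
#' @export
topography_at <- function(channel_names, center, spread = 6) {
  i0 <- match(center, channel_names)
  if (is.na(i0)) stop("channel '", center, "' not in montage")
  w <- exp(-((seq_along(channel_names) - i0)^2) / (2 * spread^2))
  w <- w - mean(w)
  w / w[i0]
}

#' Specification of one simulated ERP component
#'
#' Components come in three kinds mirroring the decomposition model:
#' stimulus-locked (`"S"`, fixed latency), central latency-variable (`"C"`,
#' condition-dependent mean latency plus within-condition Gaussian jitter and
#' a between-subject offset), and response-locked (`"R"`, centered on each
#' trial's reaction time).
#'
#' @param kind one of "S", "C", "R".
#' @param shape waveform family: "gaussian" (width = Gaussian SD in ms) or
#'   "halfcosine" (width = half-period in ms).
#' @param width_ms morphology width, > 0; scalar or one value per condition
#'   (a broader unprimed morphology is part of the default study conditions).
#' @param amplitude signed peak amplitude in microvolts; scalar or one value
#'   per condition (recycled in condition order).
#' @param topography per-channel weight vector, ~zero-mean across channels,
#'   or a channels x conditions matrix of such vectors;
#'   `NULL` selects a default map (S: occipital, C: parietal 'Pz', R: central)
#'   with per-condition `topo_spread`.
#' @param topo_spread Gaussian spread of the default topography in
#'   channel-index units; scalar or per condition.
#' @param latency_ms for S a fixed latency; for C the per-condition mean
#'   latency (scalar or one per condition); ignored for R.
#' @param jitter_sd_ms within-condition latency jitter SD (C only); scalar or
#'   per condition; must be >= 0.
#' @param subject_sd_ms SD of the per-subject latency offset (C only).
#' @param amplitude_sd trial-level additive amplitude SD in microvolts.
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(kind, shape = c("gaussian", "halfcosine"),
                           width_ms, amplitude, topography = NULL,
                           latency_ms = NULL, jitter_sd_ms = 0,
                           subject_sd_ms = 0, amplitude_sd = 0,
                           topo_spread = 6) {
  kind <- match.arg(kind, c("S", "C", "R"))
  shape <- match.arg(shape)
  stopifnot(all(width_ms > 0), all(jitter_sd_ms >= 0), subject_sd_ms >= 0,
            amplitude_sd >= 0, all(topo_spread > 0))
  if (kind != "R" && is.null(latency_ms))
    stop("latency_ms required for ", kind, " components")
  if (!is.null(topography)) {
    tm <- if (is.matrix(topography)) topography else cbind(topography)
    for (j in seq_len(ncol(tm)))
      if (abs(sum(tm[, j])) > 1e-6 * max(abs(tm[, j]), 1e-12))
        stop("topography must be ~zero-mean across channels")
  }
  structure(list(kind = kind, shape = shape, width_ms = width_ms,
                 amplitude = amplitude, topography = topography,
                 latency_ms = latency_ms, jitter_sd_ms = jitter_sd_ms,
                 subject_sd_ms = subject_sd_ms, amplitude_sd = amplitude_sd,
                 topo_spread = topo_spread),
            class = "component_spec")
}

#' Evaluate a component waveform on a time grid
#'
#' The morphology is centered at `latency_ms` and multiplied outer-product
#' style by the topography, giving a channels x samples array.
#'
#' @param spec a `component_spec`.
#' @param latency_ms center latency in ms; must lie inside the grid span.
#' @param times ms axis.
#' @param amplitude peak amplitude (overrides the spec's; required because
#'   per-condition and per-trial amplitudes are resolved by the caller).
#' @param channel_names montage, used to resolve a default topography.
#' @param condition_index which condition's width/topography/spread to use
#'   when the spec carries per-condition values.
#' @return channels x samples matrix.
#' @export
component_waveform <- function(spec, latency_ms, times,
                               amplitude = spec$amplitude[1L],
                               channel_names = montage_41(),
                               condition_index = 1L) {
  if (latency_ms < times[1L] || latency_ms > times[length(times)])
    stop("latency ", latency_ms, " ms outside epoch span [",
         times[1L], ", ", times[length(times)], "] ms")
  topo <- spec$topography
  if (is.null(topo)) {
    topo <- default_topography(spec$kind, channel_names,
                               cond_param(spec$topo_spread, condition_index))
  } else if (is.matrix(topo)) topo <- topo[, condition_index]
  width <- cond_param(spec$width_ms, condition_index)
  m <- switch(spec$shape,
    gaussian = exp(-((times - latency_ms)^2) / (2 * width^2)),
    halfcosine = {
      u <- (times - latency_ms) / width
      ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
    })
  amplitude * outer(topo, m)
}

default_topography <- function(kind, channel_names, spread = 6) {
  center <- switch(kind, S = "Oz", C = "Pz", R = "Cz")
  if (!center %in% channel_names) center <- channel_names[1L]
  topography_at(channel_names, center, spread)
}

#' Default component set emulating a face repetition-priming target epoch
#'
#' Three components: an occipital stimulus-locked S at 150 ms carrying a
#' small repetition effect; a parietal
#' latency-variable C whose mean latency is earlier for the primed than the
#' unprimed condition (360 vs 440 ms) with 50 ms within-condition jitter and a
#' 30 ms between-subject offset, and a slightly larger unprimed amplitude; a
#' central response-locked R. These defaults produce, at once, within-condition
#' jitter, a between-condition latency shift, a genuine amplitude effect and
#' RT-locked motor activity — the four variability sources the correction
#' pipeline addresses.
#'
#' @param c_latency_ms per-condition C mean latency (default c(360, 440)).
#' @param c_jitter_sd_ms within-condition C jitter SD (default 50).
#' @param c_amplitude per-condition C amplitude (default c(5, 5.5)
#'   microvolts, a genuine but modest activation effect).
#' @param c_width_ms per-condition C width (default c(90, 95) ms: the
#'   unprimed response is broader as well as later).
#' @param c_topo_spread per-condition spread of the C topography (default
#'   c(6, 6.5): the two conditions differ slightly in scalp distribution, so
#'   information survives amplitude normalization).
#' @param s_amplitude per-condition S amplitude (default c(4, 4.5)
#'   microvolts; early stimulus-locked repetition effects such as the N250r
#'   live in the S cluster, so removing S should cost the classifier some
#'   information).
#' @param subject_sd_ms between-subject C latency offset SD (default 30).
#' @return list of three `component_spec`s named S, C, R.
#' @export
default_components <- function(c_latency_ms = c(360, 440),
                               c_jitter_sd_ms = 50,
                               c_amplitude = c(5, 5.5),
                               c_width_ms = c(90, 95),
                               c_topo_spread = c(6, 6.5),
                               s_amplitude = c(4, 4.5),
                               subject_sd_ms = 30) {
  list(
    S = component_spec("S", width_ms = 40, amplitude = s_amplitude,
                       latency_ms = 150),
    C = component_spec("C", width_ms = c_width_ms, amplitude = c_amplitude,
                       latency_ms = c_latency_ms,
                       jitter_sd_ms = c_jitter_sd_ms,
                       subject_sd_ms = subject_sd_ms,
                       topo_spread = c_topo_spread),
    R = component_spec("R", width_ms = 60, amplitude = 3))
}

#' Simulation configuration
#'
#' Geometry mirrors the target-epoch design the package was written around:
#' two conditions of 72 trials per subject, 41 average-referenced channels at
#' 250 Hz, epochs spanning -100 to 1500 ms around target onset. Reaction time
#' is generated as C latency plus a log-normal motor delay, so the R component
#' is response-locked and RT co-varies with the C latency (priming shortens
#' both).
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition trials per subject x condition cell.
#' @param channel_names montage labels.
#' @param srate sampling rate, Hz.
#' @param tmin,tmax epoch span in ms (samples cover `[tmin, tmax)`).
#' @param conditions two condition labels; component per-condition parameters
#'   follow this order.
#' @param components list of `component_spec`s.
#' @param motor_delay_ms median motor delay added to C latency to form RT.
#' @param motor_sigma log-normal sigma of the motor delay (0 = deterministic).
#' @param noise_sd additive noise SD in microvolts (0 = noise free).
#' @param noise_model "correlated" (random smooth spatial mixing, realistic
#'   GFP) or "white".
#' @param noise_ar temporal AR(1) coefficient of the noise (0 = white in time).
#' @param seed integer; fully determines the simulated dataset.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20, trials_per_condition = 72,
                       channel_names = montage_41(), srate = 250,
                       tmin = -100, tmax = 1500,
                       conditions = c("primed", "unprimed"),
                       components = default_components(),
                       motor_delay_ms = 250, motor_sigma = 0.15,
                       noise_sd = 3, noise_model = c("correlated", "white"),
                       noise_ar = 0.3, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_subjects >= 1, trials_per_condition >= 1,
            length(conditions) == 2L, tmax > tmin, noise_sd >= 0,
            noise_ar >= 0, noise_ar < 1)
  structure(list(n_subjects = n_subjects,
                 trials_per_condition = trials_per_condition,
                 channel_names = channel_names, srate = srate,
                 tmin = tmin, tmax = tmax, conditions = conditions,
                 components = components, motor_delay_ms = motor_delay_ms,
                 motor_sigma = motor_sigma, noise_sd = noise_sd,
                 noise_model = noise_model, noise_ar = noise_ar,
                 seed = as.integer(seed)),
            class = "sim_config")
}

cond_param <- function(value, cond_index) {
  if (length(value) == 1L) value else value[cond_index]
}

#' Generate an epoch_set with known ground truth
#'
#' Every trial is the sum of the configured components plus noise; the true
#' per-trial C latency, amplitudes and RT are returned alongside, enabling
#' parameter-recovery tests of the decomposition and correction stages. The
#' output is a deterministic function of the config (one global seed, one
#' sub-stream per subject, so subject subsets reproduce).
#'
#' @param config a `sim_config`.
#' @return list with `epochs` (an `epoch_set`), `truth` (a data.frame with one
#'   row per trial: subject, condition, rt_ms, c_latency_ms and per-component
#'   amplitudes) and `config`.
#' @export
simulate_epochs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  step <- 1000 / config$srate
  times <- seq(config$tmin, config$tmax - step / 2, by = step)
  nch <- length(config$channel_names)
  nt_cell <- config$trials_per_condition
  n_total <- config$n_subjects * 2L * nt_cell
  set.seed(config$seed)
  mixing <- NULL
  if (config$noise_model == "correlated") {
    # random smooth spatial mixing: nearby-index channels share noise
    base <- matrix(stats::rnorm(nch * nch), nch, nch)
    kern <- outer(seq_len(nch), seq_len(nch),
                  function(i, j) exp(-((i - j)^2) / (2 * 4^2)))
    mixing <- kern %*% base
    mixing <- mixing / sqrt(rowSums(mixing^2))  # unit marginal SD
  }
  subject_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)

  data <- array(0, dim = c(n_total, nch, length(times)))
  labels <- character(n_total)
  subjects <- character(n_total)
  rts <- numeric(n_total)
  truth_rows <- vector("list", config$n_subjects)
  specs <- config$components
  row <- 0L
  for (s in seq_len(config$n_subjects)) {
    set.seed(subject_seeds[s])
    sid <- sprintf("s%02d", s)
    subj_offsets <- vapply(specs, function(sp) {
      if (sp$kind == "C" && sp$subject_sd_ms > 0)
        stats::rnorm(1, 0, sp$subject_sd_ms) else 0
    }, numeric(1))
    cell <- list()
    for (ci in 1:2) {
      cond <- config$conditions[ci]
      for (tr in seq_len(nt_cell)) {
        row <- row + 1L
        trial <- matrix(0, nch, length(times))
        c_lat <- NA_real_
        rt <- NA_real_
        amps <- numeric(length(specs))
        # C latency and RT first (R is locked to RT)
        for (k in seq_along(specs)) {
          if (specs[[k]]$kind == "C") {
            mu <- cond_param(specs[[k]]$latency_ms, ci) + subj_offsets[k]
            for (try in 1:100) {
              c_lat <- mu + stats::rnorm(1, 0, cond_param(specs[[k]]$jitter_sd_ms, ci))
              delay <- config$motor_delay_ms *
                exp(stats::rnorm(1, 0, config$motor_sigma))
              rt <- c_lat + delay
              if (c_lat > times[1L] && c_lat < times[length(times)] &&
                  rt < times[length(times)]) break
              if (try == 100) stop("could not draw a C latency/RT inside the epoch")
            }
          }
        }
        for (k in seq_along(specs)) {
          sp <- specs[[k]]
          amp <- cond_param(sp$amplitude, ci)
          if (sp$amplitude_sd > 0) amp <- amp + stats::rnorm(1, 0, sp$amplitude_sd)
          amps[k] <- amp
          lat <- switch(sp$kind,
                        S = cond_param(sp$latency_ms, ci),
                        C = c_lat,
                        R = rt)
          if (is.na(lat)) next  # R without any C/RT stream
          trial <- trial + component_waveform(sp, lat, times, amplitude = amp,
                                              channel_names = config$channel_names,
                                              condition_index = ci)
        }
        if (config$noise_sd > 0) {
          e <- matrix(stats::rnorm(nch * length(times)), nch, length(times))
          if (config$noise_ar > 0) {
            e <- t(apply(e, 1L, function(x)
              as.numeric(stats::filter(x, config$noise_ar, method = "recursive"))))
            e <- e * sqrt(1 - config$noise_ar^2)  # restore unit variance
          }
          if (!is.null(mixing)) e <- mixing %*% e
          e <- config$noise_sd * e
          e <- sweep(e, 2L, colMeans(e))  # keep the average reference
          trial <- trial + e
        }
        data[row, , ] <- trial
        labels[row] <- cond
        subjects[row] <- sid
        rts[row] <- rt
        cell[[length(cell) + 1L]] <- data.frame(
          subject = sid, condition = cond, rt_ms = rt, c_latency_ms = c_lat,
          t(stats::setNames(amps, paste0("amp_", names(specs)))))
      }
    }
    truth_rows[[s]] <- do.call(rbind, cell)
  }
  truth <- do.call(rbind, truth_rows)
  truth$trial <- seq_len(nrow(truth))
  rownames(truth) <- NULL
  if (all(is.na(rts))) rts <- NULL
  epochs <- epoch_set(data, srate = config$srate, times = times,
                      channel_names = config$channel_names,
                      labels = labels, subjects = subjects, rts = rts,
                      check_reference = FALSE)
  list(epochs = epochs, truth = truth, config = config)
}
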