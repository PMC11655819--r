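# Small synthetic geometries shared across tests. Everything is generated in
# code; sizes are kept small so the default run stays fast.

# a 16-electrode subset of the default montage that keeps the component
# centers (Oz, Pz, Cz) and the synchronization reference
tiny_montage <- function() {
  c("F3", "Fz", "F4", "FC1", "FC2", "C3", "Cz", "C4",
    "CP1", "CP2", "P3", "Pz", "P4", "O1", "Oz", "O2")
}

tiny_sim <- function(n_subjects = 1, trials = 20, noise_sd = 0, seed = 1,
                     components = default_components(), jitter = NULL,
                     shift = NULL, amp = NULL, s_amp = NULL,
                     motor_sigma = 0.3, ...) {
  if (!is.null(jitter)) components$C$jitter_sd_ms <- jitter
  if (!is.null(shift)) components$C$latency_ms <- shift
  if (!is.null(amp)) components$C$amplitude <- amp
  if (!is.null(s_amp)) components$S$amplitude <- s_amp
  sim_config(n_subjects = n_subjects, trials_per_condition = trials,
             channel_names = tiny_montage(), noise_sd = noise_sd,
             components = components, motor_sigma = motor_sigma,
             seed = seed, ...)
}

quiet_decompose <- function(epochs, ...) {
  suppressWarnings(ride_decompose_all(epochs, ...))
}

quiet_pipeline <- function(epochs, ...) {
  suppressWarnings(run_stepwise_pipeline(epochs, ...))
}

# a quick epoch_set from a plain array
toy_epochs <- function(data, srate = 250, tmin = 0, labels = NULL, ...) {
  n <- dim(data)[1L]
  if (is.null(labels)) labels <- rep(c("a", "b"), length.out = n)
  epoch_set(data, srate = srate, tmin = tmin, labels = labels,
            check_reference = FALSE, ...)
}

# separable two-class data: condition flips the sign of a fixed pattern
separable_epochs <- function(n = 60, nch = 8, nts = 50, snr = 3, seed = 1) {
  with_seed_local(seed, {
    pat <- outer(stats::rnorm(nch), stats::dnorm(seq(-3, 3, length.out = nts)))
    pat <- pat / max(abs(pat))
    X <- array(stats::rnorm(n * nch * nts, sd = 1 / snr), dim = c(n, nch, nts))
    y <- rep(c("a", "b"), length.out = n)
    for (i in seq_len(n))
      X[i, , ] <- X[i, , ] + ifelse(y[i] == "b", 1, -1) * pat
    toy_epochs(X, labels = y)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
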