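test_that("estimate_template aligns, windows and tapers", {
  times <- seq(0, 396, by = 4)
  tr <- matrix(rnorm(4 * 100), 4, 100)
  trials <- array(0, c(3, 4, 100))
  for (i in 1:3) trials[i, , ] <- tr
  tpl <- estimate_template(trials, c(0, 0, 0), c(100, 300), times)
  idx <- which(times >= 100 & times < 300)
  # zeros outside the window; taper-weighted trial inside
  expect_true(all(tpl$values[, -idx] == 0))
  w <- latstep:::cosine_taper(length(idx), 0.1)
  expect_equal(tpl$values[, idx], sweep(tr[, idx], 2, w, `*`))
})

test_that("supplying the true lags undoes the shifts before averaging", {
  times <- seq(0, 396, by = 4)
  spec <- component_spec("C", width_ms = 40, amplitude = 1, latency_ms = 200,
                         topography = c(1, -0.4, -0.6))
  base <- component_waveform(spec, 200, times, channel_names = c("a", "b", "c"))
  lags <- c(-5L, 0L, 3L, 8L)
  trials <- array(0, c(4, 3, 100))
  for (i in 1:4) trials[i, , ] <- shift_trial(base, lags[i])
  tpl <- estimate_template(trials, lags, c(100, 300), times)
  expect_equal(times[which.max(abs(tpl$values[1, ]))], 200)
})

test_that("the mean-estimator template equals a naive aligned-average loop", {
  set.seed(11)
  times <- seq(0, 196, by = 4)
  trials <- array(rnorm(6 * 3 * 50), c(6, 3, 50))
  lags <- sample(-4:4, 6, replace = TRUE)
  tpl <- estimate_template(trials, lags, c(40, 160), times,
                           estimator = "mean", taper = 0)
  idx <- which(times >= 40 & times < 160)
  oracle <- matrix(0, 3, length(idx))
  for (i in 1:6)
    oracle <- oracle + shift_trial(trials[i, , ], -lags[i])[, idx] / 6
  expect_equal(tpl$values[, idx], oracle)
})

test_that("estimate_c_latency recovers known shifts and matches an exhaustive oracle", {
  set.seed(12)
  times <- seq(-100, 1496, by = 4)
  vals <- matrix(0, 5, length(times))
  win <- times >= 200 & times < 900
  vals[, win] <- matrix(rnorm(5 * sum(win)), 5)
  tpl <- erp_template(vals, times, c(200, 900))
  expect_equal(as.integer(estimate_c_latency(vals, tpl, 50)), 0L)
  shifted <- shift_trial(vals, 5)
  expect_equal(as.integer(estimate_c_latency(shifted, tpl, 50)), 5L)

  # independent exhaustive scan with the literal score definition
  oracle_lag <- function(trial, tpl, max_lag) {
    idx <- which(tpl$times >= tpl$window[1] & tpl$times < tpl$window[2])
    tw <- tpl$values[, idx, drop = FALSE]
    tw <- tw - rowMeans(tw)
    lo <- max(-max_lag, 1 - min(idx)); hi <- min(max_lag, ncol(trial) - max(idx))
    best <- NA; best_score <- -Inf
    for (L in lo:hi) {
      seg <- trial[, idx + L, drop = FALSE]
      seg <- seg - rowMeans(seg)
      sc <- 0
      for (ch in seq_len(nrow(tw))) sc <- sc + sum(tw[ch, ] * seg[ch, ])
      if (sc > best_score + 1e-9 ||
          (abs(sc - best_score) <= 1e-9 &&
           (abs(L) < abs(best) || (abs(L) == abs(best) && L < best)))) {
        best_score <- max(sc, best_score); best <- L
      }
    }
    best
  }
  for (rep in 1:25) {
    trial <- matrix(rnorm(5 * length(times)), 5)
    expect_equal(as.integer(estimate_c_latency(trial, tpl, 40)),
                 oracle_lag(trial, tpl, 40))
  }
  expect_error(estimate_c_latency(vals, erp_template(vals * 0, times,
                                                     c(200, 900)), 50),
               "all zero")
})

test_that("a C-only dataset is recovered cleanly", {
  # bump chosen to sit fully inside the C window so the template can
  # represent it; jitter 30 ms keeps displaced bumps inside as well
  comps <- default_components(c_latency_ms = c(400, 400),
                              c_width_ms = c(60, 60), c_jitter_sd_ms = 30,
                              c_amplitude = c(5, 5))
  comps$S$amplitude <- 0; comps$R$amplitude <- 0
  gen <- simulate_epochs(tiny_sim(trials = 16, noise_sd = 0,
                                  components = comps))
  cell <- subset_trials(gen$epochs, which(gen$epochs$labels == "primed" &
                                            gen$epochs$subjects == "s01"))
  dec <- suppressWarnings(ride_decompose(cell))
  truew <- component_waveform(comps$C, 400, cell$times, amplitude = 5,
                              channel_names = tiny_montage())
  win <- cell$times >= 240 & cell$times < 860  # clear of the template taper
  cpk <- max(abs(truew))
  expect_gt(cor(as.numeric(dec$c_template$values[, win]),
                as.numeric(truew[, win])), 0.99)
  # stimulus-locked leftovers are <1% of the C peak; the response-locked
  # template retains a few percent because RT co-varies with the C latency
  expect_lt(max(abs(dec$s_template$values)), 0.01 * cpk)
  expect_lt(max(abs(dec$r_template$values)), 0.05 * cpk)
})

test_that("zero jitter yields all-zero latency lags", {
  gen <- simulate_epochs(tiny_sim(trials = 10, noise_sd = 0, jitter = 0,
                                  motor_sigma = 0))
  dec <- quiet_decompose(gen$epochs)
  expect_true(all(dec$c_lags == 0L))
})

test_that("estimated lags are invariant to global amplitude scaling", {
  gen <- simulate_epochs(tiny_sim(trials = 12, noise_sd = 1, seed = 3))
  d1 <- quiet_decompose(gen$epochs)
  scaled <- gen$epochs
  scaled$data <- scaled$data * 3.7
  d2 <- quiet_decompose(scaled)
  expect_identical(d1$c_lags, d2$c_lags)
})

test_that("adding a constant lag to every trial shifts every estimated lag", {
  comps <- default_components(c_jitter_sd_ms = 30)
  comps$S$amplitude <- 0; comps$R$amplitude <- 0
  gen <- simulate_epochs(tiny_sim(trials = 12, noise_sd = 0,
                                  components = comps, motor_sigma = 0))
  cell_idx <- which(gen$epochs$labels == "primed")
  cell <- subset_trials(gen$epochs, cell_idx)
  k <- 6L
  shifted <- cell
  for (i in seq_len(dim(cell$data)[1]))
    shifted$data[i, , ] <- shift_trial(cell$data[i, , ], k)
  d1 <- suppressWarnings(ride_decompose(cell))
  d2 <- suppressWarnings(ride_decompose(shifted))
  # template re-centering absorbs the common shift: lag differences persist
  expect_equal(d2$c_lags - mean(d2$c_lags), d1$c_lags - mean(d1$c_lags),
               tolerance = 0.5)
})

test_that("the reconstruction defect is non-increasing and decomposition exact", {
  gen <- simulate_epochs(tiny_sim(trials = 12, noise_sd = 2, seed = 6))
  cell <- subset_trials(gen$epochs, which(gen$epochs$labels == "primed"))
  dec <- suppressWarnings(ride_decompose(cell))
  rn <- dec$residual_norms
  expect_true(all(diff(rn) <= 0.01 * rn[-length(rn)]))
  # s + c + r + residual reproduces the input exactly by construction
  recon <- dec$s_trials + dec$c_trials + dec$r_trials + dec$residual
  expect_equal(recon, cell$data, tolerance = 1e-12)
})

test_that("missing RTs fall back to a two-component decomposition", {
  gen <- simulate_epochs(tiny_sim(trials = 8, noise_sd = 0))
  cell <- subset_trials(gen$epochs, which(gen$epochs$labels == "primed"))
  cell$rts <- NULL
  dec <- suppressWarnings(ride_decompose(cell))
  expect_false(dec$have_r)
  expect_null(dec$r_template)
  recon <- dec$s_trials + dec$c_trials + dec$residual
  expect_equal(recon, cell$data, tolerance = 1e-12)
})

test_that("extract_c_trials carries metadata and removes the S cluster", {
  comps <- default_components(s_amplitude = c(12, 12))  # S much larger than C
  gen <- simulate_epochs(tiny_sim(trials = 14, noise_sd = 0,
                                  components = comps))
  dec <- quiet_decompose(gen$epochs)
  c_ep <- extract_c_trials(dec)
  expect_identical(c_ep$labels, gen$epochs$labels)
  expect_identical(c_ep$subjects, gen$epochs$subjects)
  expect_equal(c_ep$rts, gen$epochs$rts)
  expect_equal(dim(c_ep$data), dim(gen$epochs$data))
  # the stimulus-locked average in the S window drops from the full S
  # amplitude to a small leftover (per-trial content there is genuine early
  # C-tail activity, which is latency-variable and averages out)
  early <- c_ep$times >= 100 & c_ep$times < 200
  oz <- match("Oz", tiny_montage())
  raw_avg <- apply(gen$epochs$data[, oz, early], 2, mean)
  c_avg <- apply(c_ep$data[, oz, early], 2, mean)
  expect_gt(max(abs(raw_avg)), 6)          # S dominates the raw average
  expect_lt(max(abs(c_avg)), 0.15 * max(abs(raw_avg)))
  expect_equal(attr(c_ep, "c_lags"), dec$c_lags)
})
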