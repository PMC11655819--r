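test_that("within-condition correction shifts each trial by minus its lag", {
  set.seed(1)
  dat <- array(rnorm(3 * 2 * 40), c(3, 2, 40))
  ep <- toy_epochs(dat, labels = rep("a", 3))
  lags <- c(5L, 0L, -3L)
  out <- correct_within_condition(ep, lags)
  for (i in 1:3)
    expect_equal(out$data[i, , ], shift_trial(dat[i, , ], -lags[i]))
  expect_equal(attr(out, "applied_shifts"), -lags)
  # all-zero lags: identity
  expect_equal(correct_within_condition(ep, c(0L, 0L, 0L))$data, dat)
  # a +50 ms lag at 250 Hz is a 13-sample shift (round half away from zero)
  expect_equal(ms_to_samples(50, 250), 13L)
  expect_equal(ms_to_samples(-50, 250), -13L)
})

test_that("jitter correction restores the smeared average peak", {
  comps <- default_components(c_jitter_sd_ms = 50, c_width_ms = c(60, 60),
                              c_amplitude = c(5, 5))
  gen <- simulate_epochs(tiny_sim(trials = 40, noise_sd = 0,
                                  components = comps, seed = 2))
  dec <- quiet_decompose(gen$epochs)
  step1 <- extract_c_trials(dec)
  step2 <- correct_within_condition(step1)
  pz <- match("Pz", tiny_montage())
  true_peak <- 5  # single-trial C peak at Pz (topography weight 1)
  for (cond in unique(step2$labels)) {
    a1 <- average_erp(step1, cond)$erp[[cond]][pz, ]
    a2 <- average_erp(step2, cond)$erp[[cond]][pz, ]
    expect_lt(max(abs(a1)), 0.92 * true_peak)     # smeared before
    expect_gt(max(abs(a2)), 0.95 * max(abs(a1)))  # never worse after
    expect_gt(max(abs(a2)), 0.9 * true_peak)      # mostly restored
  }
})

test_that("template_peak_latency finds the absolute peak with early ties", {
  times <- seq(0, 996, by = 4)
  vals <- matrix(0, 2, length(times))
  vals[1, ] <- 3 * exp(-((times - 400)^2) / (2 * 50^2))
  vals[2, ] <- -2 * exp(-((times - 600)^2) / (2 * 50^2))
  tpl <- erp_template(vals, times, c(200, 900))
  expect_equal(template_peak_latency(tpl, "a",
                                     channel_names = c("a", "b")), 400)
  # negative-going peak found under the absolute-value convention
  expect_equal(template_peak_latency(tpl, "b",
                                     channel_names = c("a", "b")), 600)
  # random template equals an argmax-by-loop oracle
  set.seed(3)
  vals2 <- matrix(rnorm(2 * length(times)), 2)
  tpl2 <- erp_template(vals2, times, c(100, 800))
  idx <- which(times >= 100 & times < 800)
  best <- idx[1]
  for (j in idx) if (abs(vals2[1, j]) > abs(vals2[1, best])) best <- j
  expect_equal(template_peak_latency(tpl2, "a", channel_names = c("a", "b")),
               times[best])
  flat <- erp_template(matrix(0, 2, length(times)), times, c(200, 900))
  expect_error(template_peak_latency(flat, "a", channel_names = c("a", "b")),
               "flat")
})

test_that("between-condition sync shifts each condition to the median peak", {
  # two conditions with peaks at 360 and 440 ms -> target 400, +-10 samples
  times <- seq(-100, 1496, by = 4)
  nch <- 3
  mk <- function(lat) {
    v <- matrix(0, nch, length(times))
    v[1, ] <- exp(-((times - lat)^2) / (2 * 40^2))
    v[2, ] <- -v[1, ] / 2; v[3, ] <- -v[1, ] / 2
    v
  }
  dat <- array(0, c(4, nch, length(times)))
  dat[1, , ] <- mk(360); dat[2, , ] <- mk(360)
  dat[3, , ] <- mk(440); dat[4, , ] <- mk(440)
  ep <- epoch_set(dat, 250, times = times, channel_names = c("Pz", "x", "y"),
                  labels = c("a", "a", "b", "b"), check_reference = FALSE)
  out <- correct_between_conditions(ep, reference_electrode = "Pz")
  expect_equal(unname(attr(out, "applied_shifts")), c(10L, 10L, -10L, -10L))
  pk <- attr(out, "peak_latencies")
  expect_equal(sort(unique(pk$target_ms)), 400)
  # equal peaks: identity
  dat2 <- dat; dat2[3, , ] <- mk(360); dat2[4, , ] <- mk(360)
  ep2 <- epoch_set(dat2, 250, times = times,
                   channel_names = c("Pz", "x", "y"),
                   labels = c("a", "a", "b", "b"), check_reference = FALSE)
  out2 <- correct_between_conditions(ep2, reference_electrode = "Pz")
  expect_true(all(attr(out2, "applied_shifts") == 0L))
  expect_equal(out2$data, dat2)
  ep3 <- subset_trials(ep, 1:2)
  expect_error(correct_between_conditions(ep3), "two conditions")
})

test_that("between-subject sync targets the median subject peak", {
  times <- seq(-100, 1496, by = 4)
  mk <- function(lat) {
    v <- matrix(0, 2, length(times))
    v[1, ] <- exp(-((times - lat)^2) / (2 * 40^2)); v[2, ] <- -v[1, ]
    v
  }
  dat <- array(0, c(6, 2, length(times)))
  peaks <- c(380, 400, 460)
  for (s in 1:3) for (t in 1:2) dat[(s - 1) * 2 + t, , ] <- mk(peaks[s])
  ep <- epoch_set(dat, 250, times = times, channel_names = c("Pz", "x"),
                  labels = rep(c("a", "b"), 3),
                  subjects = rep(c("s1", "s2", "s3"), each = 2),
                  check_reference = FALSE)
  out <- correct_between_subjects(ep, reference_electrode = "Pz")
  expect_equal(attr(out, "target_ms"), 400)
  expect_equal(unname(attr(out, "applied_shifts")),
               rep(c(5L, 0L, -15L), each = 2))
  # a single subject is left untouched
  one <- subset_trials(ep, 1:2)
  out1 <- correct_between_subjects(one, reference_electrode = "Pz")
  expect_equal(out1$data, one$data)
})

test_that("gfp_normalize equates activation and preserves topography", {
  set.seed(4)
  dat <- array(rnorm(3 * 6 * 30, sd = 4), c(3, 6, 30))
  dat <- sweep(dat, c(1, 3), apply(dat, c(1, 3), mean))  # average reference
  ep <- toy_epochs(dat, labels = rep("a", 3))
  out <- gfp_normalize(ep)
  g <- gfp(out)
  expect_true(all(abs(g - 1) < 1e-9))
  # scale invariance
  ep3 <- ep; ep3$data <- ep$data * 3
  expect_equal(gfp_normalize(ep3)$data, out$data)
  # per-time-point cosine similarity with the input is 1
  for (i in 1:3) for (t in c(1, 15, 30)) {
    x <- ep$data[i, , t]; y <- out$data[i, , t]
    expect_equal(sum(x * y) / sqrt(sum(x^2) * sum(y^2)), 1, tolerance = 1e-9)
  }
  # idempotence
  expect_equal(gfp_normalize(out)$data, out$data, tolerance = 1e-9)
  # degenerate time points are zeroed
  ep0 <- ep; ep0$data[1, , 5] <- 0
  expect_true(all(gfp_normalize(ep0)$data[1, , 5] == 0))
})

test_that("the pipeline is an identity for a zero-variability single subject", {
  comps <- default_components(c_latency_ms = c(400, 400), c_jitter_sd_ms = 0,
                              c_amplitude = c(5, 5), c_width_ms = c(90, 90),
                              c_topo_spread = c(6, 6), s_amplitude = c(4, 4),
                              subject_sd_ms = 0)
  gen <- simulate_epochs(tiny_sim(trials = 8, noise_sd = 0,
                                  components = comps, motor_sigma = 0))
  stages <- quiet_pipeline(gen$epochs, gfp = FALSE)
  for (nm in c("step2", "step3", "step4"))
    expect_true(all(stages[[nm]]$applied_shifts == 0L),
                info = paste("stage", nm))
})

test_that("all stages share the cropped analysis-window geometry", {
  gen <- simulate_epochs(tiny_sim(trials = 6, noise_sd = 1, seed = 5))
  stages <- quiet_pipeline(gen$epochs)
  for (nm in names(stages)) {
    ep <- stages[[nm]]$epochs
    expect_equal(dim(ep$data)[3], 250)  # 1 s at 250 Hz
    expect_equal(range(ep$times), c(100, 1096))
    expect_equal(dim(ep$data)[1], dim(gen$epochs$data)[1])
  }
  prov <- attr(stages, "provenance")
  expect_equal(nrow(prov), dim(gen$epochs$data)[1])
  expect_true(all(c("original", "step2", "step3", "step4") %in% names(prov)))
})

test_that("steps 3-4 shift uniformly within condition and subject", {
  gen <- simulate_epochs(tiny_sim(n_subjects = 2, trials = 6, noise_sd = 1,
                                  seed = 6))
  stages <- quiet_pipeline(gen$epochs)
  prov <- attr(stages, "provenance")
  d3 <- prov$step3 - prov$step2
  d4 <- prov$step4 - prov$step3
  cell <- paste(prov$subject, prov$condition)
  for (cl in unique(cell))
    expect_length(unique(d3[cell == cl]), 1)
  for (s in unique(prov$subject))
    expect_length(unique(d4[prov$subject == s]), 1)
})

test_that("pure time shifts preserve the interior sample multiset", {
  gen <- simulate_epochs(tiny_sim(trials = 5, noise_sd = 1, seed = 7))
  stages <- quiet_pipeline(gen$epochs, analysis_window = c(-100, 1500))
  s1 <- stages$step1$epochs; s2 <- stages$step2$epochs
  sh <- stages$step2$applied_shifts
  for (i in seq_along(sh)) {
    v1 <- as.numeric(s1$data[i, , ])
    v2 <- as.numeric(s2$data[i, , ])
    # shifted-out columns excluded: compare sorted interior values
    nts <- dim(s1$data)[3]
    keep1 <- if (sh[i] >= 0) seq_len(nts - sh[i]) else (1 - sh[i]):nts
    expect_equal(sort(as.numeric(s1$data[i, , keep1])),
                 sort(as.numeric(s2$data[i, , keep1 + sh[i]])))
  }
})

test_that("stage selection returns exactly the requested stages", {
  gen <- simulate_epochs(tiny_sim(trials = 5, noise_sd = 0, seed = 8))
  stages <- quiet_pipeline(gen$epochs, stages = c("original", "step2"))
  expect_named(stages, c("original", "step2"))
})

test_that("two pipeline runs on the same simulated seed are identical", {
  cfg <- tiny_sim(trials = 5, noise_sd = 1, seed = 9)
  s1 <- quiet_pipeline(simulate_epochs(cfg)$epochs)
  s2 <- quiet_pipeline(simulate_epochs(cfg)$epochs)
  for (nm in names(s1))
    expect_identical(s1[[nm]]$epochs$data, s2[[nm]]$epochs$data)
})
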