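test_that("gfp is the population standard deviation across channels", {
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(c(5, 5, 5, 5)), 0)
  # independent two-pass mean/variance oracle on a random 41-channel snapshot
  set.seed(1)
  v <- rnorm(41, sd = 4)
  mu <- sum(v) / length(v)
  oracle <- sqrt(sum((v - mu)^2) / length(v))
  expect_equal(gfp(v), oracle, tolerance = 1e-12)
  expect_error(gfp(3), "2 channels")
})

test_that("gfp is scale-equivariant and offset-invariant", {
  set.seed(2)
  v <- rnorm(12)
  for (a in c(-2.5, 0.3, 7)) expect_equal(gfp(a * v), abs(a) * gfp(v))
  expect_equal(gfp(v + 42), gfp(v))
  # matrix and epoch_set forms agree with the per-snapshot form
  m <- matrix(rnorm(12 * 9), 12, 9)
  expect_equal(gfp(m), apply(m, 2, gfp))
  ep <- toy_epochs(array(rnorm(2 * 12 * 9), c(2, 12, 9)))
  expect_equal(gfp(ep)[2, ], gfp(ep$data[2, , ]))
})

test_that("shift_trial pads with zeros and matches the index oracle", {
  set.seed(3)
  tr <- matrix(rnorm(5 * 20), 5, 20)
  expect_identical(shift_trial(tr, 0), tr)
  # +7 then -7: the samples never shifted off the grid are restored and the
  # 7 shifted-out samples come back as zero padding
  back <- shift_trial(shift_trial(tr, 7), -7)
  expect_equal(back[, 1:13], tr[, 1:13])
  expect_true(all(back[, 14:20] == 0))
  fwd <- shift_trial(shift_trial(tr, -7), 7)
  expect_equal(fwd[, 8:20], tr[, 8:20])
  expect_true(all(fwd[, 1:7] == 0))
  # lag -3 explicit index oracle: out[, t] = in[, t + 3]
  out <- shift_trial(tr, -3)
  for (t in 1:17) expect_equal(out[, t], tr[, t + 3])
  expect_true(all(out[, 18:20] == 0))
  expect_error(shift_trial(tr, 20), "lag")
})

test_that("shift_trial preserves energy minus the padded samples", {
  set.seed(4)
  tr <- matrix(rnorm(4 * 30), 4, 30)
  for (lag in c(-9, -1, 2, 12)) {
    out <- shift_trial(tr, lag)
    lost <- if (lag > 0) tr[, (30 - lag + 1):30, drop = FALSE]
            else tr[, 1:(-lag), drop = FALSE]
    expect_equal(sum(out^2), sum(tr^2) - sum(lost^2), tolerance = 1e-12)
  }
})

test_that("crop_epochs uses half-open windows on the sample grid", {
  ep <- toy_epochs(array(rnorm(2 * 3 * 400), c(2, 3, 400)), tmin = -100)
  expect_equal(dim(crop_epochs(ep, 100, 1100))[3], 250)  # 1 s @ 250 Hz
  expect_equal(crop_epochs(ep, -100, 1500)$data, ep$data)
  twice <- crop_epochs(crop_epochs(ep, 100, 1100), 200, 300)
  once <- crop_epochs(ep, 200, 300)
  expect_equal(twice$data, once$data)
  expect_equal(twice$times, once$times)
  expect_error(crop_epochs(ep, 2000, 2100), "no samples")
})

test_that("crop and average commute", {
  ep <- toy_epochs(array(rnorm(6 * 4 * 100), c(6, 4, 100)))
  a <- average_erp(crop_epochs(ep, 40, 200))$erp
  b <- lapply(average_erp(ep)$erp, function(m)
    m[, ep$times >= 40 & ep$times < 200])
  expect_equal(unname(a$a), unname(b$a))
  expect_equal(unname(a$b), unname(b$b))
})

test_that("average_erp averages within condition and forms difference waves", {
  tr <- matrix(rnorm(3 * 10), 3, 10)
  dat <- array(0, c(4, 3, 10))
  for (i in 1:4) dat[i, , ] <- tr
  ep <- toy_epochs(dat, labels = c("a", "a", "b", "b"))
  avg <- average_erp(ep)
  expect_equal(unname(avg$erp$a), tr)
  # v and -v average to zero
  dat2 <- array(0, c(2, 3, 10)); dat2[1, , ] <- tr; dat2[2, , ] <- -tr
  avg2 <- average_erp(toy_epochs(dat2, labels = c("a", "a")), "a")
  expect_equal(max(abs(avg2$erp$a)), 0)
  expect_error(average_erp(ep, c("a", "zz")), "zz")
})

test_that("jitter attenuates the averaged peak by the large-n smearing factor", {
  # 50 jittered Gaussian bumps vs a brute-force average at 10x the count
  set.seed(5)
  times <- seq(-100, 1496, by = 4)
  spec <- component_spec("C", width_ms = 60, amplitude = 1, latency_ms = 400,
                         topography = c(1, -1))
  gen_avg <- function(n) {
    lags <- rnorm(n, 0, 50)
    acc <- 0
    for (l in lags)
      acc <- acc + component_waveform(spec, 400 + l, times,
                                      channel_names = c("x", "y"))
    acc / n
  }
  peak50 <- max(abs(gen_avg(50)[1, ]))
  oracle <- max(abs(gen_avg(500)[1, ]))
  expect_lt(peak50, 1)  # attenuated relative to the single-trial peak
  expect_equal(peak50, oracle, tolerance = 0.1)
})

test_that("tukey_rt_filter drops short RTs and fence outliers per cell", {
  dat <- array(rnorm(11 * 2 * 10), c(11, 2, 10))
  rts <- c(seq(400, 490, by = 10), 5000)
  ep <- toy_epochs(dat, labels = rep("a", 11), rts = rts)
  kept <- tukey_rt_filter(ep)
  expect_equal(attr(kept, "kept"), 1:10)  # the 5000 ms trial is removed
  # RT below the minimum is removed regardless of fences
  ep2 <- toy_epochs(dat, labels = rep("a", 11),
                    rts = c(150, seq(400, 490, by = 10)))
  expect_false(1 %in% attr(tukey_rt_filter(ep2), "kept"))
})

test_that("tukey_rt_filter matches an independent fence oracle and is idempotent", {
  set.seed(6)
  n <- 40
  dat <- array(rnorm(n * 2 * 5), c(n, 2, 5))
  rts <- c(rlnorm(n - 3, log(500), 0.2), 150, 3000, NA)
  labs <- rep(c("a", "b"), length.out = n)
  subj <- rep(c("s1", "s2"), each = n / 2)
  ep <- epoch_set(dat, srate = 250, tmin = 0, labels = labs, subjects = subj,
                  rts = rts, check_reference = FALSE)
  kept <- attr(tukey_rt_filter(ep), "kept")
  oracle <- !is.na(rts) & rts >= 200
  repeat {
    before <- oracle
    for (s in unique(subj)) for (l in unique(labs)) {
      i <- which(subj == s & labs == l & oracle)
      q <- quantile(rts[i], c(.25, .75), names = FALSE)
      f <- q + c(-1.5, 1.5) * diff(q)
      oracle[i][rts[i] < f[1] | rts[i] > f[2]] <- FALSE
    }
    if (identical(before, oracle)) break
  }
  expect_equal(kept, which(oracle))
  again <- tukey_rt_filter(tukey_rt_filter(ep))
  expect_equal(length(again$rts), length(kept))
})

test_that("amplitude_variability is the per-channel population covariance", {
  set.seed(7)
  times <- seq(0, 396, by = 4)
  vals <- matrix(0, 3, 100)
  win <- times >= 100 & times < 300
  vals[, win] <- rnorm(3 * sum(win))
  tpl <- erp_template(vals, times, c(100, 300))
  # trial = template: covariance equals the population variance
  v <- amplitude_variability(vals, tpl)
  idx <- which(win)
  expect_equal(unname(v[1]),
               mean(vals[1, idx]^2) - mean(vals[1, idx])^2)
  # constant offsets do not change covariance
  expect_equal(amplitude_variability(vals + 3, tpl), v)
  # random pair against the explicit sum oracle
  tr <- matrix(rnorm(300), 3, 100)
  got <- amplitude_variability(tr, tpl)
  x <- tr[2, idx]; y <- vals[2, idx]
  expect_equal(unname(got[2]),
               sum((x - mean(x)) * (y - mean(y))) / length(idx))
  expect_error(amplitude_variability(tr[, 1:50], tpl), "time grid")
})

test_that("epoch_set validates its invariants", {
  dat <- array(rnorm(2 * 3 * 10), c(2, 3, 10))
  expect_error(epoch_set(dat, 250, tmin = 0, labels = "a"), "labels")
  bad <- dat; bad[1] <- NA
  expect_error(epoch_set(bad, 250, tmin = 0, labels = c("a", "b")),
               "non-finite")
  expect_error(epoch_set(dat, 250, times = rev(seq(0, 36, 4)),
                         labels = c("a", "b")), "increasing")
  expect_warning(epoch_set(dat + 10, 250, tmin = 0, labels = c("a", "b")),
                 "average-referenced")
})
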