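make_sine_epochs <- function(freq = 20, fs = 250, win = c(-0.4, 1.0),
                             n_trials = 1, amp = 1) {
  times <- seq(win[1], win[2] - 1 / fs, by = 1 / fs)
  sig <- amp * sin(2 * pi * freq * times)
  eeg_epochs(array(rep(sig, n_trials), c(1, length(times), n_trials)),
             fs, win)
}

tf_freqs <- exp(seq(log(10), log(40), length.out = 40))

test_that("wavelet power peaks at the oscillator frequency", {
  tf <- morlet_tf(make_sine_epochs(20), freqs = tf_freqs)
  mid <- tf$times > 0 & tf$times < 0.5
  peak <- tf_freqs[which.max(rowMeans(tf$power[, mid, 1]))]
  expect_equal(peak, tf_freqs[which.min(abs(tf_freqs - 20))])

  # two-tone signal: both ridges within one bin of the inputs, and the
  # peaks agree with an independent short-time Fourier estimate
  fs <- 250; win <- c(-0.4, 1.0)
  times <- seq(win[1], win[2] - 1 / fs, by = 1 / fs)
  sig <- sin(2 * pi * 12 * times) + sin(2 * pi * 30 * times)
  ep <- eeg_epochs(array(sig, c(1, length(times), 1)), fs, win)
  tf2 <- morlet_tf(ep, freqs = tf_freqs)
  prof <- rowMeans(tf2$power[, mid, 1])
  lo <- tf_freqs[tf_freqs < 20]; hi <- tf_freqs[tf_freqs >= 20]
  pk_lo <- lo[which.max(prof[tf_freqs < 20])]
  pk_hi <- hi[which.max(prof[tf_freqs >= 20])]
  expect_lt(abs(log(pk_lo / 12)), log(tf_freqs[2] / tf_freqs[1]) * 1.5)
  expect_lt(abs(log(pk_hi / 30)), log(tf_freqs[2] / tf_freqs[1]) * 1.5)
  spec <- Mod(fft(sig * (0.5 - 0.5 * cos(2 * pi * seq_along(sig) /
                                           length(sig)))))^2
  fft_freqs <- (seq_along(sig) - 1) * fs / length(sig)
  band <- fft_freqs > 5 & fft_freqs < 45
  top2 <- sort(fft_freqs[band][order(spec[band], decreasing = TRUE)][1:4])
  expect_lt(min(abs(top2 - 12)), 1)
  expect_lt(min(abs(top2 - 30)), 1)
})

test_that("wavelet power is quadratic in signal amplitude", {
  tf1 <- morlet_tf(make_sine_epochs(20, amp = 1), freqs = tf_freqs)
  tf3 <- morlet_tf(make_sine_epochs(20, amp = 3), freqs = tf_freqs)
  mid <- tf1$times > 0 & tf1$times < 0.5
  expect_equal(mean(tf3$power[, mid, 1] / tf1$power[, mid, 1]), 9,
               tolerance = 1e-6)

  # amplitude step of x2: power ratio 4 away from the transition
  fs <- 250; win <- c(-0.4, 1.0)
  times <- seq(win[1], win[2] - 1 / fs, by = 1 / fs)
  sig <- sin(2 * pi * 20 * times) * ifelse(times > 0.3, 2, 1)
  tf <- morlet_tf(eeg_epochs(array(sig, c(1, length(times), 1)), fs, win),
                  freqs = tf_freqs)
  fb <- which.min(abs(tf_freqs - 20))
  r <- mean(tf$power[fb, tf$times > 0.55 & tf$times < 0.9, 1]) /
    mean(tf$power[fb, tf$times > -0.15 & tf$times < 0.1, 1])
  expect_equal(r, 4, tolerance = 0.05)
})

test_that("epochs too short for the lowest-frequency wavelet are rejected", {
  short <- make_sine_epochs(20, win = c(-0.05, 0.15))
  expect_error(morlet_tf(short, freqs = c(2, 20)), "2.00 Hz")
})

test_that("single-trial baseline division normalizes and resists outliers", {
  set.seed(28)
  fs <- 250; win <- c(-0.4, 1.0)
  times <- seq(win[1], win[2] - 1 / fs, by = 1 / fs)
  # stationary oscillation: post-baseline power is ~1 everywhere valid
  n_tr <- 6
  dat <- array(NA_real_, c(1, length(times), n_tr))
  for (tr in 1:n_tr)
    dat[1, , tr] <- sin(2 * pi * 20 * times + runif(1, 0, 2 * pi))
  tf <- morlet_tf(eeg_epochs(dat, fs, win), freqs = tf_freqs)
  tfb <- baseline_divide(tf)
  fb <- which.min(abs(tf_freqs - 20))
  inner <- tfb$times > 0 & tfb$times < 0.7
  expect_lt(max(abs(tfb$power[fb, inner, ] - 1)), 0.05)
  expect_equal(tfb$baseline_mode, "single_trial_division")

  # event-locked amplitude doubling: ratio ~4 in the event window
  dat2 <- dat
  for (tr in 1:n_tr)
    dat2[1, , tr] <- dat[1, , tr] * ifelse(times > 0.2, 2, 1)
  tf2 <- baseline_divide(morlet_tf(eeg_epochs(dat2, fs, win),
                                   freqs = tf_freqs))
  expect_equal(mean(tf2$power[fb, tf2$times > 0.45 & tf2$times < 0.8, ]), 4,
               tolerance = 0.1)

  # one trial with an extreme-power baseline: dividing by the average
  # baseline suppresses every trial, while single-trial division only
  # rescales the noisy trial itself
  dat3 <- dat
  dat3[1, times <= 0, 1] <- dat3[1, times <= 0, 1] * 20
  tf3 <- morlet_tf(eeg_epochs(dat3, fs, win), freqs = tf_freqs)
  single <- baseline_divide(tf3)
  avg_base <- rowMeans(apply(tf3$power[, times >= -0.2 & times <= 0, ,
                                       drop = FALSE], c(1, 3), mean))
  avg_div <- sweep(apply(tf3$power, c(1, 2), mean), 1, avg_base, "/")
  single_mean <- apply(single$power, c(1, 2), mean)
  late <- tfb$times > 0.3 & tfb$times < 0.7   # clear of the baseline edge
  expect_lt(mean(avg_div[fb, late]), 0.2)     # crushed by the outlier
  expect_gt(mean(single_mean[fb, late]), 0.7) # close to its true level 1
})

test_that("per-pixel regression recovers implanted slopes and nulls", {
  set.seed(29)
  # synthetic per-trial power with known linear dependence on duration
  d <- rep(make_stimulus_set()$durations, each = 20)
  n_tr <- length(d)
  pow <- array(rnorm(8 * 10 * n_tr, sd = 0.5), c(8, 10, n_tr))
  for (tr in seq_len(n_tr)) pow[3, 5, tr] <- pow[3, 5, tr] + 2.0 * d[tr]
  tf <- structure(list(power = pow, freqs = 1:8, times = 1:10,
                       valid = matrix(TRUE, 8, 10), baseline_mode = "none",
                       trial_meta = data.frame(duration_s = d,
                                               prior_duration_s = d)),
                  class = "tf_map")
  sl <- duration_regression(tf, "present")
  se <- 0.5 / (sd(d) * sqrt(n_tr - 1))
  expect_lt(abs(sl[3, 5] - 2.0), 3 * se)
  expect_lt(abs(mean(sl[-3, ])), 0.1)

  # shuffling the regressor destroys the slope
  tf_sh <- tf
  tf_sh$trial_meta$duration_s <- sample(d)
  sl_sh <- duration_regression(tf_sh, "present")
  expect_lt(abs(sl_sh[3, 5]), abs(sl[3, 5]) / 2)

  # constant regressor is rejected; prior regressor drops NA trials
  tf_const <- tf; tf_const$trial_meta$duration_s <- 0.5
  expect_error(duration_regression(tf_const, "present"), "distinct")
  tf_na <- tf; tf_na$trial_meta$prior_duration_s[1:10] <- NA
  expect_silent(duration_regression(tf_na, "prior"))
})

test_that("cluster permutation controls errors and detects implanted effects", {
  set.seed(30)
  # all-zero maps: no clusters
  zero <- array(0, c(10, 12, 5))
  expect_equal(nrow(cluster_permutation(zero, n_perm = 50)$clusters), 0)

  # sign antisymmetry of the statistic map
  maps <- array(rnorm(10 * 12 * 8), c(10, 12, 8))
  r1 <- cluster_permutation(maps, n_perm = 20, seed = 1)
  r2 <- cluster_permutation(-maps, n_perm = 20, seed = 1)
  expect_equal(r1$stat_map, -r2$stat_map)

  # A = B: zero difference maps, no clusters
  a <- array(rnorm(10 * 12 * 6), c(10, 12, 6))
  expect_equal(nrow(cluster_permutation(condition_contrast(a, a),
                                        n_perm = 50)$clusters), 0)
  expect_equal(condition_contrast(a, a * 0), a)
  expect_error(condition_contrast(a, a[, , 1:3]), "share dimensions")

  # implanted coherent region is detected with a small p
  eff <- maps
  eff[3:5, 4:8, ] <- eff[3:5, 4:8, ] + 1.5
  res <- cluster_permutation(eff, n_perm = 500, seed = 2)
  expect_gt(nrow(res$clusters), 0)
  expect_lt(res$clusters$p[1], 0.05)
  rep <- cluster_report(res, freqs = 1:10, times = 1:12)
  expect_true(any(rep$freq_lo <= 3 & rep$freq_hi >= 5))

  # cluster mass variant runs and orders consistently
  res_m <- cluster_permutation(eff, n_perm = 200, statistic = "mass",
                               seed = 3)
  expect_lt(res_m$clusters$p[1], 0.05)

  expect_warning(cluster_permutation(maps, n_perm = 10), "too small")
  expect_error(cluster_permutation(maps[, , 1, drop = FALSE]), "2 subjects")
})

test_that("synthetic epochs carry the implanted band-power dependence", {
  set.seed(31)
  durs <- make_stimulus_set()$durations
  pd <- sample(rep(durs, 25))
  spec <- eeg_effect_spec(n_trials = length(pd), n_channels = 2,
                          slope_per_second = 2, snr = 0.8)
  ep <- simulate_eeg_epochs(spec, durations = sample(rep(durs, 25)),
                            prior_durations = pd, regressor = "prior")
  expect_equal(dim(ep$data), c(2, 350, length(pd)))
  tf <- morlet_tf(ep, freqs = tf_freqs)
  sl <- duration_regression(tf, "prior")
  band <- tf_freqs >= 17 & tf_freqs <= 23
  win <- tf$times >= 0.3 & tf$times <= 0.9
  out <- tf_freqs >= 32
  expect_gt(mean(sl[band, win]), mean(sl[out, win]) + 0.5)

  # zero slope: no systematic dependence
  spec0 <- eeg_effect_spec(n_trials = length(pd), n_channels = 1,
                           slope_per_second = 0, snr = 0.8)
  ep0 <- simulate_eeg_epochs(spec0, durations = sample(rep(durs, 25)),
                             prior_durations = pd, regressor = "prior")
  sl0 <- duration_regression(morlet_tf(ep0, freqs = tf_freqs), "prior")
  expect_lt(abs(mean(sl0[band, win])), 1)

  expect_error(eeg_effect_spec(10, epoch_window = c(0.1, 1)), "straddle")
  expect_error(eeg_effect_spec(10, effect_window = c(-1, 2)), "outside")
  expect_error(simulate_eeg_epochs(spec, durations = durs), "length")
})
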