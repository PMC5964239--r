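test_that("RT filter keeps inclusive bounds and counts removals", {
  tab <- data.frame(trial_index = 1:5, duration_s = 0.5,
                    prior_duration_s = NA, prior_was_null = FALSE,
                    session = "a", phase = "b", choice = "long",
                    rt_s = c(0.099, 0.100, 0.500, 1.000, 1.001))
  out <- filter_rt(tab, quiet = TRUE)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_removed"), 2)
  expect_equal(out$rt_s, c(0.100, 0.500, 1.000))

  # all in range: identity
  ok <- tab[2:4, ]
  expect_equal(nrow(filter_rt(ok, quiet = TRUE)), 3)

  # removal count equals an independent scan on heavy-tailed simulated RTs
  sim <- sim_session(generative_spec(rt_floor = 0), seed = 8)
  f <- filter_rt(sim, quiet = TRUE)
  expect_equal(attr(f, "n_removed"),
               sum(sim$rt_s < 0.1 | sim$rt_s > 1.0))

  expect_error(filter_rt(tab, lo = 1, hi = 0.5), "smaller")
})

test_that("Gumbel fit recovers known psychometric functions", {
  d <- make_stimulus_set()$durations
  alpha_log <- log(0.55); beta <- 0.12
  bp_true <- gumbel_q(0.5, alpha_log, beta)
  set.seed(9)
  bps <- replicate(200, {
    k <- rbinom(7, 64, gumbel_p(d, alpha_log, beta))
    suppressWarnings(fit_gumbel(d, k, rep(64, 7)))$bp
  })
  expect_lt(abs(median(bps, na.rm = TRUE) / bp_true - 1), 0.02)

  # threshold identities hold exactly on every fit
  for (r in 1:20) {
    k <- rbinom(7, 64, gumbel_p(d, alpha_log, beta))
    f <- suppressWarnings(fit_gumbel(d, k, rep(64, 7)))
    if (!f$converged) next
    expect_identical(f$dl, (f$theta75 - f$theta25) / 2)
    expect_identical(f$cv, f$dl / f$bp)
    expect_true(f$theta25 < f$bp && f$bp < f$theta75)
  }
})

test_that("fit is invariant to duplicating every trial", {
  d <- make_stimulus_set()$durations
  set.seed(10)
  k <- rbinom(7, 32, gumbel_p(d, log(0.5), 0.15))
  f1 <- fit_gumbel(d, k, rep(32, 7), min_per_level = 0)
  f2 <- fit_gumbel(d, 2 * k, rep(64, 7), min_per_level = 0)
  expect_equal(f1$bp, f2$bp, tolerance = 1e-9)
})

test_that("degenerate response patterns are flagged, not fit", {
  d <- make_stimulus_set()$durations
  # all-identical responses / all at chance: non-converged, missing bp
  expect_false(suppressWarnings(fit_gumbel(d, rep(0, 7), rep(16, 7)))$converged)
  expect_false(suppressWarnings(fit_gumbel(d, rep(16, 7), rep(16, 7)))$converged)
  f_half <- suppressWarnings(fit_gumbel(d, rep(8, 7), rep(16, 7)))
  expect_false(f_half$converged)
  expect_true(is.na(f_half$bp))

  # step data: bp bracketed by the adjacent stimulus levels
  k_step <- ifelse(d > 0.52, 64, 0)
  f_step <- suppressWarnings(fit_gumbel(d, k_step, rep(64, 7)))
  expect_true(f_step$converged)
  expect_gt(f_step$bp, d[4]); expect_lt(f_step$bp, d[5])

  expect_error(fit_gumbel(d[1:3], k = c(1, 2), n = c(5, 5)), "equal length")
  expect_error(fit_gumbel(d, k = rep(1, 7), n = NULL), "counts")
})

test_that("bisection point converges to the generative boundary with more data", {
  stim <- make_stimulus_set()
  set.seed(11)
  # strong decision evidence: the choice is governed by the first-stage
  # clock reading against the boundary, so the BP identifies the boundary
  big <- do.call(rbind, lapply(1:10, function(i)
    sim_session(generative_spec(v_gain = 40), stimuli = stim)))
  big$trial_index <- seq_len(nrow(big))
  fit <- fit_gumbel(filter_rt(big, quiet = TRUE))
  expect_lt(abs(fit$bp / 0.52 - 1), 0.03)
  # the default decision stage adds only a small systematic offset
  big2 <- do.call(rbind, lapply(1:5, function(i)
    sim_session(generative_spec(), stimuli = stim)))
  big2$trial_index <- seq_len(nrow(big2))
  fit2 <- fit_gumbel(filter_rt(big2, quiet = TRUE))
  expect_lt(abs(fit2$bp / 0.52 - 1), 0.06)
})

test_that("bias-corrected bootstrap honors its defaults and degenerates sanely", {
  d <- make_stimulus_set()$durations
  set.seed(12)
  k <- rbinom(7, 64, gumbel_p(d, log(0.53), 0.13))
  f <- fit_gumbel(d, k, rep(64, 7))
  fb <- thresholds_bootstrap(f, n_boot = 199)
  expect_equal(attr(fb$boot_ci, "n_boot"), 199)
  expect_equal(attr(fb$boot_ci, "conf"), 0.95)
  expect_true(all(fb$boot_ci[, "lower"] < fb$boot_ci[, "upper"]))
  expect_true(fb$boot_ci["bp", 1] < fb$bp && fb$bp < fb$boot_ci["bp", 2])

  # default request is the conventional 1999 simulations
  expect_equal(formals(thresholds_bootstrap)$n_boot, 1999)

  # zero-noise step data: intervals collapse toward the bracketing levels
  f_step <- suppressWarnings(fit_gumbel(d, ifelse(d > 0.52, 64, 0),
                                        rep(64, 7)))
  fs <- suppressWarnings(thresholds_bootstrap(f_step, n_boot = 99))
  expect_lt(diff(fs$boot_ci["bp", ]), d[5] - d[4] + 1e-6)

  # non-converged fits refuse to bootstrap
  bad <- suppressWarnings(fit_gumbel(d, rep(0, 7), rep(16, 7)))
  expect_error(thresholds_bootstrap(bad), "converged")
})

test_that("chronometric curves summarize RT by duration regardless of choice", {
  tab <- data.frame(trial_index = 1:12,
                    duration_s = rep(c(0.3, 0.5, 0.9), each = 4),
                    prior_duration_s = NA, prior_was_null = FALSE,
                    session = "a", phase = "b",
                    choice = rep(c("short", "long"), 6), rt_s = 0.4)
  ch <- chronometric(tab)
  expect_equal(ch$mean_rt, rep(0.4, 3))
  expect_equal(ch$se_rt, rep(0, 3))

  # single-trial level: missing standard error
  one <- tab[c(1:4, 5), ]
  ch1 <- chronometric(one)
  expect_true(is.na(ch1$se_rt[ch1$n == 1]))

  # RT decreases from the middle toward longer durations in TopDDM data
  sim <- filter_rt(sim_session(seed = 13), quiet = TRUE)
  chs <- chronometric(sim)
  expect_gt(chs$mean_rt[4], chs$mean_rt[7])
})
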