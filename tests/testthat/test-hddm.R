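test_that("Gelman-Rubin diagnostic behaves at its reference points", {
  set.seed(22)
  x <- rnorm(1000)
  # identical chains: rhat equals 1 up to the (n-1)/n finite-sample factor
  expect_lt(abs(gelman_rubin(cbind(x, x)) - 1), 1e-3)
  # grossly separated chains
  expect_gt(gelman_rubin(cbind(rnorm(1000, 0), rnorm(1000, 5))), 1.5)
  # two independent stationary chains rarely exceed 1.01
  hits <- replicate(100, gelman_rubin(cbind(rnorm(1000), rnorm(1000))) < 1.01)
  expect_gte(mean(hits), 0.95)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(gelman_rubin(list(rnorm(10), rnorm(9))), "equal length")
})

test_that("per-subject MLE recovers generative parameters", {
  set.seed(23)
  p <- ddm_params(a = 1.3, v = 0.9, t0 = 0.25, z = 0.45)
  tab <- ddm_trial_table(p, 800)
  fit <- fit_ddm_mle(tab)
  expect_equal(fit$convergence, 0)
  expect_lt(abs(fit$a / 1.3 - 1), 0.10)
  expect_lt(abs(fit$v / 0.9 - 1), 0.20)
  expect_lt(abs(fit$t0 / 0.25 - 1), 0.10)
  expect_lt(abs(fit$z - 0.45), 0.05)
})

test_that("model comparison attributes a starting-point shift to z", {
  set.seed(24)
  tabs <- lapply(1:6, function(j) {
    a <- rnorm(1, 1.2, 0.1); v <- rnorm(1, 1, 0.2); t0 <- rnorm(1, 0.25, 0.02)
    z <- rnorm(1, 0.5, 0.03)
    rbind(ddm_trial_table(ddm_params(a, v, t0, z), 300, subject = j,
                          phase = "baseline"),
          ddm_trial_table(ddm_params(a, v, t0, z + 0.05), 300, subject = j,
                          phase = "stimulation"))
  })
  trials <- do.call(rbind, tabs)
  cmp <- ddm_model_compare(trials, list(z_shift = list(z = "phase"),
                                        a_shift = list(a = "phase"),
                                        v_shift = list(v = "phase"),
                                        none = list()))
  expect_equal(cmp$model[1], "z_shift")
})

test_that("small hierarchical fits converge and shrink toward the group", {
  set.seed(25)
  truth <- list(a = 1.25, v = 0.9, t0 = 0.25, z = 0.5)
  tabs <- lapply(1:6, function(j)
    ddm_trial_table(ddm_params(rnorm(1, truth$a, 0.08),
                               rnorm(1, truth$v, 0.2),
                               rnorm(1, truth$t0, 0.02),
                               rnorm(1, truth$z, 0.04)), 250, subject = j))
  trials <- do.call(rbind, tabs)
  fit <- fit_hddm(trials, n_chains = 2, n_samples = 400, n_burn = 300,
                  seed = 1)
  expect_true(all(fit$rhat < 1.2))
  mu <- coef(fit)
  expect_lt(abs(mu[["a"]] / truth$a - 1), 0.15)
  expect_lt(abs(mu[["z"]] - truth$z), 0.07)
  expect_true(is.finite(fit$dic))
  expect_s3_class(fit, "hddm_fit")
  expect_output(print(fit), "Hierarchical diffusion fit")
})

test_that("deviance is additive: duplicated data doubles the mean deviance", {
  set.seed(26)
  tabs <- lapply(1:4, function(j)
    ddm_trial_table(ddm_params(1.25, 0.9, 0.25, 0.5), 150, subject = j))
  trials <- do.call(rbind, tabs)
  dup <- trials
  dup$trial_index <- dup$trial_index + max(trials$trial_index)
  doubled <- rbind(trials, dup)
  f1 <- fit_hddm(trials, n_chains = 2, n_samples = 300, n_burn = 200,
                 seed = 2)
  f2 <- fit_hddm(doubled, n_chains = 2, n_samples = 300, n_burn = 200,
                 seed = 3)
  expect_lt(abs(mean(f2$deviance) / (2 * mean(f1$deviance)) - 1), 0.03)
})

test_that("posterior predictive check is self-consistent", {
  set.seed(27)
  tabs <- lapply(1:4, function(j)
    ddm_trial_table(ddm_params(1.25, 0.9, 0.25, 0.5), 200, subject = j,
                    duration = rep(c(0.4, 0.52, 0.7), length.out = 200)))
  trials <- do.call(rbind, tabs)
  fit <- fit_hddm(trials, n_chains = 2, n_samples = 300, n_burn = 250,
                  seed = 4)
  ppc <- posterior_predictive(fit, n_datasets = 200, seed = 5)
  expect_equal(ppc$n_datasets, 200)
  expect_gte(ppc$fraction_inside, 0.8)
  # conventional default
  expect_equal(formals(posterior_predictive)$n_datasets, 500)
})

test_that("the full generative chain yields the expected parameter patterns", {
  set.seed(21)
  stim <- make_stimulus_set()
  big <- do.call(rbind, lapply(1:10, function(i)
    sim_session(generative_spec(), stimuli = stim)))
  big$trial_index <- seq_len(nrow(big))
  big <- filter_rt(big, quiet = TRUE)
  pars <- t(sapply(stim$durations, function(d) {
    sub <- big[big$duration_s == d, ]
    sub$trial_index <- seq_len(nrow(sub))
    as.numeric(fit_ddm_mle(sub)[1, c("a", "v", "t0", "z")])
  }))
  colnames(pars) <- c("a", "v", "t0", "z")
  # drift negative below the boundary, positive above, increasing
  expect_true(all(pars[1:3, "v"] < 0))
  expect_true(all(pars[5:7, "v"] > 0))
  expect_gt(cor(pars[, "v"], stim$durations, method = "spearman"), 0.9)
  # non-decision time decreases with duration
  expect_lt(cor(pars[, "t0"], stim$durations, method = "spearman"), -0.9)
  # starting point rises toward (and beyond) the middle of the set
  expect_gt(pars[4, "z"], pars[1, "z"])
  expect_gt(pars[7, "z"], pars[4, "z"] - 0.05)
  # boundary separation larger at the extremes than near the boundary
  expect_gt(mean(pars[c(1, 7), "a"]), pars[4, "a"])
})
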