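#' Hierarchical Bayesian estimation of decision-diffusion parameters
#'
#' Fits the second-stage decision diffusion to multi-subject choice/RT data
#' by hierarchical Bayesian MCMC: subject-level parameters are drawn from
#' group-level normal distributions whose mean and SD are themselves
#' inferred, so individual estimates are shrunk toward the group. Sampling is
#' random-walk Metropolis for the subject parameters (step sizes adapted
#' during burn-in) with conjugate Gibbs updates of the group mean and
#' variance; group priors are weakly informative (flat on the mean, a broad
#' inverse-gamma on the variance). Chains are initialized overdispersed.
#' Parameters may vary over trial-table columns via \code{varies}, e.g.
#' \code{list(v = "duration_s")} fits one drift per duration.
#'
#' @param trials trial table with \code{subject}, \code{choice}, \code{rt_s}.
#' @param varies named list mapping parameters (\code{a}, \code{v},
#'   \code{t0}, \code{z}, \code{sz}) to trial-table columns.
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_samples post-burn-in samples per chain.
#' @param n_burn burn-in iterations per chain.
#' @param estimate_sz estimate starting-point variability (otherwise fixed 0).
#' @param seed integer seed.
#' @param err series tolerance of the likelihood kernel.
#' @param progress print a line per chain.
#' @return Object of class \code{hddm_fit}: group-level draws (iterations x
#'   chains x parameters for group means \code{mu_*} and SDs \code{sigma_*}),
#'   posterior summary table, per-subject posterior means, per-parameter
#'   Gelman--Rubin \code{rhat}, deviance draws, DIC, and a \code{converged}
#'   flag (all rhat <= 1.1).
#' @export
fit_hddm <- function(trials, varies = list(), n_chains = 4,
                     n_samples = 5000, n_burn = 2000,
                     estimate_sz = FALSE, seed = NULL, err = 1e-7,
                     progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (n_chains < 1) stop("need at least one chain", call. = FALSE)
  if (n_samples < 1) stop("n_samples must exceed 0", call. = FALSE)
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  t2 <- trials[!is.na(trials$choice) & !is.na(trials$rt_s) &
                 trials$trial_index >= 1, , drop = FALSE]
  subjects <- sort(unique(t2$subject))
  J <- length(subjects)
  if (J < 2) warning("hierarchical shrinkage is ill-defined with < 2 subjects")

  lay <- ddm_layout(t2, varies)
  est_pars <- c("a", "v", "t0", "z", if (estimate_sz) "sz")
  est_idx <- unlist(lapply(est_pars, function(p)
    lay$offsets[[p]] + seq_len(lay$n_each[[p]])))
  P <- length(est_idx)
  par_type <- rep(lay$pars, lay$n_each)[est_idx]
  par_names <- lay$names[est_idx]

  lower <- c(a = 0.05, v = -25, t0 = 1e-4, z = 0.03, sz = 0)[par_type]
  upper <- c(a = 8, v = 25, t0 = 1.5, z = 0.97, sz = 0.5)[par_type]

  # per-subject data and parameter-expansion indices
  sub_dat <- lapply(subjects, function(s) {
    rows <- which(t2$subject == s)
    list(rt = t2$rt_s[rows], upper = t2$choice[rows] == "long",
         idx = lapply(lay$pars, function(p) lay$layout[[p]]$index[rows]),
         min_rt = min(t2$rt_s[rows]))
  })

  full_theta <- function(th_est) {
    th <- numeric(lay$n_theta)
    th[est_idx] <- th_est
    th
  }
  sub_ll <- function(j, th_est) {
    th <- full_theta(th_est)
    d <- sub_dat[[j]]
    vals <- lapply(seq_along(lay$pars), function(pi) {
      v <- th[lay$offsets[[pi]] + seq_len(lay$n_each[[pi]])]
      v[d$idx[[pi]]]
    })
    names(vals) <- lay$pars
    if (any(d$rt <= vals$t0)) return(-Inf)
    wfpt_sumlog_cpp(d$rt, d$upper, vals$a, vals$v, vals$t0, vals$z,
                    vals$sz, err)
  }

  start_vals <- c(a = 1.5, v = 0.5, t0 = 0.2, z = 0.5, sz = 0.05)[par_type]
  min_rt_all <- min(t2$rt_s)
  start_vals[par_type == "t0"] <- 0.6 * min_rt_all

  n_keep <- n_samples
  draws <- array(NA_real_, c(n_keep, n_chains, 2L * P),
                 dimnames = list(NULL, NULL,
                                 c(paste0("mu_", par_names),
                                   paste0("sigma_", par_names))))
  dev_draws <- matrix(NA_real_, n_keep, n_chains)
  theta_mean <- matrix(0, J, P, dimnames = list(subjects, par_names))

  # weakly informative inverse-gamma prior on the group variances
  ig_a0 <- 2; ig_b0 <- 0.02

  for (ch in seq_len(n_chains)) {
    if (progress) message("chain ", ch, "/", n_chains)
    theta <- matrix(rep(start_vals, each = J), J, P)
    theta <- theta * matrix(exp(stats::rnorm(J * P, 0, 0.15)), J, P)
    theta[, par_type == "v"] <- theta[, par_type == "v", drop = FALSE] +
      stats::rnorm(J * sum(par_type == "v"), 0, 0.5)
    theta <- pmin(pmax(theta, rep(lower + 1e-4, each = J)),
                  rep(upper - 1e-4, each = J))
    ll <- vapply(seq_len(J), function(j) sub_ll(j, theta[j, ]), 0)
    # fall back to the common start where the random init is degenerate
    for (j in which(!is.finite(ll))) {
      theta[j, ] <- start_vals
      ll[j] <- sub_ll(j, theta[j, ])
    }
    mu <- colMeans(theta)
    sigma <- pmax(apply(theta, 2, stats::sd), 0.05)
    scale <- matrix(0.1, J, P)
    acc <- matrix(0, J, P); try_n <- matrix(0, J, P)

    for (it in seq_len(n_burn + n_samples)) {
      for (j in seq_len(J)) {
        for (p in seq_len(P)) {
          prop <- theta[j, p] + scale[j, p] * stats::rnorm(1)
          try_n[j, p] <- try_n[j, p] + 1
          if (prop < lower[p] || prop > upper[p]) next
          th_new <- theta[j, ]; th_new[p] <- prop
          ll_new <- sub_ll(j, th_new)
          if (!is.finite(ll_new)) next
          lr <- ll_new - ll[j] +
            stats::dnorm(prop, mu[p], sigma[p], log = TRUE) -
            stats::dnorm(theta[j, p], mu[p], sigma[p], log = TRUE)
          if (log(stats::runif(1)) < lr) {
            theta[j, p] <- prop
            ll[j] <- ll_new
            acc[j, p] <- acc[j, p] + 1
          }
        }
      }
      if (it <= n_burn && it %% 50L == 0L) {
        rate <- acc / pmax(try_n, 1)
        scale[rate > 0.5] <- scale[rate > 0.5] * 1.3
        scale[rate < 0.25] <- scale[rate < 0.25] / 1.3
        acc[] <- 0; try_n[] <- 0
      }
      # Gibbs update of the group-level normal for each parameter
      for (p in seq_len(P)) {
        mu[p] <- stats::rnorm(1, mean(theta[, p]), sigma[p] / sqrt(J))
        ss <- sum((theta[, p] - mu[p])^2)
        sigma[p] <- sqrt(max((ig_b0 + ss / 2) /
                               stats::rgamma(1, ig_a0 + J / 2), 1e-6))
      }
      if (it > n_burn) {
        k <- it - n_burn
        draws[k, ch, ] <- c(mu, sigma)
        dev_draws[k, ch] <- -2 * sum(ll)
        theta_mean <- theta_mean + theta / (n_samples * n_chains)
      }
    }
  }

  rhat <- if (n_chains >= 2) {
    apply(draws, 3, function(m) gelman_rubin(m))
  } else rep(NA_real_, dim(draws)[3])
  names(rhat) <- dimnames(draws)[[3]]

  post <- apply(draws, 3, function(m) {
    v <- as.numeric(m)
    c(mean = mean(v), sd = stats::sd(v),
      q2.5 = stats::quantile(v, 0.025, names = FALSE),
      q50 = stats::quantile(v, 0.5, names = FALSE),
      q97.5 = stats::quantile(v, 0.975, names = FALSE))
  })

  fit <- structure(list(
    draws = draws, summary = t(post), rhat = rhat,
    subject_means = theta_mean, subjects = subjects,
    par_names = par_names, par_type = par_type,
    varies = varies, layout = lay, est_idx = est_idx,
    deviance = dev_draws,
    settings = list(n_chains = n_chains, n_samples = n_samples,
                    n_burn = n_burn, estimate_sz = estimate_sz, err = err),
    converged = all(is.finite(rhat)) && all(rhat <= 1.1, na.rm = TRUE),
    trials = t2), class = "hddm_fit")
  fit$dic <- dic(fit)
  fit
}

#' @export
print.hddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical diffusion fit: %d subjects, %d chains x %d samples\n",
              length(x$subjects), x$settings$n_chains, x$settings$n_samples))
  cat(sprintf("  convergence: %s (max rhat = %.4f), DIC = %.1f\n",
              if (x$converged) "ok" else "NOT converged",
              max(x$rhat, na.rm = TRUE), x$dic))
  print(round(x$summary, 4))
  invisible(x)
}

#' @export
summary.hddm_fit <- function(object, ...) {
  print(object)
  cat("  per-parameter rhat:\n")
  print(round(object$rhat, 4))
  invisible(object)
}

#' @export
coef.hddm_fit <- function(object, ...) {
  mu <- object$summary[paste0("mu_", object$par_names), "mean"]
  names(mu) <- object$par_names
  mu
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Convergence diagnostic comparing between- and within-chain variance:
#' \code{rhat = sqrt(((n - 1)/n W + B/n) / W)} with \code{W} the mean
#' within-chain variance and \code{B} the between-chain variance of the
#' means (times n). Values near 1 indicate the chains sample the same
#' distribution; identical chains give \code{sqrt((n - 1)/n)}, i.e. 1 up to
#' O(1/n).
#'
#' @param chains iterations x chains matrix (or a list of equal-length
#'   numeric vectors) of draws for one scalar parameter.
#' @return the potential scale reduction factor.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1) stop("chains must have equal length", call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) stop("at least 2 chains are required", call. = FALSE)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Deviance information criterion of a hierarchical fit
#'
#' \code{DIC = Dbar + pD} with \code{pD = Dbar - D(theta_bar)}: the mean
#' posterior deviance plus the effective number of parameters, evaluated at
#' the posterior means of the subject-level parameters.
#'
#' @param fit an \code{hddm_fit}.
#' @return the DIC (a warning is attached when the fit has not converged).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  d_bar <- mean(fit$deviance)
  lay <- fit$layout
  ll_at_mean <- 0
  for (j in seq_along(fit$subjects)) {
    rows <- fit$trials$subject == fit$subjects[j]
    th <- numeric(lay$n_theta)
    th[fit$est_idx] <- fit$subject_means[j, ]
    sub <- fit$trials[rows, , drop = FALSE]
    vals <- lapply(seq_along(lay$pars), function(pi) {
      v <- th[lay$offsets[[pi]] + seq_len(lay$n_each[[pi]])]
      v[lay$layout[[pi]]$index[rows]]
    })
    names(vals) <- lay$pars
    ll_at_mean <- ll_at_mean +
      wfpt_sumlog_cpp(sub$rt_s, sub$choice == "long", vals$a, vals$v,
                      vals$t0, vals$z, vals$sz, fit$settings$err)
  }
  d_hat <- -2 * ll_at_mean
  p_d <- d_bar - d_hat
  out <- d_bar + p_d
  if (!is.null(fit$converged) && !fit$converged)
    warning("DIC computed on a fit that has not converged")
  out
}

#' Per-subject maximum-likelihood diffusion fit
#'
#' Non-hierarchical companion to \code{\link{fit_hddm}}: fits each subject
#' independently by maximizing the first-passage likelihood with L-BFGS-B.
#' Useful for quick model comparison and as the "non-hierarchical" fitting
#' variant.
#'
#' @param trials trial table (one or more subjects).
#' @param varies named list mapping parameters to trial-table columns.
#' @param estimate_sz estimate starting-point variability?
#' @param err likelihood series tolerance.
#' @return data.frame with one row per subject: estimates (one column per
#'   parameter), \code{loglik}, \code{n_params}, \code{aic}, \code{n_trials},
#'   \code{convergence} (0 = success).
#' @export
fit_ddm_mle <- function(trials, varies = list(), estimate_sz = FALSE,
                        err = 1e-6) {
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  t2 <- trials[!is.na(trials$choice) & !is.na(trials$rt_s) &
                 trials$trial_index >= 1, , drop = FALSE]
  lay <- ddm_layout(t2, varies)
  est_pars <- c("a", "v", "t0", "z", if (estimate_sz) "sz")
  est_idx <- unlist(lapply(est_pars, function(p)
    lay$offsets[[p]] + seq_len(lay$n_each[[p]])))
  par_type <- rep(lay$pars, lay$n_each)[est_idx]
  par_names <- lay$names[est_idx]
  lower <- c(a = 0.05, v = -25, t0 = 1e-4, z = 0.03, sz = 0)[par_type]
  upper <- c(a = 8, v = 25, t0 = 1.5, z = 0.97, sz = 0.5)[par_type]

  res <- lapply(sort(unique(t2$subject)), function(s) {
    rows <- which(t2$subject == s)
    sub <- t2[rows, , drop = FALSE]
    idx <- lapply(seq_along(lay$pars), function(pi)
      lay$layout[[pi]]$index[rows])
    nll <- function(th_est) {
      th <- numeric(lay$n_theta)
      th[est_idx] <- th_est
      vals <- lapply(seq_along(lay$pars), function(pi) {
        v <- th[lay$offsets[[pi]] + seq_len(lay$n_each[[pi]])]
        v[idx[[pi]]]
      })
      names(vals) <- lay$pars
      if (any(sub$rt_s <= vals$t0)) return(1e10)
      ll <- wfpt_sumlog_cpp(sub$rt_s, sub$choice == "long", vals$a, vals$v,
                            vals$t0, vals$z, vals$sz, err)
      if (!is.finite(ll)) 1e10 else -ll
    }
    start <- c(a = 1.3, v = 0.3, t0 = 0.5 * min(sub$rt_s), z = 0.5,
               sz = 0.05)[par_type]
    up <- upper
    up[par_type == "t0"] <- min(sub$rt_s) - 1e-4
    opt <- stats::optim(start, nll, method = "L-BFGS-B",
                        lower = lower, upper = up,
                        control = list(maxit = 400))
    out <- as.data.frame(as.list(opt$par))
    names(out) <- par_names
    out$subject <- s
    out$loglik <- -opt$value
    out$n_params <- length(est_idx)
    out$aic <- 2 * length(est_idx) - 2 * out$loglik
    out$n_trials <- nrow(sub)
    out$convergence <- opt$convergence
    out
  })
  do.call(rbind, res)
}

#' Compare diffusion model variants by summed AIC
#'
#' Fits each candidate parameter structure to every subject by maximum
#' likelihood and sums AIC over subjects, the standard fixed-effects model
#' comparison for "which parameter carries the condition effect" questions.
#'
#' @param trials trial table.
#' @param models named list of \code{varies} specifications.
#' @param estimate_sz passed to \code{\link{fit_ddm_mle}}.
#' @return data.frame with model name, total AIC, total log-likelihood and
#'   parameter count, ordered best first.
#' @export
ddm_model_compare <- function(trials, models, estimate_sz = FALSE) {
  rows <- lapply(names(models), function(nm) {
    f <- fit_ddm_mle(trials, varies = models[[nm]], estimate_sz = estimate_sz)
    data.frame(model = nm, aic = sum(f$aic), loglik = sum(f$loglik),
               n_params = sum(f$n_params), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$aic), , drop = FALSE]
}

#' Posterior predictive check by forward simulation
#'
#' Simulates datasets from the fitted model at the per-subject posterior
#' means over the observed design, and compares per-duration choice
#' proportions and RT quantiles of the observed data with the simulated
#' 2.5--97.5\% envelope. The conventional number of simulated datasets is
#' 500.
#'
#' @param fit an \code{hddm_fit}.
#' @param n_datasets simulated datasets.
#' @param seed integer seed.
#' @param dt Euler step for simulation.
#' @return Object of class \code{ppc_result}: data.frame of statistics with
#'   observed value, envelope bounds and an \code{inside} flag, plus the
#'   fraction of statistics inside the envelope.
#' @export
posterior_predictive <- function(fit, n_datasets = 500, seed = NULL,
                                 dt = 0.002) {
  stopifnot(inherits(fit, "hddm_fit"))
  if (!fit$converged)
    warning("posterior predictive check on a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  lay <- fit$layout
  t2 <- fit$trials
  durs <- sort(unique(t2$duration_s))
  qs <- c(0.1, 0.5, 0.9)
  stat_fun <- function(tab) {
    p <- vapply(durs, function(d)
      mean(tab$choice[tab$duration_s == d] == "long"), 0)
    q <- unlist(lapply(durs, function(d)
      stats::quantile(tab$rt_s[tab$duration_s == d], qs, names = FALSE)))
    c(p, q)
  }
  stat_names <- c(paste0("p_long_", round(1000 * durs)),
                  as.vector(outer(paste0("q", 100 * qs), round(1000 * durs),
                                  paste, sep = "_rt_")))
  obs <- stat_fun(t2)

  # per-trial parameter values at the subject posterior means
  n <- nrow(t2)
  per <- list(a = numeric(n), v = numeric(n), t0 = numeric(n),
              z = numeric(n), sz = numeric(n))
  for (j in seq_along(fit$subjects)) {
    rows <- which(t2$subject == fit$subjects[j])
    th <- numeric(lay$n_theta)
    th[fit$est_idx] <- fit$subject_means[j, ]
    for (pi in seq_along(lay$pars)) {
      v <- th[lay$offsets[[pi]] + seq_len(lay$n_each[[pi]])]
      per[[lay$pars[pi]]][rows] <- v[lay$layout[[pi]]$index[rows]]
    }
  }
  sims <- matrix(NA_real_, n_datasets, length(obs))
  tab <- t2
  for (b in seq_len(n_datasets)) {
    z <- per$z
    if (any(per$sz > 0))
      z <- pmin(pmax(z + (stats::runif(n) - 0.5) * per$sz, 1e-6), 1 - 1e-6)
    sim <- ddm_sim_cpp(n, per$a, per$v, per$t0, z, dt, 20)
    tab$choice <- ifelse(sim$upper == 1L, "long", "short")
    tab$rt_s <- sim$t
    sims[b, ] <- stat_fun(tab)
  }
  lo <- apply(sims, 2, stats::quantile, 0.025, na.rm = TRUE)
  hi <- apply(sims, 2, stats::quantile, 0.975, na.rm = TRUE)
  res <- data.frame(statistic = stat_names, observed = obs,
                    lower = lo, upper = hi,
                    inside = obs >= lo & obs <= hi)
  structure(list(table = res, fraction_inside = mean(res$inside),
                 n_datasets = n_datasets), class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf(
    "Posterior predictive check: %d simulated datasets, %.0f%% of %d statistics inside the 95%% envelope\n",
    x$n_datasets, 100 * x$fraction_inside, nrow(x$table)))
  invisible(x)
}
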