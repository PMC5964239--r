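#' Filter trials by reaction time
#'
#' Removes premature and late responses, keeping trials with
#' \code{lo <= rt_s <= hi} (inclusive bounds). The default 100--1000 ms
#' window is the standard cutoff for this task. The number of removed rows
#' is attached as attribute \code{"n_removed"} and reported via message.
#'
#' @param trials trial table with \code{rt_s} present on all candidate rows.
#' @param lo,hi bounds in seconds.
#' @param quiet suppress the removal message.
#' @return the filtered trial table.
#' @export
filter_rt <- function(trials, lo = 0.100, hi = 1.000, quiet = FALSE) {
  if (lo >= hi) stop("lo must be smaller than hi", call. = FALSE)
  keep <- !is.na(trials$rt_s) & trials$rt_s >= lo & trials$rt_s <= hi
  n_removed <- sum(!keep)
  if (!quiet)
    message(sprintf("filter_rt: removed %d of %d trials outside [%g, %g] s",
                    n_removed, nrow(trials), lo, hi))
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}

#' Per-duration "long" response counts
#'
#' @param trials trial table with choices filled; lead-in rows
#'   (\code{trial_index <= 0}) are ignored.
#' @return data.frame with \code{duration_s}, \code{k} (long responses) and
#'   \code{n} (trials).
#' @export
long_counts <- function(trials) {
  t2 <- trials[trials$trial_index >= 1 & !is.na(trials$choice), , drop = FALSE]
  d <- sort(unique(t2$duration_s))
  k <- vapply(d, function(x) sum(t2$choice[t2$duration_s == x] == "long"), 0)
  n <- vapply(d, function(x) sum(t2$duration_s == x), 0)
  data.frame(duration_s = d, k = k, n = n)
}

# binomial MLE of the cumulative Gumbel on (optionally log) duration via the
# cloglog link: P(long | d) = 1 - exp(-exp((u - alpha) / beta)), u = log d.
# Returns NULL when the GLM cannot produce a usable fit.
gumbel_glm <- function(durations, k, n, log_space = TRUE) {
  u <- if (log_space) log(durations) else durations
  X <- cbind(1, u)
  fit <- suppressWarnings(
    stats::glm.fit(X, cbind(k, n - k),
                   family = stats::binomial(link = "cloglog"),
                   control = stats::glm.control(maxit = 100,
                                                epsilon = 1e-12)))
  b <- fit$coefficients
  if (any(!is.finite(b))) return(NULL)
  # perfectly separated (step) data drive the slope to infinity; the IRLS
  # iteration then stops at maxit, but the 50% crossing is still pinned
  # between the bracketing levels, so keep such fits when a crossing exists
  p_obs <- k / n
  crossing <- any(p_obs < 0.5) && any(p_obs > 0.5)
  if (!fit$converged && !crossing) return(NULL)
  list(b0 = b[[1]], b1 = b[[2]], glm = fit)
}

#' Fit a cumulative Gumbel psychometric function
#'
#' Maximum-likelihood binomial fit of the proportion of "long" responses as a
#' cumulative Gumbel on log duration, the natural choice for log-spaced
#' stimulus sets: \code{P(long | d) = 1 - exp(-exp((log d - alpha) / beta))}.
#' The quantile at level p is \code{exp(alpha + beta log(-log(1 - p)))};
#' the fit reports the bisection point (BP, the 50\% quantile), the 25\% and
#' 75\% thresholds, the difference limen \code{DL = (theta75 - theta25) / 2}
#' and the coefficient of variation \code{CV = DL / BP}.
#'
#' The function accepts either a trial table or explicit per-level counts.
#' Degenerate data (responses identical at every level, or no crossing of
#' 50\%) are flagged \code{converged = FALSE} with a missing BP rather than
#' producing a spurious fit.
#'
#' @param x a trial table (with \code{choice} filled) or a numeric vector of
#'   durations in seconds.
#' @param k,n per-level "long" counts and trial counts (when \code{x} is a
#'   duration vector).
#' @param min_per_level minimum trials per level required to attempt a fit
#'   (default 8, the conventional floor for a stable psychometric fit).
#' @param log_space fit on log duration (default) or linear duration.
#' @param ... unused.
#' @return An object of class \code{gumbel_fit} with fields \code{location}
#'   (seconds; the duration at which P(long) = 1 - 1/e), \code{scale}
#'   (Gumbel scale on the fitted axis), \code{bp}, \code{theta25},
#'   \code{theta75}, \code{dl}, \code{cv} (seconds / dimensionless),
#'   \code{n_per_level}, \code{converged}, and the per-level data.
#' @examples
#' d <- exp(seq(log(.3), log(.9), length.out = 7))
#' p <- 1 - exp(-exp((log(d) - log(0.52)) / 0.15))
#' fit <- fit_gumbel(d, k = round(64 * p), n = rep(64, 7))
#' round(fit$bp, 3)
#' @export
fit_gumbel <- function(x, k = NULL, n = NULL, min_per_level = 8,
                       log_space = TRUE, ...) {
  if (is.data.frame(x)) {
    cc <- long_counts(x)
    durations <- cc$duration_s; k <- cc$k; n <- cc$n
  } else {
    durations <- x
    if (is.null(k) || is.null(n))
      stop("supply per-level counts k and n with a duration vector",
           call. = FALSE)
  }
  if (length(durations) != length(k) || length(k) != length(n))
    stop("durations, k and n must have equal length", call. = FALSE)
  keep <- n > 0
  durations <- durations[keep]; k <- k[keep]; n <- n[keep]
  if (length(durations) < 2)
    stop("need at least 2 duration levels with trials", call. = FALSE)
  if (any(n < min_per_level))
    warning(sprintf("levels with fewer than %d trials present", min_per_level))

  out <- list(durations = durations, k = k, n = n, n_per_level = n,
              log_space = log_space, min_per_level = min_per_level,
              location = NA_real_, scale = NA_real_,
              bp = NA_real_, theta25 = NA_real_, theta75 = NA_real_,
              dl = NA_real_, cv = NA_real_, converged = FALSE,
              alpha = NA_real_, beta = NA_real_)
  class(out) <- "gumbel_fit"

  p_obs <- k / n
  degenerate <- all(k == 0) || all(k == n) ||
    stats::var(p_obs) < 1e-12
  g <- if (degenerate) NULL else gumbel_glm(durations, k, n, log_space)
  if (is.null(g) || g$b1 <= 0) return(out)
  alpha <- -g$b0 / g$b1
  beta <- 1 / g$b1
  q <- function(p) {
    u <- alpha + beta * log(-log(1 - p))
    if (log_space) exp(u) else u
  }
  bp <- q(0.5)
  # a usable fit must place the crossing in a physically sensible range
  if (!is.finite(bp) || bp <= 0 ||
      bp < min(durations) / 10 || bp > max(durations) * 10) return(out)
  out$alpha <- alpha; out$beta <- beta
  out$location <- if (log_space) exp(alpha) else alpha
  out$scale <- beta
  out$bp <- bp
  out$theta25 <- q(0.25)
  out$theta75 <- q(0.75)
  out$dl <- (out$theta75 - out$theta25) / 2
  out$cv <- out$dl / out$bp
  out$converged <- TRUE
  out
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat("Cumulative Gumbel psychometric fit",
      if (x$log_space) "(log-duration axis)" else "(linear axis)", "\n")
  if (!x$converged) {
    cat("  fit did not converge (degenerate or non-crossing data)\n")
    return(invisible(x))
  }
  cat(sprintf("  BP = %.1f ms, DL = %.1f ms, CV = %.3f\n",
              1000 * x$bp, 1000 * x$dl, x$cv))
  cat(sprintf("  thresholds: 25%% = %.1f ms, 75%% = %.1f ms\n",
              1000 * x$theta25, 1000 * x$theta75))
  if (!is.null(x$boot_ci)) {
    ci <- x$boot_ci
    cat(sprintf("  BP %d%% CI [%.1f, %.1f] ms (%d bootstrap samples)\n",
                round(100 * attr(ci, "conf")), 1000 * ci["bp", 1],
                1000 * ci["bp", 2], attr(ci, "n_boot")))
  }
  invisible(x)
}

#' @export
summary.gumbel_fit <- function(object, ...) {
  print(object)
  cat("  per-level data:\n")
  print(data.frame(duration_ms = round(1000 * object$durations),
                   p_long = round(object$k / object$n, 3),
                   n = object$n), row.names = FALSE)
  invisible(object)
}

#' @export
coef.gumbel_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, bp = object$bp,
    theta25 = object$theta25, theta75 = object$theta75,
    dl = object$dl, cv = object$cv)
}

#' @export
predict.gumbel_fit <- function(object, newdata = object$durations, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  u <- if (object$log_space) log(newdata) else newdata
  1 - exp(-exp((u - object$alpha) / object$scale))
}

#' @export
simulate.gumbel_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  replicate(nsim, stats::rbinom(length(p), object$n, p), simplify = FALSE)
}

#' @export
plot.gumbel_fit <- function(x, ...) {
  graphics::plot(1000 * x$durations, x$k / x$n, ylim = c(0, 1),
                 xlab = "Duration (ms)", ylab = "P(long)",
                 pch = 19, ...)
  if (x$converged) {
    dd <- seq(min(x$durations), max(x$durations), length.out = 200)
    graphics::lines(1000 * dd, predict(x, dd))
    graphics::abline(v = 1000 * x$bp, h = 0.5, lty = 3)
  }
  invisible(x)
}

#' Bias-corrected bootstrap intervals for psychometric thresholds
#'
#' Parametric bootstrap of the fitted psychometric function: per-level
#' binomial responses are resampled from the fitted curve, the Gumbel is
#' refit, and bias-corrected (BC) percentile intervals are formed for the
#' bisection point and the 25\%/75\% thresholds. The default 1999 bootstrap
#' simulations follow standard practice for threshold interval estimation.
#'
#' @param fit a converged \code{gumbel_fit}.
#' @param n_boot number of bootstrap simulations.
#' @param conf confidence level.
#' @param seed optional integer seed.
#' @return the fit with a \code{boot_ci} matrix attached (rows \code{bp},
#'   \code{theta25}, \code{theta75}; columns lower/upper), carrying
#'   attributes \code{n_boot} and \code{conf}.
#' @export
thresholds_bootstrap <- function(fit, n_boot = 1999, conf = 0.95,
                                 seed = NULL) {
  stopifnot(inherits(fit, "gumbel_fit"))
  if (!fit$converged)
    stop("bootstrap requires a converged fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p_hat <- predict(fit)
  stats_obs <- c(bp = fit$bp, theta25 = fit$theta25, theta75 = fit$theta75)
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, names(stats_obs)))
  for (b in seq_len(n_boot)) {
    kb <- stats::rbinom(length(p_hat), fit$n, p_hat)
    fb <- fit_gumbel(fit$durations, kb, fit$n,
                     min_per_level = 0, log_space = fit$log_space)
    if (fb$converged)
      draws[b, ] <- c(fb$bp, fb$theta25, fb$theta75)
  }
  ok <- stats::complete.cases(draws)
  draws <- draws[ok, , drop = FALSE]
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- t(vapply(names(stats_obs), function(nm) {
    x <- draws[, nm]
    # bias correction: map the observed value's bootstrap quantile through
    # the normal to shift the percentile endpoints
    frac <- mean(x < stats_obs[nm]) + 0.5 * mean(x == stats_obs[nm])
    frac <- min(max(frac, 1 / (length(x) + 1)), length(x) / (length(x) + 1))
    z0 <- stats::qnorm(frac)
    lo <- stats::pnorm(2 * z0 - zc)
    hi <- stats::pnorm(2 * z0 + zc)
    stats::quantile(x, c(lo, hi), names = FALSE, type = 6)
  }, numeric(2)))
  colnames(ci) <- c("lower", "upper")
  attr(ci, "n_boot") <- n_boot
  attr(ci, "conf") <- conf
  attr(ci, "n_used") <- nrow(draws)
  fit$boot_ci <- ci
  fit
}

#' Chronometric curve: RT by stimulus duration
#'
#' Mean and standard error of the reaction time for each tested duration,
#' regardless of the choice made. Levels with no trials are omitted with a
#' warning; a single-trial level reports a missing standard error.
#'
#' @param trials filtered trial table.
#' @return data.frame of class \code{chronometric_curve} with columns
#'   \code{duration_s}, \code{mean_rt}, \code{se_rt}, \code{n}.
#' @export
chronometric <- function(trials) {
  t2 <- trials[trials$trial_index >= 1 & !is.na(trials$rt_s), , drop = FALSE]
  d <- sort(unique(trials$duration_s[trials$trial_index >= 1]))
  rows <- lapply(d, function(x) {
    rt <- t2$rt_s[t2$duration_s == x]
    if (length(rt) == 0L) return(NULL)
    data.frame(duration_s = x, mean_rt = mean(rt),
               se_rt = if (length(rt) > 1) stats::sd(rt) / sqrt(length(rt))
                       else NA_real_,
               n = length(rt))
  })
  if (any(vapply(rows, is.null, TRUE)))
    warning("some duration levels had no usable trials and were omitted")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  class(out) <- c("chronometric_curve", "data.frame")
  out
}

#' @export
plot.chronometric_curve <- function(x, ...) {
  graphics::plot(1000 * x$duration_s, 1000 * x$mean_rt, type = "b", pch = 19,
                 xlab = "Duration (ms)", ylab = "Mean RT (ms)", ...)
  invisible(x)
}
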