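#' Annotate each trial with the previous trial's response
#'
#' Adds a \code{prior_choice} column by matching \code{trial_index - 1}
#' within each subject/session/phase. Call this on the unfiltered trial
#' table (before RT filtering) so the true predecessor is used. Trials whose
#' predecessor was a null trial, missing, or the first trial get NA.
#'
#' @param trials trial table.
#' @return the table with a \code{prior_choice} column.
#' @export
annotate_prior_response <- function(trials) {
  key_cols <- intersect(c("subject", "session", "phase"), names(trials))
  key <- do.call(paste, c(trials[key_cols], sep = "\r"))
  self <- paste(key, trials$trial_index)
  pred <- paste(key, trials$trial_index - 1L)
  idx <- match(pred, self)
  pc <- trials$choice[idx]
  pc[trials$prior_was_null | is.na(trials$prior_duration_s)] <- NA_character_
  trials$prior_choice <- pc
  trials
}

#' Perceptual and decisional carryover of the bisection point
#'
#' Quantifies trial-history effects: one psychometric fit per prior-trial
#' duration yields the BP-versus-prior-duration profile, summarized by the
#' ordinary least-squares slope (a positive slope means the categorical
#' boundary gravitates toward the previous trial's duration). Decisional
#' carryover is the BP difference between trials whose previous response was
#' "short" versus "long" (positive when the boundary sits higher after a
#' "short" response).
#'
#' Trials following null trials, first trials, and lead-in trials are
#' excluded. Prior-duration bins failing the per-level trial minimum or a
#' converged fit are dropped with a warning; the slope is reported missing
#' when fewer than 3 usable bins remain.
#'
#' @param trials trial table with choices (ideally RT-filtered and passed
#'   through \code{\link{annotate_prior_response}} for the decisional part).
#' @param min_per_bin minimum total trials in a prior-duration bin for its
#'   fit to be attempted (in the canonical design each bin holds roughly
#'   64 trials, about 8 per present duration).
#' @return Object of class \code{carryover_result}: list with
#'   \code{bp_by_prior} (data.frame prior_duration_s, bp, n), \code{slope},
#'   \code{slope_se} (seconds BP shift per second of prior duration), and
#'   \code{decisional_delta} (bp after "short" minus bp after "long",
#'   seconds; NA when prior responses are unavailable).
#' @export
carryover_bp <- function(trials, min_per_bin = 8) {
  t2 <- trials[trials$trial_index >= 1 & !trials$prior_was_null &
                 !is.na(trials$prior_duration_s) & !is.na(trials$choice), ,
               drop = FALSE]
  priors <- sort(unique(t2$prior_duration_s))
  rows <- lapply(priors, function(p) {
    sub <- t2[t2$prior_duration_s == p, , drop = FALSE]
    cc <- long_counts(sub)
    if (nrow(cc) < 2 || sum(cc$n) < min_per_bin) return(NULL)
    fit <- suppressWarnings(fit_gumbel(cc$duration_s, cc$k, cc$n,
                                       min_per_level = 0))
    if (!fit$converged) return(NULL)
    data.frame(prior_duration_s = p, bp = fit$bp, n = nrow(sub))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    warning(sprintf("%d prior-duration bin(s) dropped (too few trials or no fit)",
                    dropped))
  bp_by_prior <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  slope <- slope_se <- NA_real_; slope_df <- NA_integer_
  if (!is.null(bp_by_prior) && nrow(bp_by_prior) >= 3) {
    fit <- stats::lm(bp ~ prior_duration_s, data = bp_by_prior)
    sm <- summary(fit)$coefficients
    slope <- sm["prior_duration_s", "Estimate"]
    slope_se <- sm["prior_duration_s", "Std. Error"]
    slope_df <- fit$df.residual
  }
  decisional_delta <- NA_real_
  if ("prior_choice" %in% names(t2) && !all(is.na(t2$prior_choice))) {
    fit_for <- function(resp) {
      sub <- t2[!is.na(t2$prior_choice) & t2$prior_choice == resp, ,
                drop = FALSE]
      cc <- long_counts(sub)
      if (nrow(cc) < 2) return(NA_real_)
      f <- suppressWarnings(fit_gumbel(cc$duration_s, cc$k, cc$n,
                                       min_per_level = 0))
      if (f$converged) f$bp else NA_real_
    }
    decisional_delta <- fit_for("short") - fit_for("long")
  }
  structure(list(bp_by_prior = bp_by_prior, slope = slope,
                 slope_se = slope_se, slope_df = slope_df,
                 decisional_delta = decisional_delta),
            class = "carryover_result")
}

#' @export
print.carryover_result <- function(x, ...) {
  cat("Carryover of the bisection point\n")
  if (!is.null(x$bp_by_prior)) {
    cat("  BP by prior duration:\n")
    print(data.frame(prior_ms = round(1000 * x$bp_by_prior$prior_duration_s),
                     bp_ms = round(1000 * x$bp_by_prior$bp, 1),
                     n = x$bp_by_prior$n), row.names = FALSE)
  }
  if (is.finite(x$slope))
    cat(sprintf("  perceptual slope: %.3f +/- %.3f (s BP per s prior)\n",
                x$slope, x$slope_se))
  else cat("  perceptual slope: not estimable (< 3 usable bins)\n")
  if (is.finite(x$decisional_delta))
    cat(sprintf("  decisional delta (after short - after long): %.1f ms\n",
                1000 * x$decisional_delta))
  invisible(x)
}

#' Sliding-window bisection-point series
#'
#' Tracks the bisection point across a session by fitting the psychometric
#' function inside a sliding window of trials, advancing one trial at a time
#' by default, and smoothing the resulting series with a centered moving
#' average for trend visualization. Windows in which any duration level
#' falls below the per-level minimum are flagged \code{insufficient} rather
#' than silently trusted.
#'
#' @param trials time-ordered trial table for one session/phase.
#' @param window window length in trials (131 is the canonical value for the
#'   7-duration, 448-trial counterbalanced session; see
#'   \code{\link{minimum_window}} to derive the analogue for other designs).
#' @param step trials to advance between windows.
#' @param smooth length of the centered moving average (edge-truncated).
#' @param min_per_level per-level trial minimum for an unflagged window.
#' @return data.frame of class \code{sliding_bp} with columns \code{center}
#'   (mean trial index of the window), \code{bp}, \code{smoothed_bp},
#'   \code{insufficient}.
#' @export
sliding_bp <- function(trials, window = 131, step = 1, smooth = 10,
                       min_per_level = 8) {
  t2 <- trials[trials$trial_index >= 1, , drop = FALSE]
  t2 <- t2[order(t2$trial_index), , drop = FALSE]
  n <- nrow(t2)
  if (window > n) stop("window exceeds the number of trials", call. = FALSE)
  starts <- seq.int(1L, n - window + 1L, by = step)
  levels_all <- sort(unique(t2$duration_s))
  bp <- numeric(length(starts)); insuff <- logical(length(starts))
  centers <- numeric(length(starts))
  for (i in seq_along(starts)) {
    w <- t2[starts[i]:(starts[i] + window - 1L), , drop = FALSE]
    centers[i] <- mean(w$trial_index)
    counts <- table(factor(w$duration_s, levels = levels_all))
    insuff[i] <- any(counts < min_per_level)
    fit <- tryCatch(
      suppressWarnings(fit_gumbel(w, min_per_level = 0)),
      error = function(e) NULL)
    bp[i] <- if (!is.null(fit) && fit$converged) fit$bp else NA_real_
  }
  sm <- moving_average(bp, smooth)
  out <- data.frame(center = centers, bp = bp, smoothed_bp = sm,
                    insufficient = insuff)
  class(out) <- c("sliding_bp", "data.frame")
  attr(out, "window") <- window
  out
}

# centered moving average with edge truncation; for even lengths the window
# extends one further element forward than back
moving_average <- function(x, len) {
  if (len <= 1) return(x)
  back <- floor((len - 1) / 2); fwd <- ceiling((len - 1) / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - back):min(n, i + fwd)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Minimum sliding-window length for stable psychometric fits
#'
#' Smallest window length \code{w} such that every contiguous window of
#' \code{w} trials in the given realized sequence contains at least
#' \code{min_per_level} trials of every duration level. This is how the
#' canonical 131-trial window is derived for a 7-duration counterbalanced
#' session; the value is specific to the realized sequence.
#'
#' @param x a \code{trial_sequence}, a trial table, or a vector of labels.
#' @param min_per_level required trials of each level per window.
#' @return integer window length.
#' @export
minimum_window <- function(x, min_per_level = 8) {
  labels <- if (inherits(x, "trial_sequence")) {
    x$labels[x$labels != "NULL"]
  } else if (is.data.frame(x)) {
    as.character(x$duration_s[x$trial_index >= 1])
  } else as.character(x)
  n <- length(labels)
  lv <- unique(labels)
  f <- factor(labels, levels = lv)
  totals <- table(f)
  if (any(totals < min_per_level))
    stop("requirement unreachable: some level occurs fewer than ",
         min_per_level, " times in the whole sequence", call. = FALSE)
  ok <- function(w) {
    counts <- table(f[seq_len(w)])
    if (any(counts < min_per_level)) return(FALSE)
    if (w < n) {
      for (s in seq_len(n - w)) {
        counts[f[s]] <- counts[f[s]] - 1L
        counts[f[s + w]] <- counts[f[s + w]] + 1L
        if (any(counts < min_per_level)) return(FALSE)
      }
    }
    TRUE
  }
  # check(w) is monotone in w, so binary search brackets the minimum
  lo <- max(min_per_level * length(lv), 1L); hi <- n
  if (!ok(hi)) stop("requirement unreachable at full length", call. = FALSE)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (ok(mid)) hi <- mid else lo <- mid + 1L
  }
  as.integer(lo)
}
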