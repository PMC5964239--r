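#' Construct a log-spaced stimulus set for temporal bisection
#'
#' Builds the set of stimulus durations used in a temporal bisection session:
#' \code{n_levels} durations spaced evenly on a logarithmic axis between
#' \code{t_min} and \code{t_max}. For such a set the geometric mean of all
#' durations equals \code{sqrt(t_min * t_max)}; with the canonical 300--900 ms
#' range this is 520 ms at millisecond precision, the implicit categorical
#' anchor of the task.
#'
#' @param t_min shortest duration, in seconds. Must be positive.
#' @param t_max longest duration, in seconds. Must exceed \code{t_min}.
#' @param n_levels number of durations (at least 2).
#' @return An object of class \code{stimulus_set}: a list with elements
#'   \code{durations} (increasing numeric vector, seconds), \code{t_min},
#'   \code{t_max}, \code{n_levels} and \code{geometric_mean}.
#' @examples
#' s <- make_stimulus_set(0.3, 0.9, 7)
#' round(s$geometric_mean, 3)  # 0.52
#' @export
make_stimulus_set <- function(t_min = 0.3, t_max = 0.9, n_levels = 7) {
  if (!is.numeric(t_min) || !is.numeric(t_max) || t_min <= 0)
    stop("t_min must be a positive number", call. = FALSE)
  if (t_max <= t_min)
    stop("t_max must exceed t_min", call. = FALSE)
  if (n_levels < 2)
    stop("n_levels must be at least 2", call. = FALSE)
  d <- exp(seq(log(t_min), log(t_max), length.out = n_levels))
  structure(
    list(durations = d, t_min = t_min, t_max = t_max,
         n_levels = as.integer(n_levels),
         geometric_mean = exp(mean(log(d)))),
    class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("Stimulus set: %d log-spaced durations, %.0f-%.0f ms\n",
              x$n_levels, 1000 * x$t_min, 1000 * x$t_max))
  cat("  durations (ms):", paste(round(1000 * x$durations), collapse = ", "), "\n")
  cat(sprintf("  geometric mean: %.1f ms\n", 1000 * x$geometric_mean))
  invisible(x)
}
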