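#' Decision-stage diffusion parameters
#'
#' Container for the parameters of the second-stage, two-boundary decision
#' diffusion: boundary separation \code{a}, drift rate \code{v} (signed;
#' negative drifts accumulate toward the "short" boundary at 0, positive
#' toward the "long" boundary at \code{a}), non-decision time \code{t0}
#' (seconds), relative starting point \code{z} in (0, 1), and the width
#' \code{sz} of a uniform trial-to-trial starting-point range. The diffusion
#' coefficient is fixed at 1 (the usual identifiability convention; \code{a}
#' and \code{v} absorb the scale). All fields may be vectors of equal length
#' to index parameters by duration or condition.
#'
#' @param a boundary separation, > 0.
#' @param v drift rate (evidence units per second).
#' @param t0 non-decision time in seconds, >= 0.
#' @param z relative starting point in (0, 1).
#' @param sz starting-point variability range; \code{z +/- sz/2} must stay
#'   inside (0, 1).
#' @return An object of class \code{ddm_params} (a list of the five fields).
#' @export
ddm_params <- function(a, v, t0 = 0.25, z = 0.5, sz = 0) {
  n <- max(length(a), length(v), length(t0), length(z), length(sz))
  a <- rep_len(a, n); v <- rep_len(v, n); t0 <- rep_len(t0, n)
  z <- rep_len(z, n); sz <- rep_len(sz, n)
  if (any(a <= 0)) stop("boundary separation a must be positive", call. = FALSE)
  if (any(t0 < 0)) stop("non-decision time t0 must be >= 0", call. = FALSE)
  if (any(z <= 0 | z >= 1)) stop("z must lie strictly in (0, 1)", call. = FALSE)
  if (any(sz < 0) || any(z - sz / 2 <= 0 | z + sz / 2 >= 1))
    stop("sz must be >= 0 with z +/- sz/2 inside (0, 1)", call. = FALSE)
  structure(list(a = a, v = v, t0 = t0, z = z, sz = sz), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  cat("Decision diffusion parameters (unit diffusion coefficient):\n")
  print(df, row.names = nrow(df) > 1)
  invisible(x)
}

#' Closed-form absorption probability at the "long" boundary
#'
#' Probability that the decision diffusion with drift \code{v}, boundaries 0
#' and \code{a}, and start \code{z * a} is absorbed at the upper ("long")
#' boundary: \code{(1 - exp(-2 v z a)) / (1 - exp(-2 v a))}, reducing to
#' \code{z} when \code{v = 0}.
#'
#' @param params a \code{ddm_params} object (sz is ignored; for \code{sz > 0}
#'   the probability is the average over the uniform starting range, which by
#'   linearity in the zero-drift case equals the value at \code{z}).
#' @return numeric vector of upper-boundary probabilities.
#' @export
ddm_absorption_prob <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  with(params, {
    p <- ifelse(abs(v) < 1e-12, z, expm1(-2 * v * z * a) / expm1(-2 * v * a))
    pmin(pmax(p, 0), 1)
  })
}

#' Simulate decision-stage choices and first-passage times
#'
#' Euler--Maruyama realization of the two-boundary decision diffusion. The
#' returned RT is first-passage time plus non-decision time \code{t0}.
#'
#' @param params a \code{ddm_params} object; vector fields are recycled over
#'   trials, so per-trial parameters are supported.
#' @param n number of trials (defaults to the parameter length).
#' @param dt Euler step in seconds.
#' @param max_t simulation horizon in seconds (paths still unabsorbed are
#'   truncated there; with sensible parameters this is vanishingly rare).
#' @return data.frame with columns \code{choice} ("short"/"long") and
#'   \code{rt} (seconds). Uses the R RNG, so \code{set.seed()} governs it.
#' @export
simulate_decision <- function(params, n = NULL, dt = 0.001, max_t = 20) {
  stopifnot(inherits(params, "ddm_params"))
  if (is.null(n)) n <- length(params$a)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  z <- params$z
  if (any(params$sz > 0))
    z <- pmin(pmax(z + (stats::runif(n) - 0.5) * rep_len(params$sz, n),
                   1e-6), 1 - 1e-6)
  sim <- ddm_sim_cpp(as.integer(n), params$a, params$v, params$t0, z,
                     dt, max_t)
  data.frame(choice = ifelse(sim$upper == 1L, "long", "short"),
             rt = sim$t, stringsAsFactors = FALSE)
}
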