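#' First-stage accumulator parameters
#'
#' The first stage of the two-stage timing model is a noisy linear
#' accumulator ("pacemaker") obeying the stochastic differential equation
#' \code{dx = A dt + m sqrt(A) dB}: deterministic accumulation at rate
#' \code{A} (1/seconds) plus Brownian noise whose standard deviation scales
#' with \code{sqrt(A)}. The rate is normalized to the criterion duration
#' \code{boundary_ref} as \code{A = 1 / boundary_ref}, so the expected
#' endpoint after timing the criterion duration is exactly 1. An optional
#' delta-rule update of \code{A} toward that normalization is available in
#' \code{\link{simulate_bisection}} but off by default.
#'
#' @param boundary_ref criterion duration in seconds to which the rate is
#'   adapted (default the 300--900 ms geometric mean, 0.52 s).
#' @param A accumulation rate; defaults to \code{1 / boundary_ref}.
#' @param m diffusion noise coefficient (dimensionless); \code{m} is also the
#'   coefficient of variation of the endpoint at the criterion duration, so
#'   values of 0.1--0.2 correspond to typical sub-second timing precision.
#' @return Object of class \code{first_stage_params}.
#' @export
first_stage_params <- function(boundary_ref = 0.52, A = 1 / boundary_ref,
                               m = 0.15) {
  if (A <= 0) stop("accumulation rate A must be positive", call. = FALSE)
  if (m < 0) stop("noise coefficient m must be >= 0", call. = FALSE)
  structure(list(A = A, m = m, boundary_ref = boundary_ref),
            class = "first_stage_params")
}

#' Simulate the first-stage accumulator endpoint
#'
#' Euler--Maruyama realization of \code{dx = A dt + m sqrt(A) dB} from 0 to
#' \code{T} (discretized to \code{round(T / dt)} steps). The endpoint is
#' Gaussian with mean \code{A T} and variance \code{m^2 A T}; with
#' \code{m = 0} the result is exactly \code{A T} up to the discretization of
#' \code{T / dt}.
#'
#' @param params a \code{first_stage_params} object.
#' @param T duration to accumulate over, seconds.
#' @param dt Euler step, seconds; must not exceed \code{T}.
#' @param n number of independent replicates.
#' @param full_paths if TRUE, simulate every Euler step explicitly (slow,
#'   used for validation); otherwise draw the endpoint from the exact
#'   distribution of the summed increments, which is identical in law.
#' @return numeric vector of \code{n} endpoints x(T).
#' @export
simulate_first_stage <- function(params, T, dt = 0.001, n = 1,
                                 full_paths = FALSE) {
  stopifnot(inherits(params, "first_stage_params"))
  if (T <= 0) stop("T must be positive", call. = FALSE)
  if (dt <= 0 || dt > T) stop("dt must satisfy 0 < dt <= T", call. = FALSE)
  n_steps <- max(1L, as.integer(round(T / dt)))
  if (full_paths)
    return(accumulator_sim_cpp(as.integer(n), params$A, params$m, n_steps, dt))
  Td <- n_steps * dt
  params$A * Td + params$m * sqrt(params$A * Td) * stats::rnorm(n)
}

#' Generative specification for the two-stage bisection process
#'
#' Assembles everything needed to simulate a full temporal-bisection session:
#' the first-stage accumulator, the mapping of its endpoint into the decision
#' stage, duration-indexed decision parameters, and the trial-history
#' (carryover) drift of the categorical boundary.
#'
#' The linkage between stages is: the accumulator endpoint \code{x} at
#' stimulus offset sets the decision starting point through the clipped
#' affine map \code{z = clip(0.5 + kappa (x - 1), z_clip)}, and the drift is
#' proportional to the signed distance of the endpoint from the current
#' categorical boundary, \code{v = v_gain (x - b / boundary_ref)}. The
#' boundary \code{b} (seconds) starts at \code{boundary_ref} and after every
#' trial with a known predecessor duration is pulled toward it:
#' \code{b <- (1 - carryover_gain) b + carryover_gain * prior_duration}.
#' Boundary separation \code{a} and non-decision time \code{t0} may be
#' functions of duration; the defaults implement the qualitative profile
#' expected for bisection (boundary separation lowest near the categorical
#' boundary and rising toward the extremes; non-decision time decreasing
#' linearly with duration).
#'
#' @param first_stage a \code{first_stage_params} object.
#' @param kappa gain of the endpoint-to-starting-point map.
#' @param z_clip two-vector of clipping bounds for z.
#' @param v_gain drift per unit of (relative) endpoint-boundary distance.
#' @param a_fun function(duration_s, stimuli) -> boundary separation.
#' @param t0_fun function(duration_s, stimuli) -> non-decision time (s).
#' @param carryover_gain weight in [0, 1] pulling the categorical boundary
#'   toward the prior trial's duration (0 = no carryover).
#' @param rt_floor additive RT floor in seconds.
#' @param dt Euler step for the decision diffusion, seconds.
#' @param learning_rate optional delta-rule rate eta for the first-stage
#'   accumulation rate, \code{A <- A + eta (1 - x(T_ref))} applied after each
#'   trial at the criterion duration; 0 disables it.
#' @return Object of class \code{generative_spec}.
#' @export
generative_spec <- function(first_stage = first_stage_params(),
                            kappa = 0.8, z_clip = c(0.05, 0.95),
                            v_gain = 8,
                            a_fun = default_a_fun,
                            t0_fun = default_t0_fun,
                            carryover_gain = 0, rt_floor = 0,
                            dt = 0.001, learning_rate = 0) {
  stopifnot(inherits(first_stage, "first_stage_params"))
  if (carryover_gain < 0 || carryover_gain > 1)
    stop("carryover_gain must lie in [0, 1]", call. = FALSE)
  if (rt_floor < 0) stop("rt_floor must be >= 0", call. = FALSE)
  structure(list(first_stage = first_stage, kappa = kappa, z_clip = z_clip,
                 v_gain = v_gain, a_fun = a_fun, t0_fun = t0_fun,
                 carryover_gain = carryover_gain, rt_floor = rt_floor,
                 dt = dt, learning_rate = learning_rate),
            class = "generative_spec")
}

#' @rdname generative_spec
#' @param duration_s stimulus duration(s), seconds.
#' @param stimuli a \code{stimulus_set} giving the range used to normalize.
#' @export
default_a_fun <- function(duration_s, stimuli) {
  gm <- stimuli$geometric_mean
  u <- log(duration_s / gm) / log(stimuli$t_max / gm)
  1.1 + 0.5 * u^2
}

#' @rdname generative_spec
#' @export
default_t0_fun <- function(duration_s, stimuli) {
  0.30 - 0.10 * (duration_s - stimuli$t_min) / (stimuli$t_max - stimuli$t_min)
}

#' Simulate choices and reaction times for a bisection design
#'
#' Runs the full two-stage generative process over an annotated trial table:
#' for each stimulus trial the first-stage accumulator is integrated to the
#' stimulus offset, its endpoint sets the decision starting point and drift
#' sign/magnitude relative to the (possibly drifting) categorical boundary,
#' and the second-stage diffusion produces the choice and decision time.
#' Lead-in trials (\code{trial_index <= 0}) are simulated but their choices
#' do not enter any analysis downstream.
#'
#' @param design trial table from \code{\link{annotate_transitions}}.
#' @param spec a \code{generative_spec}.
#' @param stimuli the \code{stimulus_set} the design was built from; inferred
#'   from the distinct durations when omitted.
#' @param seed optional integer seed.
#' @return the trial table with \code{choice} and \code{rt_s} filled.
#' @export
simulate_bisection <- function(design, spec = generative_spec(),
                               stimuli = NULL, seed = NULL) {
  stopifnot(inherits(spec, "generative_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (spec$carryover_gain > 0 && !"prior_duration_s" %in% names(design))
    stop("design lacks prior-duration annotations needed for carryover",
         call. = FALSE)
  if (is.null(stimuli)) {
    d <- sort(unique(design$duration_s))
    stimuli <- make_stimulus_set(min(d), max(d), length(d))
  }
  fs <- spec$first_stage
  n <- nrow(design)
  if (n == 0L) return(design)
  b <- fs$boundary_ref                      # categorical boundary, seconds
  A <- fs$A
  choice <- character(n); rt <- numeric(n)
  for (i in seq_len(n)) {
    Ti <- design$duration_s[i]
    if (spec$carryover_gain > 0 && !is.na(design$prior_duration_s[i]))
      b <- (1 - spec$carryover_gain) * b +
        spec$carryover_gain * design$prior_duration_s[i]
    n_steps <- max(1L, as.integer(round(Ti / spec$dt)))
    Td <- n_steps * spec$dt
    x <- A * Td + fs$m * sqrt(A * Td) * stats::rnorm(1)
    z <- min(max(0.5 + spec$kappa * (x - 1), spec$z_clip[1]), spec$z_clip[2])
    v <- spec$v_gain * (x - b / fs$boundary_ref)
    a <- spec$a_fun(Ti, stimuli)
    t0 <- spec$t0_fun(Ti, stimuli)
    sim <- ddm_sim_cpp(1L, a, v, t0, z, spec$dt, 20)
    choice[i] <- if (sim$upper == 1L) "long" else "short"
    rt[i] <- sim$t + spec$rt_floor
    if (spec$learning_rate > 0) {
      x_ref <- A * fs$boundary_ref +
        fs$m * sqrt(A * fs$boundary_ref) * stats::rnorm(1)
      A <- A + spec$learning_rate * (1 - x_ref)
    }
  }
  design$choice <- choice
  design$rt_s <- rt
  design
}

#' Simulate a multi-subject bisection experiment
#'
#' Convenience wrapper that draws one counterbalanced sequence per subject
#' and simulates choices/RTs from a shared generative specification, with
#' optional between-subject jitter of the categorical boundary.
#'
#' @param n_subjects number of subjects.
#' @param stimuli a \code{stimulus_set}.
#' @param spec a \code{generative_spec}.
#' @param reps_per_transition transitions per ordered pair (8 gives the
#'   standard 448-stimulus-trial session).
#' @param boundary_sd between-subject SD of the criterion duration, seconds.
#' @param seed integer seed.
#' @return a trial table with an additional \code{subject} column.
#' @export
simulate_experiment <- function(n_subjects = 19, stimuli = make_stimulus_set(),
                                spec = generative_spec(),
                                reps_per_transition = 8,
                                boundary_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sq <- generate_sequence(stimuli$n_levels, reps_per_transition)
    tab <- annotate_transitions(sq, stimuli)
    sp <- spec
    if (boundary_sd > 0) {
      fs <- sp$first_stage
      bref <- fs$boundary_ref + stats::rnorm(1, 0, boundary_sd)
      sp$first_stage <- first_stage_params(boundary_ref = bref, m = fs$m)
    }
    tab <- simulate_bisection(tab, sp, stimuli)
    tab$subject <- s
    out[[s]] <- tab
  }
  do.call(rbind, out)
}
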