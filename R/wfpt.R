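#' Wiener first-passage time density
#'
#' Defective first-passage density of the decision diffusion (unit diffusion
#' coefficient, boundaries 0 = "short" and a = "long", start z * a, drift v)
#' at the named boundary, evaluated at total response time \code{t}
#' (non-decision time \code{t0} is subtracted internally; the density is 0
#' for \code{t <= t0}). The density combines the small-time and large-time
#' series expansions, truncated so the absolute error of the normalized
#' density is below \code{err}. With \code{sz > 0} the density is averaged
#' over a uniform starting-point range of width \code{sz} by 11-point
#' Gauss--Legendre quadrature. Integrating both boundary densities over all
#' times yields 1.
#'
#' @param t response times, seconds.
#' @param boundary \code{"long"} (upper) or \code{"short"} (lower); recycled.
#' @param params a \code{\link{ddm_params}} object (fields recycled over
#'   \code{t}).
#' @param err absolute truncation tolerance of the series.
#' @return numeric vector of densities (1/seconds).
#' @export
wfpt_density <- function(t, boundary = "long", params, err = 1e-10) {
  stopifnot(inherits(params, "ddm_params"))
  upper <- boundary_is_upper(boundary)
  wfpt_d_cpp(as.numeric(t), upper, params$a, params$v, params$t0,
             params$z, params$sz, err)
}

boundary_is_upper <- function(boundary) {
  if (is.logical(boundary)) return(boundary)
  up <- boundary %in% c("long", "upper")
  lo <- boundary %in% c("short", "lower")
  if (!all(up | lo)) stop("boundary must be 'short'/'long'", call. = FALSE)
  up
}

#' Probability mass absorbed at each boundary, by numerical integration
#'
#' Mainly a validation helper: integrates \code{\link{wfpt_density}} over
#' \code{(t0, upper)} for both boundaries.
#'
#' @param params a \code{ddm_params} object (scalar fields).
#' @param err series tolerance.
#' @param upper_t integration horizon in seconds.
#' @return named vector \code{c(short = ..., long = ...)}.
#' @export
wfpt_mass <- function(params, err = 1e-10, upper_t = Inf) {
  f <- function(t, bnd) wfpt_density(t, bnd, params, err)
  lo <- stats::integrate(f, params$t0, upper_t, bnd = "short",
                         rel.tol = 1e-8, abs.tol = 1e-10)$value
  hi <- stats::integrate(f, params$t0, upper_t, bnd = "long",
                         rel.tol = 1e-8, abs.tol = 1e-10)$value
  c(short = lo, long = hi)
}

# build per-trial parameter vectors for a model in which each DDM parameter
# may vary over the levels of one trial-table column ("varies" is a named
# list like list(v = "duration_s", z = "condition")). Returns a list of
# per-trial vectors given the flat parameter vector `theta` and the layout
# from ddm_layout().
ddm_layout <- function(trials, varies = list()) {
  pars <- c("a", "v", "t0", "z", "sz")
  layout <- list()
  for (p in pars) {
    by <- varies[[p]]
    if (is.null(by)) {
      layout[[p]] <- list(levels = NULL, index = rep(1L, nrow(trials)))
    } else {
      f <- factor(trials[[by]])
      layout[[p]] <- list(levels = levels(f), index = as.integer(f))
    }
  }
  n_each <- vapply(layout, function(l) max(l$index), 1L)
  names_flat <- unlist(lapply(pars, function(p) {
    lv <- layout[[p]]$levels
    if (is.null(lv)) p else paste0(p, "[", lv, "]")
  }))
  offsets <- cumsum(c(0L, n_each[-length(n_each)]))
  names(offsets) <- pars
  list(pars = pars, layout = layout, n_each = n_each, offsets = offsets,
       n_theta = sum(n_each), names = names_flat)
}

ddm_expand <- function(theta, lay) {
  out <- list()
  for (p in lay$pars) {
    vals <- theta[lay$offsets[[p]] + seq_len(lay$n_each[[p]])]
    out[[p]] <- vals[lay$layout[[p]]$index]
  }
  out
}

#' Log-likelihood of choices and RTs under the decision diffusion
#'
#' Sum of per-trial log first-passage densities. Parameters may vary over
#' trial-table columns through the \code{varies} specification. Any RT at or
#' below its trial's non-decision time makes the likelihood \code{-Inf}; the
#' offending trial indices are attached as attribute \code{"bad_trials"}.
#'
#' @param trials trial table with \code{choice} and \code{rt_s} filled.
#' @param params a \code{ddm_params} with scalar fields, or a named numeric
#'   vector laid out per \code{varies}.
#' @param varies named list mapping parameter names to trial-table columns
#'   over whose levels they vary (e.g. \code{list(v = "duration_s")}).
#' @param err series tolerance.
#' @return scalar log-likelihood (0 for an empty table).
#' @export
ddm_loglik <- function(trials, params, varies = list(), err = 1e-7) {
  t2 <- trials[!is.na(trials$choice) & !is.na(trials$rt_s), , drop = FALSE]
  if (nrow(t2) == 0L) return(0)
  upper <- t2$choice == "long"
  if (inherits(params, "ddm_params") && length(varies) == 0L) {
    per <- params
  } else {
    lay <- ddm_layout(t2, varies)
    theta <- if (inherits(params, "ddm_params"))
      unlist(params[lay$pars]) else params
    if (length(theta) != lay$n_theta)
      stop("parameter vector has length ", length(theta), ", expected ",
           lay$n_theta, call. = FALSE)
    per <- ddm_expand(theta, lay)
  }
  t0_per <- rep_len(per$t0, nrow(t2))
  bad <- which(t2$rt_s <= t0_per)
  if (length(bad)) {
    out <- -Inf
    attr(out, "bad_trials") <- t2$trial_index[bad]
    return(out)
  }
  wfpt_sumlog_cpp(t2$rt_s, upper, per$a, per$v, per$t0, per$z, per$sz, err)
}
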