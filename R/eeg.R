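#' Specification for synthetic EEG epochs with an implanted duration effect
#'
#' Describes a set of single-trial EEG epochs built as 1/f-shaped Gaussian
#' background noise plus a band-limited oscillation whose single-trial power
#' depends linearly on a per-trial duration regressor (the present or the
#' prior trial's duration) inside a time window. This emulates the empirical
#' signature of interest: beta-band (17--23 Hz) power that scales with the
#' previous trial's duration on top of broadband background activity.
#'
#' @param n_trials number of epochs.
#' @param n_channels number of channels (a frontocentral-like topography
#'   weights the implanted signal across channels; channel 1 carries the
#'   maximum).
#' @param sample_rate sampling rate, Hz.
#' @param epoch_window two-vector (start, end) in seconds relative to
#'   stimulus onset; must straddle 0.
#' @param effect_band two-vector (low, high) in Hz of the implanted
#'   oscillation.
#' @param effect_window two-vector (start, end) seconds of the implanted
#'   effect.
#' @param slope_per_second increase in oscillatory power (amplitude squared,
#'   relative to a baseline power of 1) per second of regressor duration.
#' @param noise_exponent spectral exponent of the 1/f background.
#' @param snr ratio of the oscillation's baseline amplitude to the noise SD.
#' @return object of class \code{eeg_effect_spec}.
#' @export
eeg_effect_spec <- function(n_trials, n_channels = 4, sample_rate = 250,
                            epoch_window = c(-0.4, 1.0),
                            effect_band = c(17, 23),
                            effect_window = c(0.3, 0.9),
                            slope_per_second = 2.0,
                            noise_exponent = 1, snr = 0.8) {
  if (epoch_window[1] >= 0 || epoch_window[2] <= 0)
    stop("epoch_window must straddle stimulus onset (start < 0 < end)",
         call. = FALSE)
  if (effect_window[1] < epoch_window[1] || effect_window[2] > epoch_window[2])
    stop("effect window outside the epoch", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 sample_rate = sample_rate, epoch_window = epoch_window,
                 effect_band = effect_band, effect_window = effect_window,
                 slope_per_second = slope_per_second,
                 noise_exponent = noise_exponent, snr = snr),
            class = "eeg_effect_spec")
}

# one epoch of 1/f^alpha Gaussian noise, unit variance, via spectral shaping
one_over_f_noise <- function(n, alpha) {
  if (alpha == 0) return(stats::rnorm(n))
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]))
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Simulate EEG epochs with a duration-dependent oscillatory effect
#'
#' Builds channel x time x trial epochs: each trial is independent 1/f noise
#' per channel, plus a Hann-windowed sinusoid at the centre of
#' \code{effect_band} whose power (squared amplitude) grows linearly with
#' the chosen regressor at \code{slope_per_second}. The oscillation is
#' projected across channels with a fixed decreasing topography (stored in
#' the metadata).
#'
#' @param spec an \code{eeg_effect_spec}.
#' @param durations per-trial present durations, seconds (length
#'   \code{n_trials}).
#' @param prior_durations per-trial prior durations (NA allowed).
#' @param regressor which duration drives the implanted power:
#'   \code{"prior"} or \code{"present"}.
#' @param seed integer seed.
#' @return object of class \code{eeg_epochs}: list with \code{data} (channel
#'   x time x trial array), \code{sample_rate}, \code{window}, \code{times},
#'   \code{trial_meta} (data.frame of present/prior durations),
#'   \code{topography}, and the generating \code{spec}.
#' @export
simulate_eeg_epochs <- function(spec, durations, prior_durations = NULL,
                                regressor = c("prior", "present"),
                                seed = NULL) {
  stopifnot(inherits(spec, "eeg_effect_spec"))
  regressor <- match.arg(regressor)
  if (!is.null(seed)) set.seed(seed)
  if (length(durations) != spec$n_trials)
    stop("durations must have length n_trials", call. = FALSE)
  if (is.null(prior_durations))
    prior_durations <- rep(NA_real_, spec$n_trials)
  reg <- if (regressor == "prior") prior_durations else durations
  fs <- spec$sample_rate
  times <- seq(spec$epoch_window[1], spec$epoch_window[2] - 1 / fs, by = 1 / fs)
  nt <- length(times)
  topo <- exp(-(seq_len(spec$n_channels) - 1) / 2)
  f0 <- mean(spec$effect_band)
  in_win <- times >= spec$effect_window[1] & times <= spec$effect_window[2]
  hann <- numeric(nt)
  nw <- sum(in_win)
  hann[in_win] <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nw))
  dat <- array(0, c(spec$n_channels, nt, spec$n_trials))
  for (tr in seq_len(spec$n_trials)) {
    r <- reg[tr]
    pow <- if (is.na(r)) 1 else max(1 + spec$slope_per_second * (r - mean(reg, na.rm = TRUE)), 0.05)
    amp <- spec$snr * sqrt(pow)
    osc <- amp * hann * sin(2 * pi * f0 * times + stats::runif(1, 0, 2 * pi))
    for (chn in seq_len(spec$n_channels)) {
      dat[chn, , tr] <- one_over_f_noise(nt, spec$noise_exponent) +
        topo[chn] * osc
    }
  }
  structure(list(data = dat, sample_rate = fs, window = spec$epoch_window,
                 times = times,
                 trial_meta = data.frame(duration_s = durations,
                                         prior_duration_s = prior_durations),
                 topography = topo, spec = spec),
            class = "eeg_epochs")
}

#' Construct an epochs container from an existing array
#'
#' @param data channel x time x trial numeric array.
#' @param sample_rate Hz.
#' @param window two-vector (start, end) seconds relative to the event.
#' @param trial_meta data.frame with per-trial \code{duration_s} and
#'   \code{prior_duration_s}.
#' @return an \code{eeg_epochs} object.
#' @export
eeg_epochs <- function(data, sample_rate, window, trial_meta = NULL) {
  stopifnot(length(dim(data)) == 3)
  nt <- dim(data)[2]
  times <- seq(window[1], window[2] - 1 / sample_rate, by = 1 / sample_rate)
  if (length(times) != nt)
    stop("time axis length must equal (end - start) * sample_rate",
         call. = FALSE)
  if (!is.null(trial_meta) && nrow(trial_meta) != dim(data)[3])
    stop("trial_meta must have one row per trial", call. = FALSE)
  structure(list(data = data, sample_rate = sample_rate, window = window,
                 times = times, trial_meta = trial_meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EEG epochs: %d channel(s) x %d samples x %d trials @ %g Hz, window [%g, %g] s\n",
              d[1], d[2], d[3], x$sample_rate, x$window[1], x$window[2]))
  invisible(x)
}

#' Morlet wavelet time/frequency decomposition
#'
#' Convolves one channel of epoched data with complex Morlet wavelets and
#' returns single-trial power (squared magnitude). Frequencies default to
#' 100 log-spaced values from 10 to 40 Hz. The wavelet cycle count grows
#' with frequency following the two-parameter convention
#' \code{cycles(f) = c0 + s * (c0 * f / f_min - c0)}: at the lowest
#' frequency the wavelet has \code{c0} cycles, and the scaling factor
#' \code{s} in [0, 1] interpolates between constant cycles (s = 0) and
#' cycles proportional to frequency (s = 1). Time points whose wavelet
#' support (3 temporal SDs) extends past the epoch edge are flagged in the
#' \code{valid} mask.
#'
#' @param epochs an \code{eeg_epochs} object.
#' @param freqs analysis frequencies in Hz.
#' @param cycles_base cycles at the lowest frequency (c0).
#' @param scaling cycle-expansion factor (s).
#' @param channel channel index to decompose.
#' @return object of class \code{tf_map}: \code{power} (frequency x time x
#'   trial array), \code{freqs}, \code{times}, \code{valid} (frequency x
#'   time logical), \code{baseline_mode} ("none") and the epoch metadata.
#' @export
morlet_tf <- function(epochs, freqs = exp(seq(log(10), log(40),
                                              length.out = 100)),
                      cycles_base = 3, scaling = 0.5, channel = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$sample_rate
  x <- epochs$data[channel, , , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  nt <- nrow(x); n_trials <- ncol(x)
  cyc <- cycles_base + scaling * (cycles_base * freqs / min(freqs) - cycles_base)
  sigma_t <- cyc / (2 * pi * freqs)
  if (any(6 * sigma_t > nt / fs)) {
    bad <- freqs[which.max(sigma_t)]
    stop(sprintf("epoch too short for the wavelet at %.2f Hz", bad),
         call. = FALSE)
  }
  nfft <- stats::nextn(nt + as.integer(ceiling(6 * max(sigma_t) * fs)), 2)
  Xf <- stats::mvfft(rbind(x, matrix(0, nfft - nt, n_trials)))
  pow <- array(NA_real_, c(length(freqs), nt, n_trials))
  valid <- matrix(TRUE, length(freqs), nt)
  for (fi in seq_along(freqs)) {
    half <- as.integer(ceiling(3 * sigma_t[fi] * fs))
    tt <- (-half:half) / fs
    w <- exp(2i * pi * freqs[fi] * tt) * exp(-tt^2 / (2 * sigma_t[fi]^2))
    w <- w / sqrt(sum(Mod(w)^2))           # unit-energy normalization
    wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::mvfft(Xf * matrix(wf, nfft, n_trials), inverse = TRUE) / nfft
    # wavelet is centered at sample `half + 1`; align to input samples
    seg <- conv[(half + 1):(half + nt), , drop = FALSE]
    pow[fi, , ] <- Mod(seg)^2
    edge <- seq_len(nt) <= half | seq_len(nt) > nt - half
    valid[fi, edge] <- FALSE
  }
  structure(list(power = pow, freqs = freqs, times = epochs$times,
                 valid = valid, baseline_mode = "none",
                 trial_meta = epochs$trial_meta, channel = channel,
                 cycles_base = cycles_base, scaling = scaling),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("Time/frequency map: %d freqs (%.1f-%.1f Hz) x %d times x %d trials, baseline: %s\n",
              d[1], min(x$freqs), max(x$freqs), d[2], d[3], x$baseline_mode))
  invisible(x)
}

#' Single-trial baseline division
#'
#' Divides each trial's power, per frequency, by that trial's mean power in
#' the baseline window. Dividing per trial (rather than by the trial-average
#' baseline) reduces the leverage of occasional extreme-power trials. Trials
#' with zero baseline power at any frequency are excluded with a warning.
#'
#' @param tf a per-trial \code{tf_map}.
#' @param window baseline window in seconds (default -200 ms to onset).
#' @return the \code{tf_map} with normalized power and
#'   \code{baseline_mode = "single_trial_division"}.
#' @export
baseline_divide <- function(tf, window = c(-0.200, 0)) {
  stopifnot(inherits(tf, "tf_map"))
  sel <- tf$times >= window[1] & tf$times <= window[2]
  if (!any(sel)) stop("baseline window outside the epoch", call. = FALSE)
  nfr <- dim(tf$power)[1]; ntr <- dim(tf$power)[3]
  base <- apply(tf$power[, sel, , drop = FALSE], c(1, 3), mean)
  bad <- which(apply(base, 2, function(b) any(b <= 0 | !is.finite(b))))
  if (length(bad)) {
    warning(sprintf("%d trial(s) with zero baseline power excluded",
                    length(bad)))
    tf$power <- tf$power[, , -bad, drop = FALSE]
    tf$trial_meta <- tf$trial_meta[-bad, , drop = FALSE]
    base <- base[, -bad, drop = FALSE]
    ntr <- ntr - length(bad)
  }
  for (tr in seq_len(ntr))
    tf$power[, , tr] <- tf$power[, , tr] / base[, tr]
  tf$baseline_mode <- "single_trial_division"
  tf
}

#' Per-pixel regression of spectral power on stimulus duration
#'
#' Ordinary least-squares slope of single-trial power on the present
#' ("direct effect") or prior ("carryover effect") trial duration at every
#' time/frequency point. For the carryover regressor, trials without a
#' usable prior duration (first trial, post-null) are excluded.
#'
#' @param tf a per-trial \code{tf_map}.
#' @param regressor \code{"present"} or \code{"prior"}.
#' @return a frequency x time matrix of slopes (power units per second),
#'   with the frequency/time axes and regressor attached as attributes.
#' @export
duration_regression <- function(tf, regressor = c("present", "prior")) {
  stopifnot(inherits(tf, "tf_map"))
  regressor <- match.arg(regressor)
  r <- if (regressor == "prior") tf$trial_meta$prior_duration_s
       else tf$trial_meta$duration_s
  keep <- !is.na(r)
  r <- r[keep]
  if (length(unique(r)) < 3)
    stop("need at least 3 distinct regressor values", call. = FALSE)
  p <- tf$power[, , keep, drop = FALSE]
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], d[3])
  rc <- r - mean(r)
  slope <- (pm %*% rc) / sum(rc^2)
  out <- matrix(slope, d[1], d[2])
  attr(out, "freqs") <- tf$freqs
  attr(out, "times") <- tf$times
  attr(out, "regressor") <- regressor
  attr(out, "valid") <- tf$valid
  out
}

#' Per-subject difference maps for a paired condition contrast
#'
#' @param maps_a,maps_b frequency x time x subject arrays (or lists of
#'   matrices) with matched subject order.
#' @return frequency x time x subject array of A - B differences.
#' @export
condition_contrast <- function(maps_a, maps_b) {
  a <- maps_to_array(maps_a); b <- maps_to_array(maps_b)
  if (!all(dim(a) == dim(b)))
    stop("condition maps must share dimensions and subject count",
         call. = FALSE)
  a - b
}

maps_to_array <- function(maps) {
  if (is.list(maps)) maps <- simplify2array(maps)
  if (length(dim(maps)) != 3)
    stop("maps must be a frequency x time x subject array", call. = FALSE)
  maps
}

#' Cluster-based permutation test on time/frequency maps
#'
#' Family-wise-error-controlled inference for per-subject statistic maps:
#' pixelwise one-sample t statistics (versus zero) are thresholded two-tailed
#' at \code{cluster_forming_p}, thresholded pixels are grouped into
#' 8-connected clusters in the frequency x time plane, and each cluster's
#' statistic (pixel count by default, summed |t| mass optionally) is
#' compared to the permutation null of the maximum cluster statistic
#' obtained by randomly sign-flipping each subject's map. Positive and
#' negative clusters are pooled into one maximum-statistic null. A paired
#' design is run by passing per-subject difference maps (see
#' \code{\link{condition_contrast}}); sign-flipping the differences is
#' exactly the condition-label swap.
#'
#' @param maps frequency x time x subject array (or list of matrices) of
#'   per-subject statistic maps (e.g. regression slopes).
#' @param n_perm number of permutations.
#' @param alpha cluster significance level.
#' @param cluster_forming_p two-tailed pixelwise threshold p.
#' @param statistic \code{"size"} (pixel count) or \code{"mass"}
#'   (sum of |t|).
#' @param seed integer seed for the permutation RNG.
#' @return object of class \code{cluster_result}: \code{stat_map} (t values),
#'   \code{labels} (cluster id per pixel, 0 = background),
#'   \code{clusters} (data.frame: id, sign, size, mass, p), \code{null_max}
#'   (permutation distribution), plus the settings.
#' @export
cluster_permutation <- function(maps, n_perm = 2000, alpha = 0.05,
                                cluster_forming_p = 0.05,
                                statistic = c("size", "mass"), seed = NULL) {
  statistic <- match.arg(statistic)
  x <- maps_to_array(maps)
  ns <- dim(x)[3]
  if (ns < 2) stop("need at least 2 subjects", call. = FALSE)
  if (n_perm < 1 / alpha)
    warning("n_perm is too small to resolve alpha")
  if (!is.null(seed)) set.seed(seed)
  tcrit <- stats::qt(1 - cluster_forming_p / 2, df = ns - 1)
  nfr <- dim(x)[1]; ntm <- dim(x)[2]
  xm <- matrix(x, nfr * ntm, ns)

  tmap_of <- function(m) {
    mu <- rowMeans(m)
    sd <- sqrt((rowSums(m^2) - ns * mu^2) / (ns - 1))
    tv <- mu / (sd / sqrt(ns))
    tv[!is.finite(tv)] <- 0
    tv
  }
  max_clust <- function(tv) {
    stat_max <- 0
    for (sgn in c(1, -1)) {
      mask <- matrix(sgn * tv > tcrit, nfr, ntm)
      if (!any(mask)) next
      lab <- label_clusters_cpp(mask)
      if (max(lab) == 0) next
      st <- if (statistic == "size") tabulate(lab[lab > 0])
            else as.numeric(tapply(abs(tv)[lab > 0], lab[lab > 0], sum))
      stat_max <- max(stat_max, st)
    }
    stat_max
  }

  t_obs <- tmap_of(xm)
  tmat <- matrix(t_obs, nfr, ntm)

  # observed clusters, both signs
  clusters <- NULL
  labels <- matrix(0L, nfr, ntm)
  next_id <- 0L
  for (sgn in c(1, -1)) {
    mask <- tmat * sgn > tcrit
    lab <- label_clusters_cpp(mask)
    k <- max(lab)
    if (k == 0) next
    for (cid in seq_len(k)) {
      sel <- lab == cid
      next_id <- next_id + 1L
      labels[sel] <- next_id
      clusters <- rbind(clusters, data.frame(
        id = next_id, sign = sgn, size = sum(sel),
        mass = sum(abs(tmat[sel])), p = NA_real_))
    }
  }

  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), ns, replace = TRUE)
    null_max[b] <- max_clust(tmap_of(xm * rep(flips, each = nfr * ntm)))
  }
  if (!is.null(clusters)) {
    obs_stat <- if (statistic == "size") clusters$size else clusters$mass
    clusters$p <- vapply(obs_stat, function(s)
      (1 + sum(null_max >= s)) / (n_perm + 1), 0)
    clusters <- clusters[order(clusters$p), , drop = FALSE]
  } else {
    clusters <- data.frame(id = integer(0), sign = numeric(0),
                           size = integer(0), mass = numeric(0),
                           p = numeric(0))
  }
  structure(list(stat_map = tmat, labels = labels, clusters = clusters,
                 null_max = null_max, n_permutations = n_perm,
                 alpha = alpha, cluster_forming_p = cluster_forming_p,
                 statistic = statistic, n_subjects = ns),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d subjects, %d permutations, statistic = %s\n",
              x$n_subjects, x$n_permutations, x$statistic))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    sig <- x$clusters$p < x$alpha
    cat(sprintf("  %d cluster(s), %d significant at alpha = %g\n",
                nrow(x$clusters), sum(sig), x$alpha))
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' Significant-cluster summary with frequency/time extents
#'
#' @param result a \code{cluster_result}.
#' @param freqs,times axes matching the map grid.
#' @param alpha significance level (defaults to the test's).
#' @return data.frame: id, sign, size, p, freq_lo, freq_hi, time_lo, time_hi.
#' @export
cluster_report <- function(result, freqs, times, alpha = result$alpha) {
  cl <- result$clusters[result$clusters$p < alpha, , drop = FALSE]
  if (nrow(cl) == 0)
    return(data.frame(id = integer(0), sign = numeric(0), size = integer(0),
                      p = numeric(0), freq_lo = numeric(0),
                      freq_hi = numeric(0), time_lo = numeric(0),
                      time_hi = numeric(0)))
  ext <- lapply(cl$id, function(cid) {
    w <- which(result$labels == cid, arr.ind = TRUE)
    data.frame(freq_lo = min(freqs[w[, 1]]), freq_hi = max(freqs[w[, 1]]),
               time_lo = min(times[w[, 2]]), time_hi = max(times[w[, 2]]))
  })
  cbind(cl[c("id", "sign", "size", "p")], do.call(rbind, ext))
}
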