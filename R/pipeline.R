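#' Default pipeline configuration
#'
#' @param seed global integer seed; every stochastic stage derives its own
#'   seed deterministically from it.
#' @return nested configuration list (serializable to YAML/JSON unchanged).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(t_min = 0.3, t_max = 0.9, n_levels = 7L,
                  reps_per_transition = 8L, include_null = TRUE,
                  lead_in = 3L),
    simulate = list(m = 0.15, kappa = 0.8, v_gain = 8,
                    carryover_gain = 0.3, rt_floor = 0),
    psychometrics = list(rt_lo = 0.1, rt_hi = 1.0, min_per_level = 8L,
                         n_boot = 499L),
    sequential = list(window = 131L, smooth = 10L),
    ddm = list(enabled = FALSE, n_chains = 2L, n_samples = 500L,
               n_burn = 300L),
    eeg = list(enabled = FALSE, n_trials = 120L, n_channels = 2L,
               sample_rate = 250, n_freqs = 40L, n_perm = 500L,
               slope_per_second = 2.0, snr = 0.8),
    format_version = "1.0")
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage seed below 2^31
  offs <- c(design = 101L, simulate = 211L, psychometrics = 307L,
            sequential = 401L, ddm = 503L, eeg = 601L)
  (as.integer(seed) * 7919L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Orchestrates design generation, generative simulation, RT filtering,
#' psychometric fitting, carryover/sliding-window analyses and (optionally)
#' diffusion-model fitting and the EEG time/frequency statistics, writing
#' all outputs plus a machine-readable manifest to \code{out_dir}. Runs are
#' fully deterministic under a fixed global seed: every stage draws its own
#' seed from it.
#'
#' @param config configuration list as from \code{\link{default_config}}, or
#'   a path to a YAML file with the same structure.
#' @param out_dir output directory (created if missing).
#' @return the manifest list, invisibly; side effect: files in
#'   \code{out_dir} (\code{trials.csv}, \code{psychometrics.json},
#'   \code{carryover.csv}, \code{sliding_bp.csv}, optional DDM/EEG
#'   summaries, \code{manifest.json}).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("bisectlab")),
                   seed = config$seed, config = config,
                   completed = character(0), outputs = character(0))
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }

  # design
  dc <- config$design
  stimuli <- make_stimulus_set(dc$t_min, dc$t_max, dc$n_levels)
  sq <- generate_sequence(dc$n_levels, dc$reps_per_transition,
                          dc$include_null,
                          seed = stage_seed(config$seed, "design"))
  design <- annotate_transitions(sq, stimuli, lead_in = dc$lead_in)
  manifest$completed <- c(manifest$completed, "design")

  # simulate behavior
  sc <- config$simulate
  spec <- generative_spec(
    first_stage = first_stage_params(m = sc$m),
    kappa = sc$kappa, v_gain = sc$v_gain,
    carryover_gain = sc$carryover_gain, rt_floor = sc$rt_floor)
  trials <- simulate_bisection(design, spec, stimuli,
                               seed = stage_seed(config$seed, "simulate"))
  trials <- annotate_prior_response(trials)
  write_trial_table(trials, file.path(out_dir, "trials.csv"))
  manifest$completed <- c(manifest$completed, "simulate")
  manifest$outputs <- c(manifest$outputs, "trials.csv")

  # psychometrics
  pc <- config$psychometrics
  filtered <- filter_rt(trials, pc$rt_lo, pc$rt_hi, quiet = TRUE)
  fit <- fit_gumbel(filtered, min_per_level = pc$min_per_level)
  if (fit$converged)
    fit <- thresholds_bootstrap(fit, n_boot = pc$n_boot,
                                seed = stage_seed(config$seed, "psychometrics"))
  chron <- chronometric(filtered)
  psy <- list(bp = fit$bp, dl = fit$dl, cv = fit$cv,
              theta25 = fit$theta25, theta75 = fit$theta75,
              converged = fit$converged,
              n_trials_removed = attr(filtered, "n_removed"),
              boot_ci = if (!is.null(fit$boot_ci))
                as.data.frame(unclass(fit$boot_ci)),
              chronometric = chron)
  jsonlite::write_json(psy, file.path(out_dir, "psychometrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$completed <- c(manifest$completed, "psychometrics")
  manifest$outputs <- c(manifest$outputs, "psychometrics.json")

  # sequential analyses
  qc <- config$sequential
  co <- suppressWarnings(carryover_bp(filtered))
  utils::write.csv(co$bp_by_prior, file.path(out_dir, "carryover.csv"),
                   row.names = FALSE)
  sl <- sliding_bp(filtered, window = min(qc$window, nrow(filtered)),
                   smooth = qc$smooth)
  utils::write.csv(as.data.frame(sl), file.path(out_dir, "sliding_bp.csv"),
                   row.names = FALSE)
  manifest$completed <- c(manifest$completed, "sequential")
  manifest$outputs <- c(manifest$outputs, "carryover.csv", "sliding_bp.csv")
  manifest$carryover_slope <- co$slope

  # optional DDM stage
  if (isTRUE(config$ddm$enabled)) {
    trials$subject <- 1L
    mle <- fit_ddm_mle(filtered_with_subject(filtered))
    utils::write.csv(mle, file.path(out_dir, "ddm_mle.csv"),
                     row.names = FALSE)
    manifest$completed <- c(manifest$completed, "ddm")
    manifest$outputs <- c(manifest$outputs, "ddm_mle.csv")
  }

  # optional EEG stage
  if (isTRUE(config$eeg$enabled)) {
    ec <- config$eeg
    nt <- min(ec$n_trials, nrow(filtered))
    sub <- filtered[seq_len(nt), , drop = FALSE]
    espec <- eeg_effect_spec(n_trials = nt, n_channels = ec$n_channels,
                             sample_rate = ec$sample_rate,
                             slope_per_second = ec$slope_per_second,
                             snr = ec$snr)
    ep <- simulate_eeg_epochs(espec, sub$duration_s, sub$prior_duration_s,
                              regressor = "prior",
                              seed = stage_seed(config$seed, "eeg"))
    freqs <- exp(seq(log(10), log(40), length.out = ec$n_freqs))
    tf <- morlet_tf(ep, freqs = freqs)
    slope <- duration_regression(tf, "prior")
    utils::write.csv(
      data.frame(freq_hz = freqs,
                 mean_slope = rowMeans(slope)),
      file.path(out_dir, "eeg_slope_by_freq.csv"), row.names = FALSE)
    manifest$completed <- c(manifest$completed, "eeg")
    manifest$outputs <- c(manifest$outputs, "eeg_slope_by_freq.csv")
  }
  finish()
}

filtered_with_subject <- function(trials) {
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  trials
}

#' Validate a trial table against the schema
#'
#' Column presence, type, and range checks for the CSV trial-table dialect:
#' durations must come from the declared stimulus set (when given), choices
#' from \{short, long\}, RTs must be non-negative.
#'
#' @param x a data.frame or a path to a trial-table CSV.
#' @param durations optional vector of admissible durations (seconds).
#' @return data.frame of violations (zero rows when valid) with columns
#'   \code{row} (NA for table-level problems), \code{column},
#'   \code{problem}.
#' @export
validate_trial_table <- function(x, durations = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("cannot read file: ", x, call. = FALSE)
    x <- read_trial_table(x)
  }
  v <- list()
  need <- c("trial_index", "duration_s", "prior_duration_s",
            "prior_was_null", "session", "phase", "choice", "rt_s")
  missing_cols <- setdiff(need, names(x))
  for (mc in missing_cols)
    v[[length(v) + 1L]] <- data.frame(row = NA_integer_, column = mc,
                                      problem = "missing column")
  if (length(missing_cols) == 0) {
    bad_rt <- which(!is.na(x$rt_s) & x$rt_s < 0)
    for (r in bad_rt)
      v[[length(v) + 1L]] <- data.frame(row = r, column = "rt_s",
                                        problem = "negative RT")
    bad_choice <- which(!is.na(x$choice) & !x$choice %in% c("short", "long"))
    for (r in bad_choice)
      v[[length(v) + 1L]] <- data.frame(row = r, column = "choice",
                                        problem = "unknown choice label")
    if (!is.null(durations)) {
      ok <- vapply(x$duration_s, function(d)
        any(abs(d - durations) < 1e-9), TRUE)
      for (r in which(!ok))
        v[[length(v) + 1L]] <- data.frame(row = r, column = "duration_s",
                                          problem = "duration not in stimulus set")
    }
  }
  if (length(v) == 0)
    data.frame(row = integer(0), column = character(0),
               problem = character(0))
  else do.call(rbind, v)
}
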