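# shared fixtures, all generated in code

# minimal trial table wrapping simulated decision-stage choices/RTs
ddm_trial_table <- function(params, n, subject = 1L, phase = "baseline",
                            duration = 0.52) {
  sim <- simulate_decision(params, n = n)
  data.frame(trial_index = seq_len(n), duration_s = duration,
             prior_duration_s = NA_real_, prior_was_null = FALSE,
             session = "alpha", phase = phase,
             choice = sim$choice, rt_s = sim$rt, subject = subject,
             stringsAsFactors = FALSE)
}

# one simulated counterbalanced bisection session
sim_session <- function(spec = generative_spec(), seed = NULL,
                        stimuli = make_stimulus_set(), reps = 8) {
  if (!is.null(seed)) set.seed(seed)
  sq <- generate_sequence(stimuli$n_levels, reps, include_null = TRUE)
  simulate_bisection(annotate_transitions(sq, stimuli), spec, stimuli)
}

# hand-built trial sequence (for annotation edge cases)
manual_sequence <- function(labels) {
  alphabet <- unique(labels)
  structure(list(labels = labels,
                 n_duration_labels = sum(alphabet != "NULL"),
                 include_null = "NULL" %in% alphabet,
                 reps_per_transition = NA_integer_,
                 transition_counts = transition_counts(labels, alphabet)),
            class = "trial_sequence")
}

# cumulative Gumbel on log duration; used to generate binomial test data
gumbel_p <- function(d, alpha_log, beta) 1 - exp(-exp((log(d) - alpha_log) / beta))
gumbel_q <- function(p, alpha_log, beta) exp(alpha_log + beta * log(-log(1 - p)))
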