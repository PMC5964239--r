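#' Generate a first-order counterbalanced trial sequence
#'
#' Produces a trial order in which every ordered pair of labels (including
#' repeats, and optionally a NULL "no stimulus" label) occurs exactly
#' \code{reps_per_transition} times when the sequence is read cyclically.
#' The sequence is a random Eulerian circuit of the complete transition
#' multigraph (Hierholzer's algorithm with seeded random edge choice), cut at
#' a random position, so trial-history analyses see every duration-to-duration
#' transition equally often. With 7 duration labels plus NULL and 8
#' repetitions this yields the canonical 512-trial session: 448 stimulus
#' trials, 64 null trials, 64 presentations of each duration, and all 64
#' ordered trial types 8 times each.
#'
#' @param n_duration_labels number of stimulus duration labels (d1, d2, ...).
#' @param reps_per_transition number of times each ordered label pair occurs.
#' @param include_null add a NULL label (blank trial) to the alphabet?
#' @param seed optional integer seed; when supplied the R RNG is seeded before
#'   the circuit is drawn so the realization is reproducible.
#' @return An object of class \code{trial_sequence}: list with \code{labels}
#'   (character vector, cyclic order; NULL trials are \code{"NULL"}),
#'   \code{n_duration_labels}, \code{include_null},
#'   \code{reps_per_transition} and \code{transition_counts} (square matrix of
#'   cyclic ordered-pair counts).
#' @examples
#' s <- generate_sequence(7, 8, include_null = TRUE, seed = 1)
#' length(s$labels)                 # 512
#' sum(s$labels != "NULL")          # 448
#' all(s$transition_counts == 8)    # TRUE
#' @export
generate_sequence <- function(n_duration_labels = 7, reps_per_transition = 8,
                              include_null = TRUE, seed = NULL) {
  if (n_duration_labels < 1) stop("need at least one duration label", call. = FALSE)
  if (reps_per_transition < 1) stop("reps_per_transition must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labs <- paste0("d", seq_len(n_duration_labels))
  if (include_null) labs <- c(labs, "NULL")
  k <- length(labs)
  cnt <- matrix(as.integer(reps_per_transition), k, k)
  n_arcs <- sum(cnt)

  # Hierholzer: walk consuming arcs, backtracking when a node has no exits.
  # The graph is connected and every node has equal in/out degree, so an
  # Eulerian circuit always exists.
  stack <- integer(n_arcs + 1L)
  circuit <- integer(n_arcs + 1L)
  sp <- 1L; cp <- 0L
  stack[1L] <- sample.int(k, 1L)
  while (sp > 0L) {
    v <- stack[sp]
    row <- cnt[v, ]
    if (any(row > 0L)) {
      j <- sample.int(k, 1L, prob = row)
      cnt[v, j] <- cnt[v, j] - 1L
      sp <- sp + 1L
      stack[sp] <- j
    } else {
      cp <- cp + 1L
      circuit[cp] <- v
      sp <- sp - 1L
    }
  }
  nodes <- rev(circuit[seq_len(cp)])
  nodes <- nodes[-length(nodes)]            # first == last; drop the repeat
  cut <- sample.int(length(nodes), 1L)      # random cyclic cut
  nodes <- c(nodes[cut:length(nodes)], if (cut > 1L) nodes[seq_len(cut - 1L)])

  seq_labels <- labs[nodes]
  tc <- transition_counts(seq_labels, labs, cyclic = TRUE)
  structure(
    list(labels = seq_labels,
         n_duration_labels = as.integer(n_duration_labels),
         include_null = include_null,
         reps_per_transition = as.integer(reps_per_transition),
         transition_counts = tc),
    class = "trial_sequence")
}

#' Count ordered label transitions in a sequence
#'
#' @param labels character vector of trial labels.
#' @param alphabet label universe defining the matrix order; defaults to the
#'   sorted unique labels.
#' @param cyclic include the wrap-around transition from last to first trial?
#' @return integer matrix of counts, rows = "from", columns = "to".
#' @export
transition_counts <- function(labels, alphabet = sort(unique(labels)),
                              cyclic = TRUE) {
  if (length(labels) == 0L)
    return(matrix(integer(0), 0, 0))
  from <- labels
  to <- c(labels[-1L], if (cyclic) labels[1L])
  if (!cyclic) from <- from[-length(from)]
  tab <- table(factor(from, levels = alphabet), factor(to, levels = alphabet))
  m <- matrix(as.integer(tab), nrow = length(alphabet),
              dimnames = list(from = alphabet, to = alphabet))
  m
}

#' @export
print.trial_sequence <- function(x, ...) {
  n_null <- sum(x$labels == "NULL")
  cat(sprintf(
    "Counterbalanced trial sequence: %d trials (%d stimulus, %d null)\n",
    length(x$labels), length(x$labels) - n_null, n_null))
  cat(sprintf("  %d labels, every ordered transition %d times (cyclic)\n",
              nrow(x$transition_counts), x$reps_per_transition))
  invisible(x)
}

#' Expand a trial sequence into an annotated trial table
#'
#' Maps sequence labels onto stimulus durations and annotates each stimulus
#' trial with the duration of its predecessor, the raw material of all
#' trial-history (carryover) analyses. NULL trials are dropped from the
#' returned table, but a trial immediately following one keeps the flag
#' \code{prior_was_null = TRUE} and a missing \code{prior_duration_s}, so that
#' carryover conditioning can exclude it while direct analyses retain it.
#' An optional lead-in of presentations at the geometric mean (used to seed
#' the subject's internal standard) is prepended with non-positive trial
#' indices; analysis functions only use \code{trial_index >= 1}.
#'
#' @param sequence a \code{trial_sequence}.
#' @param stimuli a \code{stimulus_set} whose \code{n_levels} matches the
#'   sequence's duration labels.
#' @param session session label (e.g. \code{"alpha"} or \code{"beta"}).
#' @param phase phase label (e.g. \code{"baseline"} or \code{"stimulation"}).
#' @param lead_in number of geometric-mean lead-in presentations to prepend.
#' @return A data.frame (the trial table) with columns \code{trial_index},
#'   \code{duration_s}, \code{prior_duration_s}, \code{prior_was_null},
#'   \code{session}, \code{phase}, \code{choice}, \code{rt_s}. Choice and RT
#'   are \code{NA} until filled by a simulator or real data.
#' @export
annotate_transitions <- function(sequence, stimuli,
                                 session = "alpha", phase = "baseline",
                                 lead_in = 0L) {
  stopifnot(inherits(sequence, "trial_sequence"),
            inherits(stimuli, "stimulus_set"))
  labs <- sequence$labels
  if (length(labs) == 0L) return(empty_trial_table())
  dur_labs <- setdiff(unique(labs), "NULL")
  known <- paste0("d", seq_len(stimuli$n_levels))
  if (!all(dur_labs %in% known))
    stop("sequence contains labels not in the stimulus set: ",
         paste(setdiff(dur_labs, known), collapse = ", "), call. = FALSE)
  idx <- match(labs, known)                      # NA for NULL
  dur <- stimuli$durations[idx]
  prior <- c(NA_real_, dur[-length(dur)])
  prior_null <- c(FALSE, labs[-length(labs)] == "NULL")
  keep <- labs != "NULL"
  out <- data.frame(
    trial_index = seq_len(sum(keep)),
    duration_s = dur[keep],
    prior_duration_s = ifelse(prior_null[keep], NA_real_, prior[keep]),
    prior_was_null = prior_null[keep],
    session = session, phase = phase,
    choice = NA_character_, rt_s = NA_real_,
    stringsAsFactors = FALSE)
  if (lead_in > 0L) {
    li <- data.frame(
      trial_index = seq.int(-lead_in + 1L, 0L),
      duration_s = stimuli$geometric_mean,
      prior_duration_s = NA_real_, prior_was_null = FALSE,
      session = session, phase = phase,
      choice = NA_character_, rt_s = NA_real_,
      stringsAsFactors = FALSE)
    out <- rbind(li, out)
  }
  out
}

empty_trial_table <- function() {
  data.frame(trial_index = integer(0), duration_s = numeric(0),
             prior_duration_s = numeric(0), prior_was_null = logical(0),
             session = character(0), phase = character(0),
             choice = character(0), rt_s = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read / write the trial-table CSV dialect
#'
#' UTF-8 CSV with header \code{trial_index, duration_s, prior_duration_s,
#' prior_was_null, session, phase, choice, rt_s}; missing values are written
#' as empty fields.
#'
#' @param trials a trial table data.frame.
#' @param path file path.
#' @return \code{read_trial_table} returns the trial table data.frame;
#'   \code{write_trial_table} returns \code{path} invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(trial_index = "integer",
                                        duration_s = "numeric",
                                        prior_duration_s = "numeric",
                                        prior_was_null = "logical",
                                        session = "character",
                                        phase = "character",
                                        choice = "character",
                                        rt_s = "numeric"))
  out$choice[!is.na(out$choice) & out$choice == ""] <- NA_character_
  out
}
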