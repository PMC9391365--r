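#' Construct a single neurofeedback run
#'
#' A run is an alternating sequence of REST and IMAGINE_REWARD blocks on a
#' fixed TR grid, optionally preceded by a lead-in period that carries no
#' condition. The default geometry (10 lead-in volumes, nine 20 s block pairs
#' at TR 2 s) gives 190 volumes per run; the first five lead-in volumes are
#' treated as a nuisance period by the first-level GLM. Runs always start with
#' REST so that a complete REST tail is available before the first
#' IMAGINE_REWARD block needs a feedback reference.
#'
#' @param run_type one of "baseline", "training1", "training2", "transfer".
#' @param polarity feedback polarity; "none" for runs without feedback,
#'   otherwise "standard" or "inverted". Feedback is enabled exactly for the
#'   training runs.
#' @param tr repetition time in seconds.
#' @param n_block_pairs number of REST + IMAGINE_REWARD block pairs.
#' @param block_duration duration of each block in seconds; must be a positive
#'   multiple of `tr`.
#' @param lead_in_volumes number of unlabelled volumes before the first block.
#' @return an object of class `nf_run`: a list with fields `run_type`, `tr`,
#'   `n_volumes`, `blocks` (data.frame: condition, onset, duration),
#'   `feedback_enabled`, `polarity`.
#' @examples
#' run <- nf_run("baseline")
#' run$n_volumes  # 190
#' @export
nf_run <- function(run_type = c("baseline", "training1", "training2", "transfer"),
                   polarity = "none", tr = 2, n_block_pairs = 9,
                   block_duration = 20, lead_in_volumes = 10) {
  run_type <- match.arg(run_type)
  stopifnot(tr > 0, n_block_pairs >= 1, lead_in_volumes >= 0)
  if (block_duration <= 0 || abs(block_duration / tr - round(block_duration / tr)) > 1e-9)
    stop("block duration must be a positive multiple of tr")
  is_training <- run_type %in% c("training1", "training2")
  if (is_training && !polarity %in% c("standard", "inverted"))
    stop("training runs need polarity 'standard' or 'inverted'")
  if (!is_training && polarity != "none")
    stop("polarity must be 'none' for runs without feedback")

  lead_in <- lead_in_volumes * tr
  onsets <- lead_in + block_duration * seq(0, 2 * n_block_pairs - 1)
  blocks <- data.frame(
    condition = rep(c("REST", "IMAGINE_REWARD"), n_block_pairs),
    onset = onsets,
    duration = block_duration,
    stringsAsFactors = FALSE
  )
  total <- lead_in + 2 * n_block_pairs * block_duration
  structure(
    list(run_type = run_type, tr = tr, n_volumes = as.integer(round(total / tr)),
         blocks = blocks, feedback_enabled = is_training, polarity = polarity),
    class = "nf_run"
  )
}

validate_run <- function(run) {
  b <- run$blocks
  stopifnot(all(b$duration > 0), !is.unsorted(b$onset, strictly = TRUE))
  if (any(b$onset[-1] < (b$onset + b$duration)[-nrow(b)]))
    stop("blocks overlap")
  covered <- max(b$onset + b$duration)
  if (abs(run$n_volumes * run$tr - covered) > 1e-9)
    stop("n_volumes * tr does not match the covered duration")
  if (run$feedback_enabled != run$run_type %in% c("training1", "training2"))
    stop("feedback_enabled inconsistent with run_type")
  invisible(run)
}

#' Construct a full neurofeedback session design
#'
#' A session is one baseline run, two training runs carrying the arm's
#' feedback polarity, and one transfer run. Baseline and transfer never carry
#' feedback: the transfer-versus-baseline comparison that defines the degree
#' of regulation transfer requires both runs to be feedback-free.
#'
#' @param subject_id subject identifier.
#' @param arm feedback arm, "standard" or "inverted".
#' @param study_id cohort label stored with the design (used as the group-level
#'   study covariate).
#' @param tr,n_block_pairs,block_duration,lead_in_volumes run geometry, passed
#'   to [nf_run()].
#' @return an object of class `nf_session`: list with `subject_id`, `arm`,
#'   `study_id` and `runs` (named list of `nf_run`).
#' @examples
#' des <- nf_session("sub-01", arm = "standard")
#' vapply(des$runs, function(r) r$n_volumes, integer(1))
#' @export
nf_session <- function(subject_id = "sub-01", arm = c("standard", "inverted"),
                       study_id = "study2", tr = 2, n_block_pairs = 9,
                       block_duration = 20, lead_in_volumes = 10) {
  arm <- match.arg(arm)
  runs <- list(
    baseline  = nf_run("baseline",  "none", tr, n_block_pairs, block_duration, lead_in_volumes),
    training1 = nf_run("training1", arm,    tr, n_block_pairs, block_duration, lead_in_volumes),
    training2 = nf_run("training2", arm,    tr, n_block_pairs, block_duration, lead_in_volumes),
    transfer  = nf_run("transfer",  "none", tr, n_block_pairs, block_duration, lead_in_volumes)
  )
  ses <- structure(
    list(subject_id = subject_id, arm = arm, study_id = study_id, runs = runs),
    class = "nf_session"
  )
  validate_session(ses)
}

validate_session <- function(ses) {
  stopifnot(ses$arm %in% c("standard", "inverted"))
  types <- vapply(ses$runs, function(r) r$run_type, character(1))
  if (sum(types == "baseline") != 1 || sum(types == "transfer") != 1)
    stop("session needs exactly one baseline and one transfer run")
  for (r in ses$runs) {
    validate_run(r)
    if (r$feedback_enabled && r$polarity != ses$arm)
      stop("training run polarity does not match the session arm")
  }
  invisible(ses)
}

#' @export
print.nf_session <- function(x, ...) {
  cat("Neurofeedback session design\n")
  cat("  subject:", x$subject_id, " arm:", x$arm, " study:", x$study_id, "\n")
  for (r in x$runs)
    cat(sprintf("  %-9s %d volumes, TR %g s, %d blocks, feedback: %s\n",
                r$run_type, r$n_volumes, r$tr, nrow(r$blocks),
                if (r$feedback_enabled) r$polarity else "none"))
  invisible(x)
}

#' Per-volume condition labels for a run
#'
#' Labels each volume with the condition of the block covering the volume's
#' acquisition time minus a hemodynamic shift. Volumes acquired before the
#' first shifted block (the lead-in plus the shift) are labelled `LEAD_IN`.
#' Times are 0-based and block intervals half-open, `[onset, onset + duration)`.
#'
#' @param run an `nf_run`.
#' @param hemodynamic_shift non-negative shift in seconds; must lie on the TR
#'   grid. Shifting by the hemodynamic lag aligns BOLD samples with the
#'   condition that caused them.
#' @return character vector of length `n_volumes` with values `REST`,
#'   `IMAGINE_REWARD` or `LEAD_IN`.
#' @export
labels_per_volume <- function(run, hemodynamic_shift = 0) {
  stopifnot(hemodynamic_shift >= 0)
  if (abs(hemodynamic_shift / run$tr - round(hemodynamic_shift / run$tr)) > 1e-9)
    stop("hemodynamic_shift must be a multiple of tr")
  t <- (seq_len(run$n_volumes) - 1) * run$tr - hemodynamic_shift
  lab <- rep("LEAD_IN", run$n_volumes)
  for (i in seq_len(nrow(run$blocks))) {
    b <- run$blocks[i, ]
    sel <- t >= b$onset & t < b$onset + b$duration
    lab[sel] <- b$condition
  }
  lab
}

#' Generate a randomized monetary incentive delay (MID) trial list
#'
#' Each trial presents one of three cues: large reward (magnitude uniform on
#' 0 to 2.00 CHF), small reward (uniform on 0 to 0.40 CHF) or no reward
#' (magnitude 0). The cue is followed, after a uniform 2.5 to 3 s delay, by the
#' target. Trial order is a seed-deterministic permutation.
#'
#' @param n_per_cue number of trials per cue type.
#' @param seed integer seed driving magnitudes, delays and trial order.
#' @param large_range,small_range magnitude ranges in CHF, `c(min, max)`.
#' @param delay_range cue-to-target delay range in seconds.
#' @param trial_spacing cue-onset-to-cue-onset interval in seconds.
#' @param t0 onset of the first cue in seconds.
#' @return data.frame with columns `cue_type`, `magnitude`, `cue_onset`,
#'   `delay`, `target_onset`, one row per trial in presentation order.
#' @export
mid_trials <- function(n_per_cue = 25, seed = 1,
                       large_range = c(0, 2), small_range = c(0, 0.4),
                       delay_range = c(2.5, 3), trial_spacing = 10, t0 = 10) {
  stopifnot(n_per_cue >= 1, trial_spacing > 0)
  if (diff(large_range) < 0 || diff(small_range) < 0 || diff(delay_range) < 0)
    stop("range limits inverted")
  set.seed(seed)
  n <- 3L * n_per_cue
  cue <- sample(rep(c("large", "small", "none"), n_per_cue))
  mag <- numeric(n)
  mag[cue == "large"] <- stats::runif(n_per_cue, large_range[1], large_range[2])
  mag[cue == "small"] <- stats::runif(n_per_cue, small_range[1], small_range[2])
  delay <- stats::runif(n, delay_range[1], delay_range[2])
  onset <- t0 + trial_spacing * (seq_len(n) - 1)
  data.frame(cue_type = cue, magnitude = mag, cue_onset = onset,
             delay = delay, target_onset = onset + delay,
             stringsAsFactors = FALSE)
}

#' Write and read BIDS-style events tables
#'
#' Events use the conventional columns `onset`, `duration`, `trial_type` and,
#' for MID trials, `magnitude`. Values round-trip exactly through the text
#' representation (full double precision is written).
#'
#' @param events data.frame of events.
#' @param path file path for the tab-separated table.
#' @return `read_events_tsv` returns the events data.frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(format(events, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Serialize a session design to JSON and back
#'
#' @param ses an `nf_session`.
#' @param path JSON file path.
#' @return `read_session_json` returns the reconstructed `nf_session`, equal to
#'   the one written.
#' @export
write_session_json <- function(ses, path) {
  x <- list(subject_id = ses$subject_id, arm = ses$arm, study_id = ses$study_id,
            runs = lapply(ses$runs, function(r) {
              list(run_type = r$run_type, tr = r$tr, n_volumes = r$n_volumes,
                   feedback_enabled = r$feedback_enabled, polarity = r$polarity,
                   blocks = r$blocks)
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  runs <- lapply(x$runs, function(r) {
    blocks <- as.data.frame(r$blocks)
    blocks$onset <- as.numeric(blocks$onset)
    blocks$duration <- as.numeric(blocks$duration)
    structure(list(run_type = r$run_type, tr = as.numeric(r$tr),
                   n_volumes = as.integer(r$n_volumes),
                   blocks = blocks,
                   feedback_enabled = r$feedback_enabled, polarity = r$polarity),
              class = "nf_run")
  })
  ses <- structure(list(subject_id = x$subject_id, arm = x$arm,
                        study_id = x$study_id, runs = runs),
                   class = "nf_session")
  validate_session(ses)
}
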