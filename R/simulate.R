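#' Ground-truth parameters for one simulated subject
#'
#' Collects everything the generator needs: the learning agent, the mapping
#' from strategy efficacy to midbrain signal, the noise model, the coupling of
#' dlPFC to the midbrain TD signal, and the MID-task gains. All signal
#' amplitudes are in percent-signal-change plateau units (a sustained block of
#' amplitude a settles at a percent above baseline after HRF convolution).
#'
#' @param agent an [agent_params()] object.
#' @param regulation_gain g: midbrain plateau amplitude per unit strategy
#'   efficacy during IMAGINE_REWARD blocks.
#' @param baseline_level raw signal baseline (arbitrary scanner units); the
#'   feedback engine computes percent signal change against (a REST estimate
#'   of) this level.
#' @param efficacy_noise_sd block-to-block jitter of the realized efficacy
#'   (imagery vividness varies from block to block).
#' @param noise list: `ar` AR(1) coefficient, `innovation_sd` innovation
#'   standard deviation, `drift_slope` linear drift over a run (percent),
#'   `physio_amplitudes` and `physio_freqs` of sinusoidal physiological
#'   components (Hz), shared across regions and CSF/WM voxels.
#' @param coupling list: `dlpfc_td_weight_initial` w0 (dlPFC loading on the
#'   midbrain TD trace in training run 1), `dlpfc_td_weight_decay` (fractional
#'   reduction of that loading at full learning progress),
#'   `dlpfc_task_gain` (dlPFC loading on the task boxcar signal), and
#'   `connectivity_modulation` (IMAGINE_REWARD-specific dlPFC-to-midbrain
#'   coupling picked up by the PPI analysis).
#' @param mid list: `general_gain` (response per CHF), `adaptive_gain`
#'   (response per range-normalized magnitude), `cue_gain` (magnitude
#'   independent cue response).
#' @param arm feedback arm the subject is trained in.
#' @param include_amygdala also generate an amygdala series (task-independent
#'   noise, like the control region; no mechanistic model is claimed).
#' @return list of class `subject_params`.
#' @export
subject_params <- function(agent = agent_params(),
                           regulation_gain = 2.5,
                           baseline_level = 100,
                           efficacy_noise_sd = 0.05,
                           noise = list(),
                           coupling = list(),
                           mid = list(),
                           arm = c("standard", "inverted"),
                           include_amygdala = FALSE) {
  arm <- match.arg(arm)
  noise <- utils::modifyList(list(ar = 0.3, innovation_sd = 1.0,
                                  cortical_scale = 0.4,
                                  drift_slope = 0.1,
                                  physio_amplitudes = c(0.15, 0.1),
                                  physio_freqs = c(0.25, 1.0)), noise)
  coupling <- utils::modifyList(list(dlpfc_td_weight_initial = 0.6,
                                     dlpfc_td_weight_decay = 0.9,
                                     dlpfc_task_gain = 0.5,
                                     connectivity_modulation = 0.5), coupling)
  mid <- utils::modifyList(list(general_gain = 1.0, adaptive_gain = 1.0,
                                cue_gain = 0.5), mid)
  stopifnot(regulation_gain >= 0, baseline_level > 0,
            noise$ar >= 0, noise$ar < 1, noise$innovation_sd >= 0,
            length(noise$physio_amplitudes) == length(noise$physio_freqs))
  structure(list(agent = agent, regulation_gain = regulation_gain,
                 baseline_level = baseline_level,
                 efficacy_noise_sd = efficacy_noise_sd,
                 noise = noise, coupling = coupling, mid = mid, arm = arm,
                 include_amygdala = include_amygdala),
            class = "subject_params")
}

ar1_noise <- function(n, phi, innovation_sd) {
  as.numeric(stats::filter(stats::rnorm(n, 0, innovation_sd), phi,
                           method = "recursive"))
}

physio_signal <- function(n, tr, amplitudes, freqs, phases) {
  t <- (seq_len(n) - 1) * tr
  out <- numeric(n)
  for (j in seq_along(amplitudes))
    out <- out + amplitudes[j] * sin(2 * pi * freqs[j] * t + phases[j])
  out
}

#' Simulate one subject's neurofeedback session
#'
#' Runs the session's four runs in order through a closed loop: at every
#' IMAGINE_REWARD block the agent picks a strategy (softmax over its values),
#' the midbrain neural amplitude is set to `regulation_gain` times the realized
#' efficacy, the amplitude train is HRF-convolved and corrupted with AR(1)
#' noise, drift and physiological sinusoids, and - during training runs - the
#' measured midbrain series is streamed through the feedback engine with the
#' arm's polarity. The agent perceives each block's displayed feedback with a
#' 5 s hemodynamic lag and updates the chosen strategy's value after the block.
#'
#' The dlPFC series carries a share of the task signal plus a loading
#' `w_run` on the HRF-convolved midbrain temporal-difference trace;
#' `w_run` declines with learning progress (w2 = w0 (1 - decay * progress),
#' where progress is the fractional decline of the absolute block TD error
#' from the first to the last third of training run 1), so the TD coupling
#' weakens exactly for subjects who learn. During training runs an
#' IMAGINE_REWARD-specific interaction `connectivity_modulation *
#' I(t) * (dlPFC - mean)` is added to the measured midbrain series, the
#' coupling the PPI analysis is built to detect. The parahippocampal control
#' region (and the optional amygdala) carries task-independent noise only.
#'
#' @param params a [subject_params()] object.
#' @param design an [nf_session()]; its arm must match `params$arm`.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param feedback_lag perceived-feedback lag in seconds.
#' @return list of class `nf_subject` with elements `design`, `roi` (per-run
#'   data.frames of region series), `csf_wm` (per-run voxel x time matrices),
#'   `motion` (per-run n x 6 matrices), `feedback` (per-training-run
#'   `fb_trace`), `agent` (choices, block feedback, TD traces, final values,
#'   learning progress, per-run TD weights) and `truth` (the input params).
#' @export
simulate_subject <- function(params, design = nf_session(arm = params$arm),
                             seed = 1, feedback_lag = 5) {
  stopifnot(inherits(params, "subject_params"), inherits(design, "nf_session"))
  if (design$arm != params$arm) stop("design arm does not match subject arm")
  set.seed(seed)

  ag <- params$agent
  values <- if (ag$prior_sd > 0)
    stats::rnorm(ag$n_strategies, 0, ag$prior_sd) else rep(0, ag$n_strategies)
  tried <- rep(FALSE, ag$n_strategies)
  alpha_eff <- ag$learning_rate * ag$contingency
  n_csf_voxels <- 20L

  roi <- list(); csf <- list(); motion <- list(); feedback <- list()
  block_log <- list(); td_traces <- list()
  values_at_run_start <- list(); tried_at_run_start <- list()
  w_runs <- c(training1 = NA_real_, training2 = NA_real_)
  progress <- 0

  for (run_name in names(design$runs)) {
    run <- design$runs[[run_name]]
    values_at_run_start[[run_name]] <- values
    tried_at_run_start[[run_name]] <- tried
    n <- run$n_volumes; tr <- run$tr
    labels <- labels_per_volume(run, 0)
    t_run <- (seq_len(n) - 1) * tr

    phases <- stats::runif(length(params$noise$physio_freqs), 0, 2 * pi)
    physio <- physio_signal(n, tr, params$noise$physio_amplitudes,
                            params$noise$physio_freqs, phases)
    sd_cort <- params$noise$innovation_sd * params$noise$cortical_scale
    noise_sn <- ar1_noise(n, params$noise$ar, params$noise$innovation_sd)
    noise_dl <- ar1_noise(n, params$noise$ar, sd_cort)
    noise_ph <- ar1_noise(n, params$noise$ar, sd_cort)
    noise_am <- if (params$include_amygdala)
      ar1_noise(n, params$noise$ar, sd_cort) else NULL
    drift <- params$noise$drift_slope * (t_run / max(t_run) - 0.5)

    amp <- numeric(n)
    eng <- if (run$feedback_enabled)
      fb_engine(run$polarity, clamp_psc = 2, window = 3, ref_window = 5)
    ma_v <- ref_v <- psc_v <- disp_v <- rep(NA_real_, n)
    measured <- rep(NA_real_, n)
    blocks <- run$blocks
    # block bookkeeping for lagged perception and value updates
    pending <- list()
    run_blocks <- data.frame(block = integer(0), condition = character(0),
                             chosen = integer(0), feedback = numeric(0),
                             td_error = numeric(0))

    # volume index ranges per block (plus the pre-block lead-in)
    vol_of <- function(t_from, t_to) which(t_run >= t_from & t_run < t_to)

    for (bi in seq_len(nrow(blocks) + 1L)) {
      if (bi == 1L) {               # lead-in segment (may be empty)
        vols <- vol_of(0, blocks$onset[1])
        cond <- "LEAD_IN"
      } else {
        b <- blocks[bi - 1L, ]
        vols <- vol_of(b$onset, b$onset + b$duration)
        cond <- b$condition
      }
      if (length(vols) == 0 && bi == 1L) next

      if (cond == "IMAGINE_REWARD") {
        # settle any perceived feedback that is now fully available
        if (run$feedback_enabled && length(pending)) {
          done <- integer(0)
          for (pi in seq_along(pending)) {
            w <- pending[[pi]]$window
            if (max(w) < min(vols)) {
              fb_block <- mean(disp_v[w], na.rm = TRUE)
              delta_b <- fb_block - values[pending[[pi]]$chosen]
              values[pending[[pi]]$chosen] <-
                values[pending[[pi]]$chosen] + alpha_eff * delta_b
              run_blocks[nrow(run_blocks) + 1L, ] <-
                list(pending[[pi]]$block, "IMAGINE_REWARD",
                     pending[[pi]]$chosen, fb_block, delta_b)
              done <- c(done, pi)
            }
          }
          if (length(done)) pending <- pending[-done]
        }
        if (run$feedback_enabled) {
          chosen <- agent_select(values + ag$novelty_bonus * !tried,
                                 ag$temperature * ag$explore_factor)
          tried[chosen] <- TRUE
        } else {
          chosen <- agent_select(values, ag$temperature)
        }
        e_real <- ag$efficacies[chosen] +
          stats::rnorm(1, 0, params$efficacy_noise_sd)
        amp[vols] <- params$regulation_gain * max(0, e_real)
        if (run$feedback_enabled) {
          lag_from <- blocks$onset[bi - 1L] + feedback_lag
          window <- vol_of(lag_from, lag_from + blocks$duration[bi - 1L])
          pending[[length(pending) + 1L]] <-
            list(block = bi - 1L, chosen = chosen, window = window)
        } else {
          run_blocks[nrow(run_blocks) + 1L, ] <-
            list(bi - 1L, "IMAGINE_REWARD", chosen, NA_real_, NA_real_)
        }
      }

      # measured midbrain signal up to the end of this segment (causal HRF)
      bold <- convolve_hrf(amp, tr)
      measured[vols] <- params$baseline_level + bold[vols] +
        noise_sn[vols] + drift[vols] + physio[vols]

      if (run$feedback_enabled) {
        for (i in vols) {
          s <- fb_step_core(eng, measured[i], labels[i])
          ma_v[i] <- s[1]; ref_v[i] <- s[2]; psc_v[i] <- s[3]; disp_v[i] <- s[4]
        }
      }
    }

    # settle any remaining pending blocks with the volumes that exist
    if (run$feedback_enabled && length(pending)) {
      for (pi in seq_along(pending)) {
        w <- pending[[pi]]$window
        w <- w[w <= n]
        fb_block <- mean(disp_v[w], na.rm = TRUE)
        delta_b <- fb_block - values[pending[[pi]]$chosen]
        values[pending[[pi]]$chosen] <-
          values[pending[[pi]]$chosen] + alpha_eff * delta_b
        run_blocks[nrow(run_blocks) + 1L, ] <-
          list(pending[[pi]]$block, "IMAGINE_REWARD",
               pending[[pi]]$chosen, fb_block, delta_b)
      }
    }

    task_bold <- convolve_hrf(amp, tr)
    # collapsed TD trace of the measured midbrain series, one value per TR
    td <- c(0, diff(measured))
    if (run$feedback_enabled) {
      if (run_name == "training1") {
        w_run <- params$coupling$dlpfc_td_weight_initial
      } else {
        w_run <- params$coupling$dlpfc_td_weight_initial *
          (1 - params$coupling$dlpfc_td_weight_decay * progress)
      }
      w_runs[run_name] <- w_run
    } else w_run <- 0

    dlpfc <- params$baseline_level +
      params$coupling$dlpfc_task_gain * task_bold +
      w_run * convolve_hrf(td, tr) +
      noise_dl + physio
    if (run$feedback_enabled && params$coupling$connectivity_modulation != 0) {
      i_im <- as.numeric(labels == "IMAGINE_REWARD")
      measured <- measured + params$coupling$connectivity_modulation *
        i_im * (dlpfc - mean(dlpfc))
    }
    parahip <- params$baseline_level + noise_ph + physio + drift

    df <- data.frame(sn_vta = measured, dlpfc = dlpfc,
                     parahippocampus = parahip)
    if (params$include_amygdala)
      df$amygdala <- params$baseline_level + noise_am + physio
    roi[[run_name]] <- df

    csf[[run_name]] <- t(sapply(seq_len(n_csf_voxels), function(v)
      physio * stats::runif(1, 0.5, 1.5) + stats::rnorm(n, 0, 0.5)))
    motion[[run_name]] <- sapply(seq_len(6), function(m)
      cumsum(stats::rnorm(n, 0, 0.01)))

    if (run$feedback_enabled) {
      feedback[[run_name]] <- {
        out <- data.frame(volume = seq_len(n), raw = measured,
                          moving_average = ma_v, reference = ref_v,
                          psc = psc_v, displayed = disp_v,
                          valid = !is.na(ref_v))
        class(out) <- c("fb_trace", "data.frame")
        out
      }
      td_traces[[run_name]] <- c(NA, diff(disp_v))
      if (run_name == "training1") {
        # learning progress = fractional decline of the block TD error from
        # the first to the last third of run 1; a non-learner's errors do not
        # shrink, so its progress stays near zero
        d <- abs(run_blocks$td_error[order(run_blocks$block)])
        d <- d[is.finite(d)]
        nb <- length(d)
        if (nb >= 6) {
          early <- mean(d[seq_len(3)])
          late <- mean(d[seq(nb - 2, nb)])
          progress <- if (early > 1e-12) min(1, max(0, 1 - late / early)) else 0
        } else progress <- 0
      }
    }
    block_log[[run_name]] <- run_blocks
  }

  structure(list(design = design, roi = roi, csf_wm = csf, motion = motion,
                 feedback = feedback,
                 agent = list(values_final = values, blocks = block_log,
                              values_at_run_start = values_at_run_start,
                              tried_at_run_start = tried_at_run_start,
                              td_traces = td_traces, progress = progress,
                              td_weights = w_runs),
                 truth = params),
            class = "nf_subject")
}

#' @export
print.nf_subject <- function(x, ...) {
  cat("Simulated neurofeedback subject (", x$design$subject_id, ", ",
      x$design$arm, " arm)\n", sep = "")
  cat("  runs:", paste(names(x$roi), collapse = ", "), "\n")
  cat("  final strategy values:",
      paste(sprintf("%.2f", x$agent$values_final), collapse = " "), "\n")
  invisible(x)
}

#' Simulate one subject's MID session
#'
#' The dlPFC response to each reward cue is an impulse of height
#' `cue_gain + general_gain * magnitude + adaptive_gain * magnitude / range`
#' (range = width of the cue type's magnitude distribution; the adaptive term
#' rescales reward to its local context, so a CHF in the small range counts
#' for more). Impulses are HRF-convolved and AR(1) noise is added.
#'
#' @param params a [subject_params()] (fields under `$mid` and `$noise` used).
#' @param trials trial table from [mid_trials()].
#' @param seed integer seed.
#' @param tr repetition time in seconds.
#' @param large_range,small_range the magnitude ranges used for adaptive
#'   normalization (must match the trial generator).
#' @return list of class `mid_subject` with `series` (dlPFC), `trials`, `tr`,
#'   `n_volumes`, `truth`.
#' @export
simulate_mid_subject <- function(params, trials, seed = 1, tr = 2,
                                 large_range = c(0, 2), small_range = c(0, 0.4)) {
  set.seed(seed)
  n <- ceiling((max(trials$target_onset) + 20) / tr)
  amp <- numeric(n)
  rng <- c(large = diff(large_range), small = diff(small_range), none = NA)
  for (i in seq_len(nrow(trials))) {
    v <- floor(trials$cue_onset[i] / tr) + 1L
    adaptive <- if (trials$cue_type[i] == "none") 0 else
      trials$magnitude[i] / rng[[trials$cue_type[i]]]
    amp[v] <- amp[v] + params$mid$cue_gain +
      params$mid$general_gain * trials$magnitude[i] +
      params$mid$adaptive_gain * adaptive
  }
  series <- convolve_hrf(amp, tr) +
    ar1_noise(n, params$noise$ar,
              params$noise$innovation_sd * params$noise$cortical_scale)
  structure(list(series = series, trials = trials, tr = tr, n_volumes = n,
                 truth = params$mid),
            class = "mid_subject")
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject parameters around two archetypes. Regulators have a
#' positive learning rate and a spread strategy repertoire; non-regulators are
#' non-learners (learning rate 0) with otherwise matched parameters. The
#' assignment is deterministic (first `n_regulators` subjects are regulators).
#' In the inverted arm the feedback contingency defaults to 0: the sign-flipped
#' display is still produced and perceived, but it no longer teaches the
#' strategy-feedback association, so learning cannot converge on upregulation.
#'
#' @param n_regulators,n_nonregulators archetype counts.
#' @param arm feedback arm for the whole cohort.
#' @param seed cohort seed; per-subject seeds are drawn from it.
#' @param study_id study label written into designs and the manifest.
#' @param include_mid also simulate a MID session per subject.
#' @param mid_couples_regulation if TRUE, the MID adaptive gain increases with
#'   the subject's true regulation skill (gain x efficacy spread x learner),
#'   creating the generative link between adaptive reward coding and DRT.
#' @param contingency feedback contingency passed to the agent; defaults to 1
#'   for the standard arm and 0 for the inverted arm.
#' @param n_mid_trials_per_cue MID trials per cue type.
#' @return list of class `nf_cohort` with `subjects` (list of `nf_subject`),
#'   `mid` (list of `mid_subject` or NULL) and `manifest` (data.frame of
#'   ground-truth parameters).
#' @export
simulate_cohort <- function(n_regulators, n_nonregulators,
                            arm = c("standard", "inverted"), seed = 1,
                            study_id = "study2", include_mid = FALSE,
                            mid_couples_regulation = TRUE,
                            contingency = NULL,
                            n_mid_trials_per_cue = 25) {
  arm <- match.arg(arm)
  n <- n_regulators + n_nonregulators
  if (n < 1) stop("empty cohort")
  if (is.null(contingency)) contingency <- if (arm == "standard") 1 else 0
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)

  subjects <- vector("list", n)
  mid_list <- if (include_mid) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    regulator <- i <= n_regulators
    g <- exp(stats::rnorm(1, log(3), 0.35))
    spread <- stats::runif(1, 0.5, 1.5)
    eff <- pmin(1, pmax(0, 0.5 + spread * (stats::runif(5) - 0.5)))
    alpha <- if (regulator) stats::runif(1, 0.2, 0.5) else 0
    drift <- stats::rnorm(1, 0, 0.3)
    skill <- g * (max(eff) - mean(eff)) * as.numeric(alpha > 0)
    general_gain <- max(0.2, stats::rnorm(1, 1, 0.25))
    adaptive_gain <- if (mid_couples_regulation)
      max(0, 0.4 + 0.8 * skill + stats::rnorm(1, 0, 0.1))
    else max(0.2, stats::rnorm(1, 1, 0.2))

    prm <- subject_params(
      agent = agent_params(n_strategies = 5, efficacies = eff,
                           learning_rate = alpha, temperature = 0.15,
                           contingency = contingency),
      regulation_gain = g,
      noise = list(drift_slope = drift),
      mid = list(general_gain = general_gain, adaptive_gain = adaptive_gain),
      arm = arm
    )
    sid <- sprintf("sub-%02d", i)
    des <- nf_session(sid, arm = arm, study_id = study_id)
    subjects[[i]] <- simulate_subject(prm, des, seed = subject_seeds[n + i])
    if (include_mid) {
      trials <- mid_trials(n_mid_trials_per_cue, seed = subject_seeds[n + i])
      mid_list[[i]] <- simulate_mid_subject(prm, trials,
                                            seed = subject_seeds[n + i] + 1L)
    }
    rows[[i]] <- data.frame(
      subject_id = sid, arm = arm, study_id = study_id,
      archetype = if (regulator) "regulator" else "non_regulator",
      learning_rate = alpha, contingency = contingency,
      regulation_gain = g, efficacy_max = max(eff), efficacy_mean = mean(eff),
      drift_slope = drift, skill = skill,
      general_gain = general_gain, adaptive_gain = adaptive_gain,
      seed = subject_seeds[n + i], stringsAsFactors = FALSE)
  }
  structure(list(subjects = subjects, mid = mid_list,
                 manifest = do.call(rbind, rows)),
            class = "nf_cohort")
}

#' @export
print.nf_cohort <- function(x, ...) {
  m <- x$manifest
  cat("Simulated cohort:", nrow(m), "subjects (",
      sum(m$archetype == "regulator"), "regulators /",
      sum(m$archetype == "non_regulator"), "non-regulators ),",
      m$arm[1], "arm\n")
  invisible(x)
}
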