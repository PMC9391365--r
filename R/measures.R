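#' Degree of regulation transfer (midbrain variant)
#'
#' The transfer statistic
#' \deqn{DRT = (BOLD_{IMAGINE,Transfer} - BOLD_{REST,Transfer}) -
#'             (BOLD_{IMAGINE,Baseline} - BOLD_{REST,Baseline})}
#' computed from condition means of the PSC-normalized region series of the
#' two feedback-free runs. Condition labels are shifted by a hemodynamic lag
#' (default 4 s, i.e. two volumes at TR 2 s) so that samples are attributed to
#' the condition that caused them; set `hemodynamic_shift = 0` for raw block
#' means. A positive DRT means relatively stronger IMAGINE-versus-REST
#' activity after training than before.
#'
#' @param baseline,transfer lists with elements `series` (region time course)
#'   and `run` (the corresponding [nf_run()]); both runs must be feedback-free.
#' @param hemodynamic_shift label shift in seconds (multiple of TR).
#' @param normalize PSC-normalize each run's series first (default TRUE).
#' @return object of class `drt_result`: list with `drt` and `components`
#'   (the four condition means).
#' @export
compute_drt <- function(baseline, transfer, hemodynamic_shift = 4,
                        normalize = TRUE) {
  for (x in list(baseline, transfer)) {
    if (x$run$feedback_enabled)
      stop("DRT is defined on feedback-free runs only")
    if (length(x$series) != x$run$n_volumes)
      stop("series length does not match the run")
  }
  cond_means <- function(x) {
    s <- if (normalize) psc_normalize(x$series) else x$series
    lab <- labels_per_volume(x$run, hemodynamic_shift)
    c(imagine = mean(s[lab == "IMAGINE_REWARD"]),
      rest = mean(s[lab == "REST"]))
  }
  b <- cond_means(baseline); tr <- cond_means(transfer)
  comp <- c(imagine_transfer = tr[["imagine"]], rest_transfer = tr[["rest"]],
            imagine_baseline = b[["imagine"]], rest_baseline = b[["rest"]])
  structure(list(drt = (comp[["imagine_transfer"]] - comp[["rest_transfer"]]) -
                   (comp[["imagine_baseline"]] - comp[["rest_baseline"]]),
                 components = comp),
            class = "drt_result")
}

#' @export
print.drt_result <- function(x, ...) {
  cat("Degree of regulation transfer:", round(x$drt, 4), "\n")
  print(round(x$components, 4))
  invisible(x)
}

#' Midbrain DRT of a simulated subject
#'
#' @param subject an `nf_subject`.
#' @param region which region series to use (default the SN/VTA target).
#' @inheritParams compute_drt
#' @return the DRT value (numeric scalar).
#' @export
subject_drt <- function(subject, region = "sn_vta", hemodynamic_shift = 4) {
  compute_drt(
    list(series = subject$roi$baseline[[region]],
         run = subject$design$runs$baseline),
    list(series = subject$roi$transfer[[region]],
         run = subject$design$runs$transfer),
    hemodynamic_shift = hemodynamic_shift
  )$drt
}

imagine_minus_rest <- c(imagine = 1, rest = -1)

#' Non-midbrain (region) DRT from block-design fits
#'
#' Difference of the IMAGINE_REWARD-minus-REST contrast estimates between the
#' transfer and baseline fits of one region.
#'
#' @param fit_baseline,fit_transfer `nf_glm` fits of the block design.
#' @return numeric scalar.
#' @export
compute_region_drt <- function(fit_baseline, fit_transfer) {
  run_contrast(fit_transfer, imagine_minus_rest)$estimate -
    run_contrast(fit_baseline, imagine_minus_rest)$estimate
}

#' Training slope of midbrain regulation
#'
#' IMAGINE-minus-REST contrast in the second training run minus the same
#' contrast in the first: how much stronger the regulation became over
#' training.
#'
#' @param fit_run1,fit_run2 `nf_glm` block-design fits of the two training
#'   runs.
#' @return numeric scalar.
#' @export
training_slope <- function(fit_run1, fit_run2) {
  run_contrast(fit_run2, imagine_minus_rest)$estimate -
    run_contrast(fit_run1, imagine_minus_rest)$estimate
}

#' Temporal-difference coupling slope
#'
#' Change in the IMAGINE_REWARD TD-modulator beta between the training runs
#' (run 2 minus run 1) for a region fitted with the TD design. Negative values
#' mean the region's coupling to midbrain temporal differences weakened as
#' training progressed - the signature expected for learners.
#'
#' @param fit_run1,fit_run2 `nf_glm` TD-design fits of the two training runs.
#' @return numeric scalar.
#' @export
td_slope <- function(fit_run1, fit_run2) {
  for (f in list(fit_run1, fit_run2))
    if (!"imagine_td" %in% names(f$betas))
      stop("fit lacks the TD modulator beta (not a TD design?)")
  fit_run2$betas[["imagine_td"]] - fit_run1$betas[["imagine_td"]]
}

#' Full per-subject summary
#'
#' Runs the whole first-level pipeline on one simulated (or imported) subject:
#' nuisance construction, PSC normalization, block / TD / PPI designs and
#' fits, midbrain and region DRT, training slope, TD slope, PPI interaction
#' contrast, and (if a MID session is present) the reward-sensitivity betas.
#'
#' @param subject an `nf_subject`.
#' @param mid optional `mid_subject` for the same person.
#' @param hemodynamic_shift label shift in seconds for the midbrain DRT.
#' @return one-row data.frame (class `subject_summary`).
#' @export
subject_summary <- function(subject, mid = NULL, hemodynamic_shift = 4) {
  des <- subject$design
  nuis <- lapply(names(des$runs), function(rn) run_nuisance(subject, rn))
  names(nuis) <- names(des$runs)
  y <- lapply(names(des$runs), function(rn)
    lapply(subject$roi[[rn]], psc_normalize))
  names(y) <- names(des$runs)

  block_fit <- function(rn, region)
    fit_ols(build_block_design(des$runs[[rn]], nuis[[rn]]), y[[rn]][[region]])
  td_fit <- function(rn, region)
    fit_ols(build_td_design(des$runs[[rn]], subject$roi[[rn]]$sn_vta,
                            nuis[[rn]]), y[[rn]][[region]])
  ppi_fit <- function(rn)
    fit_ols(build_ppi_design(y[[rn]]$dlpfc, des$runs[[rn]], nuis[[rn]]),
            y[[rn]]$sn_vta)

  ppi_contrast <- function(fit)
    run_contrast(fit, c(ppi_imagine = 1, ppi_rest = -1))$estimate

  out <- data.frame(
    subject_id = des$subject_id,
    arm = des$arm,
    study_id = des$study_id,
    midbrain_drt = subject_drt(subject, hemodynamic_shift = hemodynamic_shift),
    dlpfc_drt = compute_region_drt(block_fit("baseline", "dlpfc"),
                                   block_fit("transfer", "dlpfc")),
    control_drt = compute_region_drt(block_fit("baseline", "parahippocampus"),
                                     block_fit("transfer", "parahippocampus")),
    training_slope = training_slope(block_fit("training1", "sn_vta"),
                                    block_fit("training2", "sn_vta")),
    td_slope = td_slope(td_fit("training1", "dlpfc"),
                        td_fit("training2", "dlpfc")),
    ppi_estimate = mean(c(ppi_contrast(ppi_fit("training1")),
                          ppi_contrast(ppi_fit("training2")))),
    mid_sensitivity_beta = NA_real_,
    mid_adaptive_beta = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(mid)) {
    betas <- mid_modulator_betas(mid)
    out$mid_sensitivity_beta <- betas[["mod_small"]] + betas[["mod_large"]]
    out$mid_adaptive_beta <- betas[["mod_small"]] - betas[["mod_large"]]
  }
  class(out) <- c("subject_summary", "data.frame")
  out
}

#' MID parametric-modulator betas
#'
#' Fits the MID design to the subject's dlPFC series and returns the small and
#' large magnitude-modulator betas. The general reward sensitivity is their
#' sum, adaptive reward coding their difference (small minus large).
#'
#' @param mid a `mid_subject`.
#' @return named numeric vector with `mod_small` and `mod_large`.
#' @export
mid_modulator_betas <- function(mid) {
  X <- build_mid_design(mid$trials, mid$n_volumes, mid$tr)
  fit <- fit_ols(X, mid$series)
  c(mod_small = fit$betas[["mod_small"]], mod_large = fit$betas[["mod_large"]])
}

#' Recover generative MID gains from modulator betas
#'
#' With magnitudes m and context ranges r, the generative trial response is
#' `general * m + adaptive * m / r`, so the fitted per-CHF slopes are
#' `b = general + adaptive / r` in each range. Two ranges give two equations;
#' this solves them for the two gains.
#'
#' @param betas named vector with `mod_small` and `mod_large` (per-CHF betas).
#' @param large_range,small_range the cue-type magnitude ranges.
#' @return named vector `c(general, adaptive)`.
#' @export
mid_recover_gains <- function(betas, large_range = c(0, 2),
                              small_range = c(0, 0.4)) {
  rl <- diff(large_range); rs <- diff(small_range)
  adaptive <- (betas[["mod_small"]] - betas[["mod_large"]]) / (1 / rs - 1 / rl)
  general <- betas[["mod_large"]] - adaptive / rl
  c(general = general, adaptive = adaptive)
}

#' Summaries for a whole cohort
#'
#' @param cohort an `nf_cohort` from [simulate_cohort()].
#' @param hemodynamic_shift label shift in seconds for the midbrain DRT.
#' @return data.frame with one [subject_summary()] row per subject (a
#'   `group_table`).
#' @export
cohort_summary <- function(cohort, hemodynamic_shift = 4) {
  rows <- lapply(seq_along(cohort$subjects), function(i)
    subject_summary(cohort$subjects[[i]],
                    mid = if (!is.null(cohort$mid)) cohort$mid[[i]],
                    hemodynamic_shift = hemodynamic_shift))
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$subject_id)) stop("duplicate subject ids")
  class(out) <- c("group_table", "data.frame")
  out
}
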