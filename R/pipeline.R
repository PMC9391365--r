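#' Simulate a cohort and write it to disk
#'
#' File-based front end of the generator: one directory per subject with the
#' region series, CSF/WM voxels, motion traces, feedback traces and events as
#' TSV, plus a session JSON; the cohort-level ground truth goes into
#' `manifest.tsv` and the full configuration into `config.json`. Running the
#' same configuration twice produces byte-identical output.
#'
#' @param config list of [simulate_cohort()] arguments (must include `seed`);
#'   unknown keys are an error.
#' @param dir output directory (created if missing).
#' @return the `nf_cohort`, invisibly.
#' @export
simulate_study <- function(config, dir) {
  allowed <- names(formals(simulate_cohort))
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) stop("config must set a seed")
  cohort <- do.call(simulate_cohort, config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  fmt <- function(df) format(df, digits = 17, trim = TRUE, scientific = FALSE)
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    sdir <- file.path(dir, sub$design$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    write_session_json(sub$design, file.path(sdir, "session.json"))
    for (rn in names(sub$roi)) {
      utils::write.table(fmt(sub$roi[[rn]]),
                         file.path(sdir, paste0(rn, "_roi.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fmt(as.data.frame(t(sub$csf_wm[[rn]]))),
                         file.path(sdir, paste0(rn, "_csfwm.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fmt(as.data.frame(sub$motion[[rn]])),
                         file.path(sdir, paste0(rn, "_motion.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      run <- sub$design$runs[[rn]]
      write_events_tsv(data.frame(onset = run$blocks$onset,
                                  duration = run$blocks$duration,
                                  trial_type = run$blocks$condition),
                       file.path(sdir, paste0(rn, "_events.tsv")))
    }
    for (rn in names(sub$feedback))
      utils::write.table(fmt(sub$feedback[[rn]]),
                         file.path(sdir, paste0(rn, "_feedback.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(fmt(cohort$manifest), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Validate a simulated dataset directory
#'
#' Checks the schema simulate_study writes: a manifest, and per subject a
#' session JSON plus per-run ROI tables with the required region columns.
#' Violations are reported with the file and column that failed.
#'
#' @param dir dataset directory.
#' @return invisibly TRUE; errors otherwise.
#' @export
validate_dataset_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("missing manifest.tsv in ", dir)
  manifest <- utils::read.table(man_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  required_cols <- c("volume", "sn_vta", "dlpfc", "parahippocampus")
  for (sid in manifest$subject_id) {
    sdir <- file.path(dir, sid)
    if (!file.exists(file.path(sdir, "session.json")))
      stop("missing session.json for ", sid)
    ses <- read_session_json(file.path(sdir, "session.json"))
    for (rn in names(ses$runs)) {
      p <- file.path(sdir, paste0(rn, "_roi.tsv"))
      if (!file.exists(p)) stop("missing ROI table: ", p)
      head1 <- utils::read.table(p, header = TRUE, sep = "\t", nrows = 1)
      miss <- setdiff(setdiff(required_cols, "volume"), names(head1))
      if (length(miss))
        stop(p, " lacks required column(s): ", paste(miss, collapse = ", "))
    }
  }
  invisible(TRUE)
}

read_subject_dir <- function(sdir) {
  ses <- read_session_json(file.path(sdir, "session.json"))
  roi <- list(); csf <- list(); motion <- list()
  for (rn in names(ses$runs)) {
    roi[[rn]] <- utils::read.table(file.path(sdir, paste0(rn, "_roi.tsv")),
                                   header = TRUE, sep = "\t")
    csf[[rn]] <- t(as.matrix(utils::read.table(
      file.path(sdir, paste0(rn, "_csfwm.tsv")), header = TRUE, sep = "\t")))
    motion[[rn]] <- as.matrix(utils::read.table(
      file.path(sdir, paste0(rn, "_motion.tsv")), header = TRUE, sep = "\t"))
  }
  structure(list(design = ses, roi = roi, csf_wm = csf, motion = motion,
                 feedback = list(), agent = NULL, truth = NULL),
            class = "nf_subject")
}

#' Analyze a simulated cohort (in memory)
#'
#' Runs preprocessing, first-level GLMs, subject measures and the group-level
#' statistics on an `nf_cohort`, returning the subject table and the group
#' results.
#'
#' @param cohort an `nf_cohort`.
#' @param hemodynamic_shift label shift in seconds for the midbrain DRT.
#' @param bootstrap_reps bootstrap resamples for the correlation CIs.
#' @param seed seed for the bootstrap.
#' @return list of class `nf_results` with `summary` (the per-subject
#'   `group_table`) and `group` (named list of test results).
#' @export
analyze_cohort <- function(cohort, hemodynamic_shift = 4,
                           bootstrap_reps = 2000, seed = 1) {
  smry <- cohort_summary(cohort, hemodynamic_shift = hemodynamic_shift)
  group <- list()
  if (length(unique(smry$arm)) == 1 && nrow(smry) >= 10) {
    group$slope_drt_correlation <- correlate_with_ci(
      smry$training_slope, smry$midbrain_drt, method = "spearman",
      side = "greater", reps = bootstrap_reps, seed = seed)
    group$td_slope_drt_correlation <- spearman(
      smry$td_slope, smry$midbrain_drt, side = "less")
  }
  structure(list(summary = smry, group = group,
                 parameters = list(hemodynamic_shift = hemodynamic_shift,
                                   bootstrap_reps = bootstrap_reps,
                                   seed = seed)),
            class = "nf_results")
}

#' Analyze a dataset directory
#'
#' File-based equivalent of [analyze_cohort()]: validates the directory
#' schema, reads every subject back, computes the subject summaries and group
#' statistics, and writes `subject_summary.tsv` plus `group_results.json`
#' into `out_dir`.
#'
#' @param dir dataset directory produced by [simulate_study()].
#' @param out_dir results directory (default `<dir>/results`).
#' @inheritParams analyze_cohort
#' @return the `nf_results`, invisibly.
#' @export
analyze_study <- function(dir, out_dir = file.path(dir, "results"),
                          hemodynamic_shift = 4, bootstrap_reps = 2000,
                          seed = 1) {
  validate_dataset_dir(dir)
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  subjects <- lapply(manifest$subject_id,
                     function(sid) read_subject_dir(file.path(dir, sid)))
  cohort <- structure(list(subjects = subjects, mid = NULL,
                           manifest = manifest), class = "nf_cohort")
  res <- analyze_cohort(cohort, hemodynamic_shift, bootstrap_reps, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(format(res$summary, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     file.path(out_dir, "subject_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  grp <- lapply(res$group, unclass)
  jsonlite::write_json(list(group = grp, parameters = res$parameters),
                       file.path(out_dir, "group_results.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Human-readable report of an analysis
#'
#' @param results an `nf_results` (or a results directory containing
#'   `subject_summary.tsv`).
#' @return character vector of report lines (also printed).
#' @export
nf_report <- function(results) {
  if (is.character(results)) {
    p <- file.path(results, "subject_summary.tsv")
    if (!file.exists(p)) stop("no results found in ", results)
    smry <- utils::read.table(p, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    results <- list(summary = smry, group = list())
  }
  s <- results$summary
  if (nrow(s) == 0) return("nothing to report: empty subject table")
  lines <- c(
    sprintf("Subjects: %d (%s arm)", nrow(s), paste(unique(s$arm), collapse = "/")),
    sprintf("Midbrain DRT: mean %.3f, sd %.3f, range [%.3f, %.3f]",
            mean(s$midbrain_drt), stats::sd(s$midbrain_drt),
            min(s$midbrain_drt), max(s$midbrain_drt)),
    sprintf("Training slope: mean %.3f, sd %.3f",
            mean(s$training_slope), stats::sd(s$training_slope)),
    sprintf("TD slope (dlPFC): mean %.3f", mean(s$td_slope)),
    sprintf("PPI interaction estimate: mean %.3f", mean(s$ppi_estimate))
  )
  for (nm in names(results$group)) {
    g <- results$group[[nm]]
    if (inherits(g, "correlation_result"))
      lines <- c(lines, sprintf("%s: %s = %.3f, p = %.4g", nm, g$statistic,
                                g$estimate, g$p))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
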