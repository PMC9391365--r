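#' Weighted ROI extraction
#'
#' Averages voxel time series into one region series using non-negative
#' weights (e.g. probabilistic atlas values), normalized to sum to one.
#'
#' @param voxel_series voxel x time numeric matrix.
#' @param weights per-voxel weights, all >= 0 with at least one positive;
#'   `NULL` for a plain mean.
#' @return numeric vector, one value per time point.
#' @export
extract_roi <- function(voxel_series, weights = NULL) {
  voxel_series <- as.matrix(voxel_series)
  if (is.null(weights)) weights <- rep(1, nrow(voxel_series))
  if (length(weights) != nrow(voxel_series))
    stop("weights length does not match the number of voxels")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with a positive sum")
  as.numeric(crossprod(voxel_series, weights / sum(weights)))
}

#' PCA-based physiological nuisance set
#'
#' Computes the uncentered global mean of the CSF/WM voxel pool and the first
#' `k` temporal principal components of the column-centered voxel x time
#' matrix (aCompCor-style). Components are unit-normalized, mutually
#' orthogonal, ordered by explained variance, and oriented so each component's
#' largest-magnitude loading over time is positive (reproducible sign).
#'
#' @param csf_wm voxel x time matrix of CSF and white-matter voxel series.
#' @param k number of components (default 6, matching the first-level model).
#' @param motion optional n x 6 motion-parameter matrix stored alongside.
#' @param n_initial number of initial volumes flagged as a nuisance period.
#' @return list of class `nuisance_set`: `global_mean` (length-n vector),
#'   `pca_components` (n x k matrix), `explained_variance` (length-k vector),
#'   `motion` (n x 6 or NULL), `initial_volumes` (0/1 indicator vector).
#' @export
pca_nuisance <- function(csf_wm, k = 6, motion = NULL, n_initial = 5) {
  csf_wm <- as.matrix(csf_wm)
  n_vox <- nrow(csf_wm); n_t <- ncol(csf_wm)
  if (n_vox < k) stop("need at least k voxels")
  if (n_t <= k) stop("time series shorter than k")
  # temporal PCA: observations are voxels, variables are time points
  pc <- stats::prcomp(csf_wm, center = TRUE, scale. = FALSE)
  n_informative <- sum(pc$sdev > 1e-10 * pc$sdev[1])
  if (n_informative < k)
    warning("only ", n_informative, " informative components (degenerate matrix)")
  comp <- pc$rotation[, seq_len(k), drop = FALSE]
  # fix sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  colnames(comp) <- paste0("pca", seq_len(k))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_t, ncol(motion) == 6)
    colnames(motion) <- paste0("motion", 1:6)
  }
  structure(list(global_mean = colMeans(csf_wm),
                 pca_components = comp,
                 explained_variance = pc$sdev[seq_len(k)]^2,
                 motion = motion,
                 initial_volumes = as.numeric(seq_len(n_t) <= n_initial)),
            class = "nuisance_set")
}

#' Nuisance set for a simulated run
#'
#' Convenience wrapper building the [pca_nuisance()] set from a simulated
#' subject's CSF/WM voxels and motion traces for one run.
#'
#' @param subject an `nf_subject`.
#' @param run_name one of the run names in the subject's design.
#' @return a `nuisance_set`.
#' @export
run_nuisance <- function(subject, run_name) {
  pca_nuisance(subject$csf_wm[[run_name]], k = 6,
               motion = subject$motion[[run_name]])
}

#' Write a nuisance set as TSV
#' @param nuis a `nuisance_set`.
#' @param path output file.
#' @export
write_nuisance_tsv <- function(nuis, path) {
  df <- data.frame(global_mean = nuis$global_mean, nuis$pca_components,
                   initial_volumes = nuis$initial_volumes)
  if (!is.null(nuis$motion)) df <- cbind(df, nuis$motion)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percent-signal-change normalization of a run series
#'
#' `100 * (x - mean(x)) / mean(x)`: puts runs with different baselines on a
#' common percent scale before condition means or GLM fits are compared
#' across runs.
#'
#' @param x raw series with a positive mean.
#' @return PSC series (mean zero).
#' @export
psc_normalize <- function(x) {
  m <- mean(x)
  if (m <= 0) stop("series mean must be positive for PSC normalization")
  100 * (x - m) / m
}
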