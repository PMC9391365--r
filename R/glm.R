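#' First-level design matrices
#'
#' Builders for the per-run design matrices: the block design (condition
#' boxcars plus nuisance; fifteen columns for the default run), the
#' TD-modulated event design, the linear-time control design, the MID design
#' and the PPI design. All task columns are sampled on the TR grid and
#' convolved with the canonical HRF; parametric modulators are mean-centered
#' within their condition before convolution.
#'
#' @param run an [nf_run()].
#' @param nuisance a `nuisance_set` from [pca_nuisance()] (or NULL to omit
#'   nuisance columns).
#' @return a `design_matrix`: a numeric matrix with named columns and
#'   attributes `run_id` and `tr`.
#' @name designs
NULL

nuisance_columns <- function(nuisance, n) {
  if (is.null(nuisance)) return(NULL)
  stopifnot(length(nuisance$initial_volumes) == n)
  cbind(initial_volumes = nuisance$initial_volumes,
        nuisance$motion,
        nuisance$pca_components)
}

as_design <- function(cols, run_id, tr) {
  X <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
  if (anyDuplicated(colnames(X))) stop("duplicate design column names")
  structure(X, run_id = run_id, tr = tr, class = c("design_matrix", class(X)))
}

condition_boxcars <- function(run) {
  labels <- labels_per_volume(run, 0)
  if (!any(labels == "IMAGINE_REWARD") || !any(labels == "REST"))
    stop("run lacks blocks of one condition (malformed design)")
  list(imagine = as.numeric(labels == "IMAGINE_REWARD"),
       rest = as.numeric(labels == "REST"))
}

#' @rdname designs
#' @export
build_block_design <- function(run, nuisance = NULL) {
  bc <- condition_boxcars(run)
  as_design(list(imagine = convolve_hrf(bc$imagine, run$tr),
                 rest = convolve_hrf(bc$rest, run$tr),
                 nuisance_columns(nuisance, run$n_volumes)),
            run$run_type, run$tr)
}

# centered within-condition parametric modulator column, HRF-convolved
modulator_column <- function(indicator, modulator, tr) {
  m <- modulator * indicator
  sel <- indicator > 0
  m[sel] <- m[sel] - mean(m[sel])
  convolve_hrf(m, tr)
}

#' @rdname designs
#' @param snvta measured SN/VTA series for the run (full length); its
#'   one-volume backward difference is the collapsed temporal-difference
#'   modulator (first volume gets 0).
#' @export
build_td_design <- function(run, snvta, nuisance = NULL) {
  stopifnot(length(snvta) == run$n_volumes)
  bc <- condition_boxcars(run)
  td <- c(0, diff(snvta))
  as_design(list(imagine = convolve_hrf(bc$imagine, run$tr),
                 imagine_td = modulator_column(bc$imagine, td, run$tr),
                 rest = convolve_hrf(bc$rest, run$tr),
                 rest_td = modulator_column(bc$rest, td, run$tr),
                 nuisance_columns(nuisance, run$n_volumes)),
            run$run_type, run$tr)
}

#' @rdname designs
#' @param direction "increase" for a linear ramp over the run, "decrease" for
#'   its reverse; used by the sensitization/desensitization control analysis.
#' @export
build_linear_time_design <- function(run, direction = c("increase", "decrease"),
                                     nuisance = NULL) {
  direction <- match.arg(direction)
  bc <- condition_boxcars(run)
  ramp <- seq_len(run$n_volumes) / run$n_volumes
  if (direction == "decrease") ramp <- rev(ramp)
  as_design(list(imagine = convolve_hrf(bc$imagine, run$tr),
                 imagine_time = modulator_column(bc$imagine, ramp, run$tr),
                 rest = convolve_hrf(bc$rest, run$tr),
                 rest_time = modulator_column(bc$rest, ramp, run$tr),
                 nuisance_columns(nuisance, run$n_volumes)),
            run$run_type, run$tr)
}

#' @rdname designs
#' @param trials MID trial table from [mid_trials()].
#' @param n_volumes run length in volumes.
#' @param tr repetition time in seconds.
#' @export
build_mid_design <- function(trials, n_volumes, tr, nuisance = NULL) {
  if (any(trials$cue_onset / tr >= n_volumes))
    stop("trial outside the run")
  onset_vol <- floor(trials$cue_onset / tr) + 1L
  stick <- function(sel, height = rep(1, sum(sel))) {
    x <- numeric(n_volumes)
    x[onset_vol[sel]] <- height
    x
  }
  cols <- list(intercept = rep(1, n_volumes))
  for (ct in c("large", "small", "none")) {
    sel <- trials$cue_type == ct
    if (!any(sel)) next
    cols[[paste0("cue_", ct)]] <- convolve_hrf(stick(sel), tr)
    if (ct != "none") {
      m <- trials$magnitude[sel]
      cols[[paste0("mod_", ct)]] <- convolve_hrf(stick(sel, m - mean(m)), tr)
    }
  }
  cols$nuis <- nuisance_columns(nuisance, n_volumes)
  names(cols)[names(cols) == "nuis"] <- ""
  as_design(cols, "mid", tr)
}

#' @rdname designs
#' @param seed_series the (dlPFC) seed region series, full run length. The
#'   interaction columns are formed in the measured-signal domain (no
#'   deconvolution): centered condition indicator times centered seed.
#' @export
build_ppi_design <- function(seed_series, run, nuisance = NULL) {
  stopifnot(length(seed_series) == run$n_volumes)
  bc <- condition_boxcars(run)
  seed_c <- seed_series - mean(seed_series)
  as_design(list(imagine = convolve_hrf(bc$imagine, run$tr),
                 rest = convolve_hrf(bc$rest, run$tr),
                 seed = seed_c,
                 ppi_imagine = (bc$imagine - mean(bc$imagine)) * seed_c,
                 ppi_rest = (bc$rest - mean(bc$rest)) * seed_c,
                 nuisance_columns(nuisance, run$n_volumes)),
            run$run_type, run$tr)
}

#' Ordinary least-squares fit of a design matrix
#'
#' QR-based OLS with residual variance on `n - rank` degrees of freedom.
#' Rank-deficient designs are refused, naming the offending columns.
#'
#' @param X a design matrix (columns named).
#' @param y response series (region time course), same length as `nrow(X)`.
#' @return object of class `nf_glm`: list with `betas` (named), `sigma2`,
#'   `dof`, `XtXinv`, `run_id`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) > ncol(X))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  dof <- nrow(X) - qr_x$rank
  structure(list(betas = stats::setNames(as.numeric(beta), colnames(X)),
                 sigma2 = sum(res^2) / dof,
                 dof = dof,
                 XtXinv = chol2inv(qr.R(qr_x))[order(qr_x$pivot),
                                               order(qr_x$pivot), drop = FALSE],
                 residuals = as.numeric(res),
                 run_id = attr(X, "run_id")),
            class = "nf_glm")
}

#' @export
print.nf_glm <- function(x, ...) {
  cat("First-level GLM fit (", length(x$betas), " regressors, ",
      x$dof, " dof)\n", sep = "")
  print(round(x$betas, 4))
  invisible(x)
}

#' Contrast estimate and t statistic
#'
#' @param fit an `nf_glm` from [fit_ols()].
#' @param weights contrast weight vector, either the full column length or a
#'   named vector over a subset of columns (others 0).
#' @return list with `estimate`, `se`, `t`, `dof`, `p` (two-sided).
#' @export
run_contrast <- function(fit, weights) {
  k <- length(fit$betas)
  if (!is.null(names(weights))) {
    w <- stats::setNames(numeric(k), names(fit$betas))
    missing <- setdiff(names(weights), names(fit$betas))
    if (length(missing))
      stop("unknown contrast columns: ", paste(missing, collapse = ", "))
    w[names(weights)] <- weights
  } else {
    if (length(weights) != k) stop("contrast length does not match columns")
    w <- weights
  }
  est <- sum(w * fit$betas)
  se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$XtXinv %*% w))
  tt <- if (se == 0) 0 else est / se
  list(estimate = est, se = se, t = tt, dof = fit$dof,
       p = 2 * stats::pt(-abs(tt), fit$dof))
}
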