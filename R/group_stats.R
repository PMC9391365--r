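#' Spearman rank correlation
#'
#' Midrank-based rank correlation. The p-value uses the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom; below n = 10 the
#' exact permutation distribution of rho is enumerated instead.
#'
#' @param x,y numeric vectors of equal length (n >= 4), neither constant.
#' @param side "two" (default), "greater" or "less".
#' @return list of class `correlation_result`: `estimate`, `n`, `p`, `side`,
#'   `method`.
#' @export
spearman <- function(x, y, side = c("two", "greater", "less")) {
  side <- match.arg(side)
  n <- length(x)
  stopifnot(n == length(y), n >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: ranks undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- permutations_of(n)
    rho_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- switch(side,
                two = mean(abs(rho_all) >= abs(rho) - 1e-12),
                greater = mean(rho_all >= rho - 1e-12),
                less = mean(rho_all <= rho + 1e-12))
    method <- "exact permutation"
  } else {
    p <- t_approx_p(rho, n, side)
    method <- "t approximation"
  }
  structure(list(estimate = rho, n = n, p = p, side = side,
                 statistic = "spearman_rho", method = method),
            class = "correlation_result")
}

t_approx_p <- function(r, n, side) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  switch(side,
         two = 2 * stats::pt(-abs(tt), n - 2),
         greater = stats::pt(tt, n - 2, lower.tail = FALSE),
         less = stats::pt(tt, n - 2))
}

# all permutations of 1..n as a matrix (n <= 9)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor.test()] returning the package's
#' `correlation_result` container.
#'
#' @inheritParams spearman
#' @export
pearson <- function(x, y, side = c("two", "greater", "less")) {
  side <- match.arg(side)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  alt <- switch(side, two = "two.sided", greater = "greater", less = "less")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alt)
  structure(list(estimate = unname(ct$estimate), n = length(x),
                 p = ct$p.value, side = side, statistic = "pearson_r",
                 method = "t test"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (n = %d), p = %.4g (%s-sided, %s)\n",
              x$statistic, x$estimate, x$n, x$p,
              if (x$side == "two") "two" else "one", x$method))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap %g%% CI [%.4f, %.4f] (%d reps)\n",
                100 * x$ci_level, x$ci[1], x$ci[2], x$ci_reps))
  invisible(x)
}

#' Compare two independent correlations (Fisher z)
#'
#' \deqn{z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2) /
#'           \sqrt{1/(n_1-3) + 1/(n_2-3)}}
#'
#' @param r1,r2 correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 sample sizes (> 3).
#' @param side "one" tests r1 > r2; "two" is two-sided.
#' @return list with `z` and `p`.
#' @export
fisher_z_diff <- function(r1, n1, r2, n2, side = c("one", "two")) {
  side <- match.arg(side)
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (side == "one") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) via
#' [stats::oneway.test()].
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list with `F`, `df` (c(k-1, N-k)) and `p`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared p on k-1 df, via
#' [stats::kruskal.test()].
#'
#' @inheritParams anova_oneway
#' @return list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2)
  values <- unlist(groups, use.names = FALSE)
  if (stats::sd(values) == 0) stop("all values identical")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(values, g)
  list(H = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pooled-variance two-sample t test
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return list with `t`, `df` (n1+n2-2) and `p` (two-sided).
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Percentile bootstrap confidence interval for a paired statistic
#'
#' Resamples (x, y) pairs with replacement and returns the percentile interval
#' of the statistic. Seed-deterministic.
#'
#' @param x,y paired observations (n >= 4).
#' @param statistic function of (x, y) returning a scalar; default Spearman
#'   rho.
#' @param reps number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `ci` (length-2), `level`, `reps`, `seed`, `estimate`.
#' @export
bootstrap_ci <- function(x, y, statistic = function(x, y) stats::cor(rank(x), rank(y)),
                         reps = 10000, level = 0.95, seed = 1) {
  n <- length(x)
  stopifnot(n == length(y), n >= 4, reps >= 1)
  set.seed(seed)
  stat <- numeric(reps)
  for (r in seq_len(reps)) {
    i <- sample.int(n, n, replace = TRUE)
    stat[r] <- statistic(x[i], y[i])
  }
  a <- (1 - level) / 2
  list(ci = unname(stats::quantile(stat, c(a, 1 - a), na.rm = TRUE)),
       level = level, reps = reps, seed = seed, estimate = statistic(x, y))
}

#' Correlation adjusted for a covariate
#'
#' Regresses the covariate (e.g. the study indicator) out of both variables
#' and correlates the residuals; with a constant covariate this reduces to
#' the unadjusted correlation.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric or factor covariate.
#' @param method "pearson" or "spearman".
#' @param side passed to the correlation.
#' @return a `correlation_result`.
#' @export
partial_covariate <- function(x, y, covariate,
                              method = c("pearson", "spearman"),
                              side = "two") {
  method <- match.arg(method)
  cov_num <- if (is.factor(covariate) || is.character(covariate))
    as.numeric(as.factor(covariate)) else as.numeric(covariate)
  if (stats::sd(cov_num) == 0) {
    rx <- x; ry <- y
  } else {
    if (abs(stats::cor(cov_num, x)) > 1 - 1e-12)
      stop("covariate is collinear with x")
    rx <- stats::residuals(stats::lm(x ~ cov_num))
    ry <- stats::residuals(stats::lm(y ~ cov_num))
  }
  if (method == "pearson") pearson(rx, ry, side) else spearman(rx, ry, side)
}

#' Conjunction and disjunction of two region-level result sets
#'
#' A region is in the conjunction when its statistic passes the threshold in
#' the stated direction in both analyses, and in the disjunction when it
#' passes in exactly one.
#'
#' @param results_a,results_b named numeric vectors of per-region statistics
#'   over the same region set.
#' @param threshold significance threshold on the statistic.
#' @param direction "positive" (statistic >= threshold) or "negative"
#'   (statistic <= -threshold).
#' @return list with character vectors `conjunction`, `disjunction`,
#'   `neither`.
#' @export
conjunction_disjunction <- function(results_a, results_b, threshold,
                                    direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (!setequal(names(results_a), names(results_b)) ||
      is.null(names(results_a)))
    stop("result sets must be named over the same regions")
  results_b <- results_b[names(results_a)]
  pass <- function(x) if (direction == "positive") x >= threshold else x <= -threshold
  a <- pass(results_a); b <- pass(results_b)
  regions <- names(results_a)
  list(conjunction = regions[a & b],
       disjunction = regions[xor(a, b)],
       neither = regions[!a & !b])
}

#' Benjamini-Hochberg discovery flags
#'
#' Step-up FDR control at level q via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return logical vector of discoveries.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Correlation with bootstrap CI attached
#'
#' Convenience wrapper: computes the correlation and a percentile bootstrap
#' CI and stores both in one result.
#'
#' @inheritParams spearman
#' @param method "spearman" or "pearson".
#' @param reps,level,seed bootstrap settings.
#' @return a `correlation_result` with fields `ci`, `ci_level`, `ci_reps`.
#' @export
correlate_with_ci <- function(x, y, method = c("spearman", "pearson"),
                              side = "two", reps = 2000, level = 0.95,
                              seed = 1) {
  method <- match.arg(method)
  res <- if (method == "spearman") spearman(x, y, side) else pearson(x, y, side)
  statf <- if (method == "spearman")
    function(x, y) stats::cor(rank(x), rank(y)) else stats::cor
  bs <- bootstrap_ci(x, y, statf, reps = reps, level = level, seed = seed)
  res$ci <- bs$ci; res$ci_level <- level; res$ci_reps <- reps
  res
}
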