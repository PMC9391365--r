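test_that("Spearman correlation matches the rank-formula oracle", {
  r <- spearman(c(1, 2, 3, 4), c(4, 2, 3, 1))
  d <- rank(c(1, 2, 3, 4)) - rank(c(4, 2, 3, 1))
  oracle <- 1 - 6 * sum(d^2) / (4 * (4^2 - 1))   # untied closed form
  expect_equal(r$estimate, oracle)
  expect_identical(r$method, "exact permutation")
  # strictly monotone transforms give rho = 1
  x <- c(0.3, 1.2, 2.2, 5, 9, 11, 14, 20, 21, 30)
  expect_equal(spearman(x, exp(x))$estimate, 1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("Spearman handles ties through midranks", {
  set.seed(1)
  x <- sample(1:5, 20, replace = TRUE)
  y <- sample(1:4, 20, replace = TRUE)
  ours <- spearman(x, y)
  # Pearson-on-midranks oracle
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(ours$estimate, oracle)
  # the t-approximation p matches cor.test's asymptotic path
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(ours$p, ct$p.value, tolerance = 1e-10)
})

test_that("the exact permutation p is calibrated on tiny samples", {
  # enumeration oracle: p of the observed |rho| under all 5! pairings
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- spearman(x, y)
  perms <- combinat_perms <- NULL
  # brute force via recursive enumeration
  allp <- expand.grid(rep(list(1:5), 5))
  allp <- allp[apply(allp, 1, function(p) length(unique(p)) == 5), ]
  rho_all <- apply(allp, 1, function(p) cor(rank(x), rank(y[as.numeric(p)])))
  expect_equal(r$p, mean(abs(rho_all) >= abs(r$estimate) - 1e-12))
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 4, 2, 7, 3)
  expect_equal(pearson(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson(x, -x)$estimate, -1)
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b)$estimate, oracle)
  expect_error(pearson(rep(2, 5), 1:5), "variance")
})

test_that("the Fisher z comparison follows the closed form", {
  expect_equal(fisher_z_diff(0.4, 30, 0.4, 50)$z, 0)
  # closed-form oracle at the published group sizes
  z_oracle <- (atanh(0.62) - atanh(-0.30)) / sqrt(1 / (42 - 3) + 1 / (17 - 3))
  res <- fisher_z_diff(0.62, 42, -0.30, 17, side = "one")
  expect_equal(res$z, z_oracle)
  expect_equal(res$z, 3.32, tolerance = 0.005)
  expect_equal(res$p, pnorm(z_oracle, lower.tail = FALSE))
  # monotone in r1
  zs <- vapply(seq(0.1, 0.9, 0.1),
               function(r) fisher_z_diff(r, 30, 0.2, 30)$z, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_error(fisher_z_diff(1, 10, 0.5, 10))
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  expect_equal(anova_oneway(list(1:3, 1:3, 1:3))$F, 0)
  res <- anova_oneway(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(res$F, 4)                       # closed-form SS oracle
  expect_equal(unname(res$df), c(2, 3))
  expect_error(anova_oneway(list(1, 1:3)))
})

test_that("ANOVA p-values are calibrated under label permutation", {
  set.seed(3)
  x <- rnorm(30)
  ps <- replicate(600, {
    g <- sample(rep(1:3, 10))
    anova_oneway(split(x, g))$p
  })
  expect_lt(max(abs(sort(ps) - seq_along(ps) / length(ps))), 0.1)
})

test_that("Kruskal-Wallis matches the rank-sum formula with tie correction", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$H, 12 / (6 * 7) * 2 * ((1.5 - 3.5)^2 + 0 + (5.5 - 3.5)^2))
  expect_equal(unname(res$df), 2)
  # tie-corrected textbook formula on tied data
  g <- list(c(1, 1, 2), c(2, 3, 3), c(1, 3, 4))
  x <- unlist(g); r <- rank(x); N <- length(x)
  Ri <- tapply(r, rep(seq_along(g), lengths(g)), sum)
  H <- (12 / (N * (N + 1))) * sum(Ri^2 / lengths(g)) - 3 * (N + 1)
  ties <- table(x)
  H_corr <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(kruskal_wallis(g)$H, unname(H_corr))
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("the pooled two-sample t matches the closed form", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 5, 6)
  expect_equal(two_sample_t(a, a)$t, 0)
  expect_equal(two_sample_t(a, b)$t, -two_sample_t(b, a)$t)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  res <- two_sample_t(a, b)
  expect_equal(res$t, t_oracle)
  expect_equal(unname(res$df), 6)
})

test_that("bootstrap CIs are deterministic and degenerate correctly", {
  x <- 1:8; y <- 2 * (1:8) + 3            # all resamples lie on a line
  bs <- bootstrap_ci(x, y, statistic = cor, reps = 200, seed = 4)
  expect_equal(unname(bs$ci), c(1, 1))
  b1 <- bootstrap_ci(rnorm(10), rnorm(10), reps = 500, seed = 9)
  set.seed(123)  # unrelated RNG state must not matter
  b2 <- bootstrap_ci(rnorm(10), rnorm(10), reps = 500, seed = 9)
  expect_false(identical(b1$estimate, b2$estimate))  # different data
  x <- rnorm(12); y <- rnorm(12)
  expect_identical(bootstrap_ci(x, y, reps = 300, seed = 5)$ci,
                   bootstrap_ci(x, y, reps = 300, seed = 5)$ci)
})

test_that("bootstrap coverage is close to nominal", {
  # Monte-Carlo coverage oracle: known rho from a bivariate normal
  rho <- 0.5
  covered <- vapply(1:200, function(i) {
    set.seed(2000 + i)
    z <- rnorm(50); x <- z + rnorm(50); y <- rho_y <- z + rnorm(50)
    true_rho <- 0.5  # cor(x, y) = 1 / 2 by construction
    bs <- bootstrap_ci(x, y, statistic = cor, reps = 400, level = 0.95,
                       seed = i)
    bs$ci[1] <= true_rho && true_rho <= bs$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 1.00)
})

test_that("the study covariate is regressed out of both variables", {
  set.seed(6)
  study <- rep(c(0, 1), each = 40)
  x <- rnorm(80) + 3 * study
  y <- 0.6 * x + rnorm(80) - 5 * study
  raw <- pearson(x, y)$estimate
  adj <- partial_covariate(x, y, study)$estimate
  # within-study correlation oracle
  within <- cor(c(scale(x[1:40], scale = FALSE), scale(x[41:80], scale = FALSE)),
                c(scale(y[1:40], scale = FALSE), scale(y[41:80], scale = FALSE)))
  expect_equal(adj, within, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(raw, adj)))
  # constant covariate is a no-op
  expect_equal(partial_covariate(x, y, rep(1, 80))$estimate, raw)
  expect_error(partial_covariate(x, y, x), "collinear")
})

test_that("injected between-study shifts are removed on average", {
  est <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    study <- rep(c(0, 1), each = 20)
    base_x <- rnorm(40); base_y <- 0.5 * base_x + rnorm(40) * sqrt(0.75)
    x <- base_x + 4 * study; y <- base_y - 4 * study
    partial_covariate(x, y, study)$estimate
  }, numeric(1))
  # cor(base_x, base_y) = 0.5 by construction; adjustment recovers it
  expect_equal(mean(est), 0.5, tolerance = 0.05)
})

test_that("conjunction and disjunction partition the region set", {
  ta <- c(r1 = 3, r2 = 0.5, r3 = 2.5, r4 = -1)
  tb <- c(r1 = 2.2, r2 = 2.8, r3 = 0.1, r4 = -2)
  out <- conjunction_disjunction(ta, tb, threshold = 2)
  expect_identical(out$conjunction, "r1")
  expect_setequal(out$disjunction, c("r2", "r3"))
  expect_identical(out$neither, "r4")
  # partition property on random inputs
  for (i in 1:10) {
    set.seed(i)
    a <- setNames(rnorm(12), paste0("g", 1:12))
    b <- setNames(rnorm(12), paste0("g", 1:12))
    res <- conjunction_disjunction(a, b, 0.5)
    all_regions <- sort(c(res$conjunction, res$disjunction, res$neither))
    expect_identical(all_regions, sort(names(a)))
  }
  expect_error(conjunction_disjunction(ta, tb[1:3], 2), "same regions")
})

test_that("BH-FDR implements the step-up rule", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05),
                   rep(TRUE, 4))                 # step-up oracle
  expect_identical(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  # monotonicity: lowering any p never loses discoveries
  set.seed(7)
  for (i in 1:10) {
    p <- runif(15)
    d0 <- sum(bh_fdr(p, 0.1))
    j <- sample(15, 1)
    p[j] <- p[j] / 2
    expect_gte(sum(bh_fdr(p, 0.1)), d0)
  }
})

test_that("correlations with bootstrap CIs contain the point estimate", {
  set.seed(8)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  res <- correlate_with_ci(x, y, method = "spearman", reps = 500, seed = 3)
  expect_gte(res$estimate, res$ci[1])
  expect_lte(res$estimate, res$ci[2])
  expect_true(abs(res$estimate) <= 1)
})
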