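# independent discrete-convolution oracle (direct double loop)
conv_oracle <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n))
    for (j in seq_len(min(t, length(k))))
      out[t] <- out[t] + k[j] * x[t - j + 1]
  out
}

sim_nuisance <- function(sub, rn) run_nuisance(sub, rn)

test_that("the default block design has exactly fifteen regressors", {
  sub <- simulate_subject(regulator_params(), nf_session(), seed = 1)
  X <- build_block_design(sub$design$runs$baseline, sim_nuisance(sub, "baseline"))
  expect_identical(ncol(X), 15L)
  expect_identical(colnames(X)[1:3], c("imagine", "rest", "initial_volumes"))
  expect_identical(nrow(X), 190L)
})

test_that("boxcar columns match a direct convolution oracle", {
  run <- nf_run("baseline", n_block_pairs = 3, lead_in_volumes = 5)
  X <- build_block_design(run)
  lab <- labels_per_volume(run, 0)
  k <- hrf(seq(0, 32, by = run$tr)); k <- k / sum(k)
  expect_equal(X[, "imagine"], conv_oracle(as.numeric(lab == "IMAGINE_REWARD"), k))
  expect_equal(X[, "rest"], conv_oracle(as.numeric(lab == "REST"), k))
})

test_that("a run without one condition is refused", {
  run <- nf_run("baseline", n_block_pairs = 1)
  run$blocks <- run$blocks[run$blocks$condition == "REST", , drop = FALSE]
  run$n_volumes <- as.integer(max(run$blocks$onset + run$blocks$duration) / run$tr)
  expect_error(build_block_design(run), "malformed")
})

test_that("TD modulator columns behave under degenerate inputs", {
  run <- nf_run("training1", "standard", n_block_pairs = 2, lead_in_volumes = 5)
  n <- run$n_volumes
  # constant series: zero difference, zero modulator
  X <- build_td_design(run, rep(5, n))
  expect_true(all(X[, "imagine_td"] == 0))
  expect_true(all(X[, "rest_td"] == 0))
  # linear ramp: constant difference, centred away to zero
  X2 <- build_td_design(run, seq_len(n) * 0.5)
  expect_equal(max(abs(X2[, "imagine_td"])), 0, tolerance = 1e-12)
})

test_that("TD modulator construction commutes with signal scaling", {
  run <- nf_run("training1", "standard", n_block_pairs = 2, lead_in_volumes = 5)
  set.seed(6)
  s <- 100 + rnorm(run$n_volumes)
  X1 <- build_td_design(run, s)
  X3 <- build_td_design(run, 3 * s)
  expect_equal(X3[, "imagine_td"], 3 * X1[, "imagine_td"])
})

test_that("linear-time modulators are centred mirror images", {
  run <- nf_run("training1", "standard", n_block_pairs = 2, lead_in_volumes = 5)
  Xi <- build_linear_time_design(run, "increase")
  Xd <- build_linear_time_design(run, "decrease")
  expect_equal(Xi[, "imagine_time"], -Xd[, "imagine_time"], tolerance = 1e-12)
  # pre-convolution centring: the convolved column sums are (near) zero late
  expect_equal(sum(Xi[, "imagine_time"] + Xd[, "imagine_time"]), 0,
               tolerance = 1e-12)
})

test_that("linear amplitude trends are recovered in sign", {
  run <- nf_run("training1", "standard")
  lab <- labels_per_volume(run, 0)
  k <- hrf(seq(0, 32, by = 2)); k <- k / sum(k)
  hits <- vapply(1:40, function(i) {
    set.seed(700 + i)
    ramp <- seq_len(run$n_volumes) / run$n_volumes
    amp <- as.numeric(lab == "IMAGINE_REWARD") * (0.5 + 1.5 * ramp)
    y <- conv_oracle(amp, k) + rnorm(run$n_volumes, 0, 0.5)
    fit <- fit_ols(build_linear_time_design(run, "increase"), y)
    fit$betas[["imagine_time"]] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("MID designs centre modulators within cue type", {
  trials <- mid_trials(8, seed = 2)
  X <- build_mid_design(trials, n_volumes = 150, tr = 2)
  expect_true(all(c("cue_large", "cue_small", "cue_none",
                    "mod_large", "mod_small") %in% colnames(X)))
  expect_false("mod_none" %in% colnames(X))
  # equal magnitudes within a type: modulator column vanishes
  tr_eq <- trials; tr_eq$magnitude[tr_eq$cue_type == "small"] <- 0.2
  X2 <- build_mid_design(tr_eq, 150, 2)
  expect_true(all(X2[, "mod_small"] == 0))
  bad <- trials; bad$cue_onset[1] <- 1e4
  expect_error(build_mid_design(bad, 150, 2), "outside")
})

test_that("PPI designs form centred interactions", {
  run <- nf_run("training1", "standard", n_block_pairs = 2, lead_in_volumes = 5)
  X <- build_ppi_design(rep(3, run$n_volumes), run)
  expect_true(all(X[, "ppi_imagine"] == 0))    # constant seed, centred away
  set.seed(8)
  seed_series <- rnorm(run$n_volumes)
  X2 <- build_ppi_design(seed_series, run)
  lab <- labels_per_volume(run, 0)
  i_c <- as.numeric(lab == "IMAGINE_REWARD")
  i_c <- i_c - mean(i_c)
  expect_equal(X2[, "ppi_imagine"], i_c * (seed_series - mean(seed_series)))
})

test_that("PPI interaction t is null without true coupling", {
  run <- nf_run("training1", "standard")
  ts <- vapply(1:60, function(i) {
    set.seed(900 + i)
    seed_series <- as.numeric(stats::filter(rnorm(190), 0.3, method = "recursive"))
    y <- as.numeric(stats::filter(rnorm(190), 0.3, method = "recursive"))
    fit <- fit_ols(build_ppi_design(seed_series, run), y)
    run_contrast(fit, c(ppi_imagine = 1, ppi_rest = -1))$t
  }, numeric(1))
  expect_lt(abs(mean(ts)), 1.96 / sqrt(60) * sd(ts) + 0.15)
})

test_that("OLS reproduces exact and oracle solutions", {
  x <- rnorm(50)
  fit <- fit_ols(matrix(x, dimnames = list(NULL, "x")), 2 * x)
  expect_equal(unname(fit$betas), 2)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  # normal-equations oracle on random problems
  for (i in 1:20) {
    set.seed(1000 + i)
    n <- sample(20:60, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("c", 1:p)))
    y <- rnorm(n)
    beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
    fit <- fit_ols(X, y)
    expect_equal(unname(fit$betas), as.numeric(beta_oracle), tolerance = 1e-8)
  }
})

test_that("collinear designs are refused with the offending column", {
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x)
  expect_error(fit_ols(X, rnorm(30)), "rank-deficient.*b")
})

test_that("contrasts follow c'beta with correct standard errors", {
  set.seed(11)
  X <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  y <- rnorm(40)
  fit <- fit_ols(X, y)
  expect_identical(run_contrast(fit, c(0, 0, 0))$estimate, 0)
  w <- c(1, -1, 0.5)
  cr <- run_contrast(fit, w)
  expect_equal(cr$estimate, sum(w * fit$betas))   # direct product oracle
  # cross-check t against lm
  lmfit <- lm(y ~ 0 + X)
  se_or <- sqrt(sum(diag(t(w) %*% vcov(lmfit) %*% w)))
  expect_equal(cr$se, se_or, tolerance = 1e-10)
  # named-weight interface
  expect_equal(run_contrast(fit, c(a = 1, b = -1))$estimate,
               fit$betas[["a"]] - fit$betas[["b"]])
  expect_error(run_contrast(fit, c(zz = 1)), "unknown")
})

test_that("orthogonal nuisance columns leave contrasts unchanged", {
  run <- nf_run("baseline", n_block_pairs = 3, lead_in_volumes = 5)
  X <- build_block_design(run)
  set.seed(12)
  y <- X %*% c(1.2, 0.4) + rnorm(run$n_volumes, 0, 0.3)
  base <- run_contrast(fit_ols(X, y), c(imagine = 1, rest = -1))$estimate
  extra <- qr.resid(qr(cbind(X, y)), rnorm(run$n_volumes))  # orthogonal to both
  X2 <- cbind(X, orth = extra)
  with_extra <- run_contrast(fit_ols(X2, y), c(imagine = 1, rest = -1))$estimate
  expect_equal(with_extra, base, tolerance = 1e-10)
})
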