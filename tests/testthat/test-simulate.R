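test_that("the canonical HRF has the expected shape", {
  expect_identical(hrf(0), 0)
  grid <- seq(0, 32, by = 0.05)
  h <- hrf(grid)
  peak <- grid[which.max(h)]
  expect_gte(peak, 4); expect_lte(peak, 7)          # grid-search oracle
  expect_equal(max(h), 1)                            # unit peak
  expect_gt(sum(h) * 0.05, 0)                        # net positive response
  expect_lt(min(h), 0)                               # undershoot exists
})

test_that("identical seeds give bit-identical datasets", {
  prm <- regulator_params()
  des <- nf_session("s1")
  a <- simulate_subject(prm, des, seed = 5)
  b <- simulate_subject(prm, des, seed = 5)
  expect_identical(a, b)
  c <- simulate_subject(prm, des, seed = 6)
  expect_false(identical(a$roi$baseline$sn_vta, c$roi$baseline$sn_vta))
})

test_that("all per-run series have the run length and plausible levels", {
  sub <- simulate_subject(regulator_params(), nf_session("s1"), seed = 2)
  for (rn in names(sub$roi)) {
    n <- sub$design$runs[[rn]]$n_volumes
    expect_identical(nrow(sub$roi[[rn]]), n)
    expect_identical(ncol(sub$csf_wm[[rn]]), n)
    expect_identical(dim(sub$motion[[rn]]), c(n, 6L))
    expect_equal(mean(sub$roi[[rn]]$sn_vta), 100, tolerance = 0.05)
  }
  expect_named(sub$feedback, c("training1", "training2"))
  expect_true(all(abs(sub$feedback$training1$displayed) <= 2, na.rm = TRUE))
})

test_that("non-learner arms differ only in the displayed feedback sign", {
  prm_s <- nonlearner_params(arm = "standard")
  prm_i <- nonlearner_params(arm = "inverted")
  a <- simulate_subject(prm_s, nf_session("s1", arm = "standard"), seed = 9)
  b <- simulate_subject(prm_i, nf_session("s1", arm = "inverted"), seed = 9)
  for (rn in names(a$roi))
    expect_identical(a$roi[[rn]]$sn_vta, b$roi[[rn]]$sn_vta)
  ok <- a$feedback$training1$valid
  expect_identical(b$feedback$training1$displayed[ok],
                   -a$feedback$training1$displayed[ok])
})

test_that("non-learners with flat strategies have null expected DRT", {
  drts <- vapply(1:60, function(i)
    subject_drt(simulate_subject(nonlearner_params(), nf_session(), seed = 100 + i)),
    numeric(1))
  ci <- 1.96 * sd(drts) / sqrt(length(drts))
  expect_lt(abs(mean(drts)), ci + 1e-12)
})

test_that("regulators regulate more strongly in training run 2 than run 1", {
  diffs <- vapply(1:40, function(i) {
    sub <- simulate_subject(regulator_params(), nf_session(), seed = 200 + i)
    con <- vapply(c("training1", "training2"), function(rn) {
      lab <- labels_per_volume(sub$design$runs[[rn]], 4)
      s <- sub$roi[[rn]]$sn_vta
      mean(s[lab == "IMAGINE_REWARD"]) - mean(s[lab == "REST"])
    }, numeric(1))
    con[2] - con[1]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(t.test(diffs)$statistic, 2)
})

test_that("the dlPFC TD coupling declines only for learners", {
  w_reg <- vapply(1:20, function(i)
    simulate_subject(regulator_params(), nf_session(), seed = 300 + i)$agent$td_weights,
    numeric(2))
  w_non <- vapply(1:20, function(i)
    simulate_subject(nonlearner_params(), nf_session(), seed = 300 + i)$agent$td_weights,
    numeric(2))
  # decay is bounded by estimated progress, so w2 never exceeds w0
  expect_true(all(w_non[2, ] <= w_non[1, ] + 1e-12))
  expect_true(all(w_reg[2, ] <= w_reg[1, ] + 1e-12))
  # learners lose substantially more coupling than non-learners
  expect_lt(mean(w_reg[2, ]), mean(w_non[2, ]))
  expect_gt(mean(w_non[2, ]), 0.8 * mean(w_non[1, ]))
})

test_that("MID simulation is deterministic and carries the generative gains", {
  prm <- subject_params(arm = "standard",
                        mid = list(general_gain = 0.8, adaptive_gain = 0.6))
  trials <- mid_trials(10, seed = 3)
  a <- simulate_mid_subject(prm, trials, seed = 4)
  b <- simulate_mid_subject(prm, trials, seed = 4)
  expect_identical(a, b)
  expect_identical(a$truth$general_gain, 0.8)
  expect_length(a$series, a$n_volumes)
  # construction: per-CHF generative slope is larger in the small range
  expect_gt(prm$mid$general_gain + prm$mid$adaptive_gain / 0.4,
            prm$mid$general_gain + prm$mid$adaptive_gain / 2)
})

test_that("null MID gains yield modulator betas centred on zero", {
  prm <- subject_params(arm = "standard",
                        mid = list(general_gain = 0, adaptive_gain = 0))
  betas <- t(vapply(1:60, function(i) {
    trials <- mid_trials(15, seed = 400 + i)
    mid_modulator_betas(simulate_mid_subject(prm, trials, seed = 500 + i))
  }, numeric(2)))
  for (j in 1:2) {
    z <- mean(betas[, j]) / (sd(betas[, j]) / sqrt(nrow(betas)))
    expect_lt(abs(z), 3)
  }
})

test_that("cohorts allocate archetypes deterministically and log the truth", {
  co1 <- simulate_cohort(1, 0, arm = "standard", seed = 3)
  expect_length(co1$subjects, 1)
  expect_identical(nrow(co1$manifest), 1L)
  expect_identical(co1$manifest$learning_rate,
                   co1$subjects[[1]]$truth$agent$learning_rate)
  co <- simulate_cohort(20, 20, arm = "standard", seed = 4)
  expect_identical(sum(co$manifest$archetype == "regulator"), 20L)
  expect_identical(sum(co$manifest$archetype == "non_regulator"), 20L)
  # the DRT distribution spans both signs across the cohort
  drts <- vapply(co$subjects, subject_drt, numeric(1))
  expect_gt(sum(drts > 0), 0)
  expect_gt(sum(drts < 0), 0)
  expect_error(simulate_cohort(0, 0), "empty")
})

test_that("inverted-arm cohorts carry zero contingency by default", {
  co <- simulate_cohort(2, 2, arm = "inverted", seed = 5)
  expect_true(all(co$manifest$contingency == 0))
  expect_true(all(vapply(co$subjects,
                         function(s) s$design$arm == "inverted", logical(1))))
})
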