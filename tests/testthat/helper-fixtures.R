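# shared fixtures: small designs and canned subjects built in code

tiny_run <- function(tr = 2, pairs = 1, dur = 20, lead = 0,
                     run_type = "baseline", polarity = "none") {
  nf_run(run_type, polarity, tr = tr, n_block_pairs = pairs,
         block_duration = dur, lead_in_volumes = lead)
}

# deterministic regulator / non-learner parameter sets
regulator_params <- function(eff = c(0.9, 0.5, 0.3, 0.6, 0.2), alpha = 0.35,
                             arm = "standard", ...) {
  subject_params(agent = agent_params(efficacies = eff, learning_rate = alpha),
                 arm = arm, ...)
}

nonlearner_params <- function(eff = rep(0.5, 5), arm = "standard", ...) {
  subject_params(agent = agent_params(efficacies = eff, learning_rate = 0),
                 arm = arm, ...)
}

# condition series with exact per-condition values, for DRT arithmetic tests
constant_condition_series <- function(run, imagine, rest, lead_in = 0) {
  lab <- labels_per_volume(run, 0)
  out <- numeric(run$n_volumes)
  out[lab == "IMAGINE_REWARD"] <- imagine
  out[lab == "REST"] <- rest
  out[lab == "LEAD_IN"] <- lead_in
  out
}
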