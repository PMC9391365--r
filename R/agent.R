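#' Temporal-difference error
#'
#' The classic TD error \eqn{\delta_t = R_{t+1} + \gamma V(S_{t+1}) - V(S_t)}.
#' With continuous feedback (the displayed smiley height), the next reward and
#' the next state's value collapse into the observed feedback, so the error
#' reduces to the difference between consecutive feedback states; that
#' collapsed form is what [td_error_collapsed()] computes and what the
#' parametric-modulator GLM tracks at TR resolution.
#'
#' @param R_next reward received at the next step.
#' @param V_next value of the next state.
#' @param V_current value of the current state.
#' @param gamma discount factor in (0, 1].
#' @return the TD error (vectorized).
#' @examples
#' td_error(1, 0.5, 0.2, 0.9)        # 1.25
#' td_error_collapsed(0.5, 0.2)      # 0.3
#' @export
td_error <- function(R_next, V_next, V_current, gamma = 1) {
  stopifnot(gamma > 0, gamma <= 1)
  R_next + gamma * V_next - V_current
}

#' @rdname td_error
#' @param feedback_next,feedback_current consecutive feedback states.
#' @export
td_error_collapsed <- function(feedback_next, feedback_current) {
  feedback_next - feedback_current
}

#' Parameters of the strategy-learning agent
#'
#' The mental-strategy repertoire is modelled as a K-armed problem: each
#' strategy k has an (unknown to the agent) regulation efficacy e_k in [0, 1].
#' At every IMAGINE_REWARD block the agent draws a strategy by softmax over its
#' current values and, after perceiving the block's feedback, updates the
#' chosen strategy's value with a delta rule. `learning_rate = 0` defines a
#' non-learner whose values never move. `contingency` scales the effective
#' learning rate and models how informative the displayed feedback is about
#' the strategy-outcome association; the inverted control arm is simulated as
#' non-contingent (`contingency = 0`) by default, because sign-reversed
#' feedback breaks the learnable association between imagery and display.
#'
#' @param n_strategies number of strategies K.
#' @param efficacies per-strategy regulation efficacies in [0, 1]; default
#'   equally spaced over [0.1, 0.9].
#' @param learning_rate delta-rule learning rate alpha >= 0.
#' @param temperature softmax temperature tau > 0 (lower = greedier).
#' @param discount TD discount gamma in (0, 1].
#' @param contingency multiplier in [0, 1] on the effective learning rate.
#' @param prior_sd spread of the agent's initial strategy values. Subjects
#'   start with an idiosyncratic preference among their strategies (imagery
#'   they find vivid), unrelated to true regulation efficacy; a non-learner
#'   therefore keeps the same preferred imagery at baseline and transfer,
#'   which is what makes the transfer-minus-baseline difference a clean null
#'   for non-learners.
#' @param explore_factor multiplier on the softmax temperature during
#'   feedback (training) runs. Participants are encouraged to try out
#'   different strategies while feedback is available; without feedback they
#'   fall back on their (possibly updated) preferences at the base
#'   temperature.
#' @param novelty_bonus selection bonus added to not-yet-tried strategies
#'   during training runs (directed exploration: participants were explicitly
#'   encouraged to try the example strategies). The bonus only affects choice
#'   while feedback is available; it never enters the learned values, so
#'   baseline and transfer choices reflect values alone.
#' @return list of class `agent_params`.
#' @export
agent_params <- function(n_strategies = 5, efficacies = NULL,
                         learning_rate = 0.3, temperature = 0.15,
                         discount = 1, contingency = 1, prior_sd = 0,
                         explore_factor = 1, novelty_bonus = 1.5) {
  if (is.null(efficacies))
    efficacies <- seq(0.1, 0.9, length.out = n_strategies)
  stopifnot(length(efficacies) == n_strategies,
            all(efficacies >= 0 & efficacies <= 1),
            learning_rate >= 0, temperature > 0,
            discount > 0, discount <= 1,
            contingency >= 0, contingency <= 1, prior_sd >= 0,
            explore_factor >= 1, novelty_bonus >= 0)
  structure(list(n_strategies = n_strategies, efficacies = efficacies,
                 learning_rate = learning_rate, temperature = temperature,
                 discount = discount, contingency = contingency,
                 prior_sd = prior_sd, explore_factor = explore_factor,
                 novelty_bonus = novelty_bonus),
            class = "agent_params")
}

#' Softmax strategy selection
#'
#' Draws a strategy index with probabilities proportional to
#' \eqn{\exp(V_k/\tau)}. Uses the current RNG stream, so a seed set by the
#' caller makes the choice sequence deterministic.
#'
#' @param values numeric vector of strategy values.
#' @param temperature softmax temperature (> 0).
#' @return integer strategy index.
#' @export
agent_select <- function(values, temperature) {
  stopifnot(temperature > 0)
  z <- values / temperature
  p <- exp(z - max(z))
  sample.int(length(values), 1L, prob = p / sum(p))
}

#' Block-level value update
#'
#' Delta rule on the chosen strategy only:
#' \eqn{V_c \leftarrow V_c + \alpha (R_{block} - V_c)}, where the block reward
#' is the perceived mean displayed feedback for the block.
#'
#' @param values current strategy values.
#' @param chosen index of the strategy used in the block.
#' @param feedback perceived block feedback (mean displayed value).
#' @param alpha effective learning rate.
#' @return updated value vector.
#' @export
agent_update <- function(values, chosen, feedback, alpha) {
  stopifnot(chosen >= 1, chosen <= length(values), alpha >= 0)
  values[chosen] <- values[chosen] + alpha * (feedback - values[chosen])
  values
}
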