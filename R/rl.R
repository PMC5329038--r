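#' Parameters of the reinforcement-learning model
#'
#' Extends the utility-learning parameters with the initial entry utilities
#' of the three strategies and the chain timing used for reward discounting.
#'
#' @inheritParams utility_params
#' @param initial_utilities Numeric length-3 vector: utilities of the zero-,
#'   first- and second-order strategy entry productions (100, 25, 5): a lot
#'   of experience with zero-order reasoning, more with first- than with
#'   second-order.
#' @param chain_lengths Integer length-3 vector: productions per strategy
#'   chain beyond the two shared fact-retrieval steps (1, 2, 3, mirroring the
#'   nesting depth of the reasoning).
#' @param step_time Simulated seconds per production firing, used only to
#'   compute the firing-to-reward delays that discount rewards. The committed
#'   calibrated value is 5.5 s per reasoning step (seconds-scale pace of a
#'   verbally administered task; see the methods vignette).
#'
#' @return A list of class `rl_params` (also a valid `utility_params`).
#' @export
rl_params <- function(alpha = 0.2, s_util = 3,
                      reward_correct = 20, reward_wrong = 0,
                      initial_utilities = c(100, 25, 5),
                      chain_lengths = c(1L, 2L, 3L),
                      step_time = 5.5) {
  p <- utility_params(alpha = alpha, s_util = s_util,
                      reward_correct = reward_correct,
                      reward_wrong = reward_wrong)
  stopifnot(length(initial_utilities) == 3, length(chain_lengths) == 3,
            all(chain_lengths >= 1), step_time > 0)
  p$initial_utilities <- as.numeric(initial_utilities)
  p$chain_lengths <- as.integer(chain_lengths)
  p$step_time <- step_time
  class(p) <- c("rl_params", class(p))
  p
}

#' Initialize the reinforcement-learning model
#'
#' Builds the procedural memory: two shared fact-retrieval productions
#' (never rewarded -- they are common to every strategy), one entry
#' production per strategy level carrying the initial utilities 100/25/5,
#' and the chain-member productions of each strategy (utility 0).
#'
#' @param params An [rl_params()].
#' @param facts Scenario facts.
#' @return A list of class `rl_state`.
#' @export
#' @examples
#' st <- rl_init()
#' vapply(st$productions[c("strategy0", "strategy1", "strategy2")],
#'        `[[`, numeric(1), "utility")
rl_init <- function(params = rl_params(), facts = initial_facts()) {
  prods <- list(
    retrieve_action_fact = production("retrieve_action_fact", 0),
    request_latest_fact  = production("request_latest_fact", 0)
  )
  for (k in 0:2) {
    entry_id <- paste0("strategy", k)
    prods[[entry_id]] <- production(entry_id, params$initial_utilities[k + 1],
                                    strategy_level = k)
    len <- params$chain_lengths[k + 1]
    if (len > 1) for (j in 2:len) {
      id <- paste0(entry_id, "_step", j)
      prods[[id]] <- production(id, 0, strategy_level = k)
    }
  }
  structure(
    list(productions = prods, params = params, facts = facts,
         question = fb_question(2, facts), clock = 0, trial_index = 0L,
         firing_log = list()),
    class = "rl_state"
  )
}

# ids of the chain productions of level k, entry first
chain_ids <- function(params, k) {
  entry <- paste0("strategy", k)
  len <- params$chain_lengths[k + 1]
  c(entry, if (len > 1) paste0(entry, "_step", 2:len))
}

#' Run one repetition of the task under the reinforcement-learning model
#'
#' One trial: (1) the two shared fact-retrieval productions fire (they
#' receive no reward); (2) conflict resolution selects among the three
#' strategy entry productions by utility plus logistic noise; (3) the
#' selected strategy's chain fires, one production per `step_time` seconds,
#' each firing logged; (4) the level's answer is derived and evaluated;
#' (5) the reward (20 if correct, 0 if wrong) arrives at answer time and is
#' propagated back to every logged firing, discounted by the time elapsed
#' since that firing -- a zero reward therefore acts as a punishment; (6) the
#' firing log is cleared.
#'
#' @param state An [rl_init()] state.
#' @return A list with `record` (repetition, level used, answer, feedback,
#'   and the three entry utilities at choice time) and `state` (updated).
#' @export
rl_trial <- function(state) {
  params <- state$params
  dt <- params$step_time
  t0 <- state$clock

  ## shared steps 1-2 fire at t0 and t0 + dt; not logged for reward
  t_entry <- t0 + 2 * dt

  entries <- state$productions[paste0("strategy", 0:2)]
  snap <- vapply(entries, `[[`, numeric(1), "utility")
  names(snap) <- paste0("U_level", 0:2)

  sel <- select_production(unname(entries), params)
  k <- sel$strategy_level

  ids <- chain_ids(params, k)
  fire_times <- t_entry + dt * (seq_along(ids) - 1)
  log <- Map(firing_event, ids, fire_times)
  now <- fire_times[length(fire_times)] + dt  # answer follows the last firing

  answer <- answer_with_level(k, state$facts)
  feedback <- evaluate_answer(answer, state$question, state$facts)
  R <- if (feedback == "correct") params$reward_correct else params$reward_wrong

  state$productions <- apply_reward(state$productions, log, R, now, params)
  state$firing_log <- list()  # propagation window closed at each reward
  state$clock <- now
  state$trial_index <- state$trial_index + 1L

  record <- c(list(repetition = state$trial_index, level_used = k,
                   answer = answer, feedback = feedback), as.list(snap))
  list(record = record, state = state)
}
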