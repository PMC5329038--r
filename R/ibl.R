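#' Parameters of the instance-based learning model
#'
#' Extends the declarative-memory parameters with the task-repetition
#' timing and the initialized activation of the zero-order strategy chunk.
#'
#' @inheritParams memory_params
#' @param trial_interval Simulated seconds between task repetitions. Together
#'   with `s_act` this is one of the two committed calibration constants (see
#'   the methods vignette); only its logarithm enters activation differences,
#'   so it acts as a unitless decay-pacing constant rather than a physical
#'   claim about session timing.
#' @param init_activation Activation of the zero-order strategy chunk at the
#'   first repetition (6): children arrive with extensive zero-order
#'   experience. Realized as a constant `base_offset` on a chunk with one
#'   presentation created at time 0, so that decay erodes it over repetitions.
#'
#' @return A list of class `ibl_params` (also a valid `memory_params`).
#' @export
ibl_params <- function(d = 0.5, s_act = 0.23, tau = -5,
                       trial_interval = 0.002, init_activation = 6) {
  p <- memory_params(d = d, s_act = s_act, tau = tau)
  stopifnot(trial_interval > 0)
  p$trial_interval <- trial_interval
  p$init_activation <- init_activation
  class(p) <- c("ibl_params", class(p))
  p
}

#' Initialize the instance-based learning model
#'
#' Declarative memory starts with the five story facts plus a single
#' zero-order strategy chunk whose activation at the first repetition equals
#' `init_activation`; no first- or second-order strategy chunk exists yet.
#'
#' @param params An [ibl_params()].
#' @param facts Scenario facts (default: the packaged prototype).
#' @return A list of class `ibl_state`.
#' @export
#' @examples
#' st <- ibl_init(ibl_params(s_act = 0))
#' st$clock
ibl_init <- function(params = ibl_params(), facts = initial_facts()) {
  store <- encode_facts(dm_store(), facts, now = 0)
  ## offset chosen so that B(now = trial_interval) = init_activation for
  ## n = 1, creation at 0: B = ln(1/(1-d)) - d ln(I) + offset
  offset <- params$init_activation -
    (log(1 / (1 - params$d)) - params$d * log(params$trial_interval))
  store <- dm_encode(store,
                     chunk("strategy", list(level = 0L), base_offset = offset),
                     now = 0)
  structure(
    list(store = store, facts = facts, params = params,
         question = fb_question(2, facts), clock = 0, trial_index = 0L),
    class = "ibl_state"
  )
}

# noise-free activations of the strategy chunks by level at time `now`
# (NA for levels whose chunk does not exist yet)
strategy_activations <- function(store, now, params) {
  out <- c(NA_real_, NA_real_, NA_real_)
  idx <- which(store$kind == "strategy")
  if (length(idx)) {
    lev <- vapply(store$slots[idx], function(s) as.integer(s$level), integer(1))
    out[lev + 1L] <- dm_activation(store, idx, now, params)
  }
  names(out) <- paste0("B_level", 0:2)
  out
}

#' Run one repetition of the task under the instance-based learning model
#'
#' One trial: (1) the shared fact-retrieval steps recall the latest
#' relocation; (2) the strategy chunk with the highest noisy activation is
#' retrieved; (3) that level's answer is derived and (4) evaluated against
#' the second-order question; (5) on a wrong answer a strategy chunk one
#' level above the one just used (capped at level 2) is encoded -- created,
#' or merged with the existing identical chunk; on a correct answer the
#' successful chunk is strengthened. Retrieval itself never strengthens a
#' chunk; only the feedback-driven encoding does. The clock advances by one
#' `trial_interval` per repetition.
#'
#' @param state An [ibl_init()] state.
#' @return A list with `record` (one trial's data: repetition, level used,
#'   answer, feedback, and each strategy chunk's noise-free activation at
#'   choice time) and `state` (the updated model state).
#' @export
ibl_trial <- function(state) {
  params <- state$params
  now <- state$clock + params$trial_interval

  ## steps 1-2: retrieve a relocation fact; if not the latest, request it
  f1 <- dm_retrieve(state$store, retrieval_request("fact", verb = "put"),
                    now, params)
  latest <- latest_location_fact(state$facts)
  if (is.null(f1) || as.integer(f1$slots$time_index) != latest$time_index) {
    dm_retrieve(state$store,
                retrieval_request("fact", verb = "put",
                                  time_index = latest$time_index),
                now, params)
  }

  ## snapshot of the noise-free activations that govern this choice
  snap <- strategy_activations(state$store, now, params)

  ## step 3: strategy retrieval by highest noisy activation
  strat <- dm_retrieve(state$store, retrieval_request("strategy"), now, params)
  if (is.null(strat)) {
    stop("below-threshold error: no strategy chunk retrievable", call. = FALSE)
  }
  k <- as.integer(strat$slots$level)

  ## step 4: answer and feedback
  answer <- answer_with_level(k, state$facts)
  feedback <- evaluate_answer(answer, state$question, state$facts)

  ## step 5: strengthen on success, or add/strengthen the next level up
  enc_level <- if (feedback == "correct") k else min(k + 1L, 2L)
  state$store <- dm_encode(state$store,
                           chunk("strategy", list(level = enc_level)),
                           now = now)

  state$clock <- now
  state$trial_index <- state$trial_index + 1L
  record <- c(list(repetition = state$trial_index, level_used = k,
                   answer = answer, feedback = feedback), as.list(snap))
  list(record = record, state = state)
}
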