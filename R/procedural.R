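#' Utility-learning parameters
#'
#' Parameters of the procedural (reinforcement-learning) substrate: the
#' utility learning rate, the utility noise scale, and the rewards attached
#' to correct and wrong answers.
#'
#' @param alpha Learning rate in (0, 1]; ACT-R default 0.2.
#' @param s_util Scale of the zero-mean logistic noise added to utilities at
#'   conflict resolution, `>= 0`; the modeled value is 3.
#' @param reward_correct Reward delivered on a correct answer (20).
#' @param reward_wrong Reward delivered on a wrong answer (0). With a zero
#'   reward the effective, time-discounted reward is negative: a punishment.
#'
#' @return A list of class `utility_params`.
#' @export
utility_params <- function(alpha = 0.2, s_util = 3,
                           reward_correct = 20, reward_wrong = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha <= 1)
  if (!is.numeric(s_util) || length(s_util) != 1 || s_util < 0) {
    stop("`s_util` must be a single non-negative number", call. = FALSE)
  }
  structure(list(alpha = alpha, s_util = s_util,
                 reward_correct = reward_correct,
                 reward_wrong = reward_wrong),
            class = "utility_params")
}

#' Create a production rule
#'
#' A condition-action rule in procedural memory, carrying a utility value
#' subject to reward learning. `strategy_level` tags the theory-of-mind
#' strategy a rule belongs to (`NA` for shared or chain-internal rules).
#'
#' @param id Identifier string.
#' @param utility Initial utility (finite real).
#' @param strategy_level Integer 0..2 or `NA`.
#' @return A list of class `production`.
#' @export
#' @examples
#' production("strategy0", utility = 100, strategy_level = 0)
production <- function(id, utility = 0, strategy_level = NA) {
  stopifnot(is.character(id), length(id) == 1, is.finite(utility))
  if (!is.na(strategy_level)) stopifnot(strategy_level %in% 0:2)
  structure(list(id = id, utility = as.numeric(utility),
                 strategy_level = strategy_level),
            class = "production")
}

#' Select a production by noisy utility maximization
#'
#' Returns the candidate maximizing `utility + logistic noise` with scale
#' `params$s_util` (ACT-R conflict resolution). With `s_util = 0` this is the
#' deterministic utility argmax. Randomness uses R's global RNG.
#'
#' @param candidates Non-empty list of [production()] objects.
#' @param params A [utility_params()].
#' @return The selected [production()].
#' @export
#' @examples
#' set.seed(1)
#' ps <- list(production("p0", 100, 0), production("p1", 25, 1))
#' select_production(ps, utility_params(s_util = 0))$id  # "p0"
select_production <- function(candidates, params = utility_params()) {
  if (length(candidates) == 0) {
    stop("conflict-resolution error: empty candidate list", call. = FALSE)
  }
  u <- vapply(candidates, `[[`, numeric(1), "utility")
  if (params$s_util > 0) u <- u + stats::rlogis(length(u), 0, params$s_util)
  candidates[[which.max(u)]]
}

#' A production-firing event
#'
#' Records that a production fired at a given simulated time, for later
#' reward propagation.
#'
#' @param production_id Identifier of the fired production.
#' @param fire_time Simulated seconds.
#' @return A list of class `firing_event`.
#' @export
firing_event <- function(production_id, fire_time) {
  structure(list(production_id = production_id,
                 fire_time = as.numeric(fire_time)),
            class = "firing_event")
}

#' Propagate a time-discounted reward to fired productions
#'
#' Implements the utility-learning update `U <- U + alpha * (R_eff - U)`
#' where, for a production that fired at time `t`, the effective reward is
#' `R_eff = reward - (now - t)`: the assigned reward minus the time passed
#' since the firing, so that more distant firings receive less reward. With
#' `reward = 0` the effective reward is negative (punishment). The
#' propagation window is all firings logged since the previous reward; the
#' caller clears the log afterwards.
#'
#' @param productions Named list of [production()] objects (names = ids).
#' @param firing_log List of [firing_event()]s since the previous reward.
#' @param reward Assigned reward value `R`.
#' @param now Simulated seconds at which the reward arrives; no logged firing
#'   may be later than `now`.
#' @param params A [utility_params()].
#' @return The updated named list of productions.
#' @export
#' @examples
#' ps <- list(strategy0 = production("strategy0", 100, 0))
#' log <- list(firing_event("strategy0", 9))
#' apply_reward(ps, log, reward = 0, now = 10)$strategy0$utility  # 79.8
apply_reward <- function(productions, firing_log, reward, now,
                         params = utility_params()) {
  for (ev in firing_log) {
    if (ev$fire_time > now) {
      stop("clock error: firing event later than reward time", call. = FALSE)
    }
    effective <- reward - (now - ev$fire_time)
    p <- productions[[ev$production_id]]
    if (is.null(p)) {
      stop("unknown production id in firing log: ", ev$production_id,
           call. = FALSE)
    }
    p$utility <- p$utility + params$alpha * (effective - p$utility)
    productions[[ev$production_id]] <- p
  }
  productions
}
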