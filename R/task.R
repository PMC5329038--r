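#' Construct a story-fact table
#'
#' Validates and returns a set of story facts for a second-order false-belief
#' scenario. Each fact is one row: an agent either `put` an object somewhere
#' at a time index, or `saw` / `did-not-see` another agent at that time.
#'
#' @param subject Character: acting agent.
#' @param verb Character: one of `"put"`, `"saw"`, `"did-not-see"`.
#' @param object Character: the item moved (for `put`) or the agent observed
#'   (for `saw` / `did-not-see`).
#' @param location Character location for `put` facts; `"none"` otherwise.
#' @param time_index Integer time index; larger means later.
#' @return A `data.frame` of class `story_facts`.
#' @export
story_facts <- function(subject, verb, object, location, time_index) {
  f <- data.frame(subject = subject, verb = verb, object = object,
                  location = location, time_index = as.integer(time_index),
                  stringsAsFactors = FALSE)
  stopifnot(all(f$verb %in% c("put", "saw", "did-not-see")))
  if (any(f$verb == "put" & f$location == "none")) {
    stop("a `put` fact must name a location", call. = FALSE)
  }
  if (any(f$verb != "put" & f$location != "none")) {
    stop("`saw`/`did-not-see` facts carry no location", call. = FALSE)
  }
  class(f) <- c("story_facts", "data.frame")
  f
}

#' The five story facts of the three-locations prototype
#'
#' The packaged scenario: Murat puts the chocolate into the drawer (t1); in
#' his absence -- but secretly watched by him -- Ayla moves it to the toy box
#' (t2); finally the mother moves it to the TV stand (t3), seen by no one.
#' The second-order question is "Where does Ayla think that Murat will look
#' for the chocolate?": Ayla, unaware that Murat saw her, should expect him
#' to search the drawer.
#'
#' A copy of this table is shipped as JSON in
#' `system.file("extdata", "story_three_locations.json", package = "tomsim")`.
#'
#' @return A `story_facts` data.frame with five rows.
#' @export
#' @examples
#' initial_facts()
initial_facts <- function() {
  story_facts(
    subject    = c("Murat", "Ayla",    "Murat", "Ayla",        "mother"),
    verb       = c("put",   "put",     "saw",   "did-not-see", "put"),
    object     = c("chocolate", "chocolate", "Ayla", "Murat",  "chocolate"),
    location   = c("drawer", "toy_box", "none",  "none",       "tv_stand"),
    time_index = c(1L,       2L,        2L,      2L,           3L)
  )
}

#' Load a scenario fact table from JSON
#'
#' Alternative scenarios with the same schema (permuted agents, objects,
#' locations) are accepted by all task operations; the three-locations
#' prototype is the packaged default.
#'
#' @param path Path to a JSON file as written by [save_scenario()].
#' @return A `story_facts` data.frame.
#' @export
load_scenario <- function(path) {
  f <- jsonlite::fromJSON(path)
  story_facts(f$subject, f$verb, f$object, f$location, f$time_index)
}

#' Save a scenario fact table to JSON
#' @param facts A `story_facts` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(facts, path) {
  jsonlite::write_json(as.data.frame(facts), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' The latest object-relocation fact
#'
#' Returns the `put` fact with the greatest time index: the reasoning steps
#' shared by both models first retrieve a fact with an action verb and, if it
#' is not the latest one, request the latest.
#'
#' @param facts A `story_facts` data.frame with at least one `put` fact.
#' @return A one-row `story_facts` data.frame.
#' @export
latest_location_fact <- function(facts) {
  puts <- facts[facts$verb == "put", , drop = FALSE]
  if (nrow(puts) == 0) {
    stop("task-state error: no `put` fact present", call. = FALSE)
  }
  puts[which.max(puts$time_index), , drop = FALSE]
}

# the two observer roles of the scenario, derived from the schema: in
# "A did-not-see B", B is the agent the first-order question is about and
# (A, B) is the second-order perspective chain
scenario_roles <- function(facts) {
  dns <- facts[facts$verb == "did-not-see", , drop = FALSE]
  if (nrow(dns) != 1) {
    stop("task-state error: scenario must contain exactly one did-not-see fact",
         call. = FALSE)
  }
  list(outer = dns$subject[1], inner = dns$object[1],
       blind_time = dns$time_index[1])
}

# where `agent` last saw the object: an agent witnesses a relocation if they
# performed it themselves or saw the actor at that time ("seeing leads to
# knowing"; "people search where they last saw the object")
last_seen_location <- function(agent, facts) {
  puts <- facts[facts$verb == "put", , drop = FALSE]
  witnessed <- vapply(seq_len(nrow(puts)), function(i) {
    p <- puts[i, ]
    p$subject == agent ||
      any(facts$verb == "saw" & facts$subject == agent &
            facts$object == p$subject & facts$time_index == p$time_index)
  }, logical(1))
  if (!any(witnessed)) return(NA_character_)
  w <- puts[witnessed, , drop = FALSE]
  w$location[which.max(w$time_index)]
}

#' Derive the answer a k-th-order strategy gives
#'
#' Applies zero-, first-, or second-order theory-of-mind reasoning to the
#' story facts, using the task-independent knowledge both models share:
#' the location of an object changes by an action toward it; seeing leads to
#' knowing; people search for an object where they last saw it; and other
#' people reason "like me", applied recursively.
#'
#' * `k = 0`: answer from reality -- the location of the latest relocation.
#' * `k = 1`: answer from the inner observer's belief -- where that agent
#'   last saw the object.
#' * `k = 2`: apply the first-order procedure from the outer observer's
#'   perspective: if she did not see the inner observer witness the
#'   relocation, she expects him to search where he himself put the object;
#'   otherwise her attribution coincides with first-order reasoning.
#'
#' For the packaged prototype this yields `tv_stand` (k = 0), `toy_box`
#' (k = 1) and `drawer` (k = 2).
#'
#' @param k Integer reasoning level, 0..2.
#' @param facts A `story_facts` data.frame (default: the packaged prototype).
#' @return A location string (an `Answer`).
#' @export
#' @examples
#' vapply(0:2, answer_with_level, character(1))
answer_with_level <- function(k, facts = initial_facts()) {
  if (!is.numeric(k) || length(k) != 1 || !(k %in% 0:2)) {
    stop("level error: k must be 0, 1 or 2", call. = FALSE)
  }
  if (k == 0) return(latest_location_fact(facts)$location)
  roles <- scenario_roles(facts)
  if (k == 1) {
    loc <- last_seen_location(roles$inner, facts)
    if (is.na(loc)) stop("task-state error: missing required fact", call. = FALSE)
    return(loc)
  }
  ## k == 2: did the outer observer see the inner observer at the time of the
  ## secret relocation? If not, she expects him to search where he himself
  ## last put the object.
  saw_inner <- any(facts$verb == "saw" & facts$subject == roles$outer &
                     facts$object == roles$inner &
                     facts$time_index == roles$blind_time)
  if (saw_inner) return(last_seen_location(roles$inner, facts))
  own <- facts[facts$verb == "put" & facts$subject == roles$inner, , drop = FALSE]
  if (nrow(own) == 0) stop("task-state error: missing required fact", call. = FALSE)
  own$location[which.max(own$time_index)]
}

#' A false-belief question of a given order
#'
#' @param order Integer 0..2.
#' @param facts Scenario facts used to derive the perspective chain.
#' @return A list of class `fb_question` with the order and perspective
#'   chain (empty for order 0, `inner` agent for order 1, `outer, inner` for
#'   order 2).
#' @export
#' @examples
#' fb_question(2)
fb_question <- function(order = 2, facts = initial_facts()) {
  stopifnot(order %in% 0:2)
  roles <- scenario_roles(facts)
  chain <- switch(as.character(order),
                  "0" = character(0),
                  "1" = roles$inner,
                  "2" = c(roles$outer, roles$inner))
  structure(list(order = as.integer(order), chain = chain),
            class = "fb_question")
}

#' Evaluate an answer against a question
#'
#' The feedback is bare: `"correct"` or `"wrong"`, with no further
#' explanation -- exactly what the simulated child receives.
#'
#' @param answer A location string or `"dont_know"`.
#' @param question A [fb_question()].
#' @param facts Scenario facts.
#' @return `"correct"` or `"wrong"`.
#' @export
#' @examples
#' evaluate_answer("drawer", fb_question(2))   # "correct"
#' evaluate_answer("tv_stand", fb_question(2)) # "wrong"
evaluate_answer <- function(answer, question, facts = initial_facts()) {
  truth <- answer_with_level(question$order, facts)
  if (identical(answer, truth)) "correct" else "wrong"
}

#' Classify an answer by the reasoning level it reveals
#'
#' Maps an answer location back to the strategy level that produces it
#' (for the prototype: TV stand -> 0, toy box -> 1, drawer -> 2);
#' `"dont_know"` maps to `"dont_know"`.
#'
#' @param answer A location string or `"dont_know"`.
#' @param facts Scenario facts.
#' @return `0`, `1`, `2` (integer) or the string `"dont_know"`; `NA` if the
#'   location matches no level's answer.
#' @export
#' @examples
#' classify_answer("toy_box")  # 1
classify_answer <- function(answer, facts = initial_facts()) {
  if (identical(answer, "dont_know")) return("dont_know")
  for (k in 0:2) if (identical(answer_with_level(k, facts), answer)) {
    return(as.integer(k))
  }
  NA_integer_
}

# encode the story facts of a scenario into a declarative-memory store
encode_facts <- function(store, facts, now = 0) {
  for (i in seq_len(nrow(facts))) {
    f <- facts[i, ]
    ch <- chunk("fact",
                list(subject = f$subject, verb = f$verb, object = f$object,
                     location = f$location, time_index = f$time_index),
                creation_time = now)
    store <- dm_encode(store, ch, now = now)
  }
  store
}
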