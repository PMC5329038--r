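# shared full-size cohorts (100 children x 100 repetitions, base seed 42,
# committed calibrated parameters), computed once per test run
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(model) {
  if (is.null(.cohort_cache[[model]])) {
    .cohort_cache[[model]] <- run_cohort(model, n_children = 100, n_reps = 100,
                                         base_seed = 42, return_trials = TRUE)
  }
  .cohort_cache[[model]]
}

# a scenario structurally equivalent to the prototype with permuted agent,
# object and location names, for task-logic property tests
permuted_scenario <- function() {
  story_facts(
    subject    = c("Jan",  "Mila", "Jan", "Mila",        "father"),
    verb       = c("put",  "put",  "saw", "did-not-see", "put"),
    object     = c("marble", "marble", "Mila", "Jan",    "marble"),
    location   = c("basket", "shelf", "none", "none",    "cupboard"),
    time_index = c(1L, 2L, 2L, 2L, 3L)
  )
}
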