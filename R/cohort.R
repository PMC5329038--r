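#' Simulate one virtual child
#'
#' Runs `n_reps` repetitions of the second-order false-belief task from a
#' fresh model state, driven by a child-specific seed. All randomness
#' (retrieval noise or utility noise) is drawn from R's RNG seeded with
#' `seed`, so identical seeds give bitwise-identical trajectories.
#'
#' @param model `"ibl"` (instance-based learning) or `"rl"`
#'   (reinforcement learning).
#' @param n_reps Number of task repetitions, `>= 1`.
#' @param seed Integer seed for this child.
#' @param params An [ibl_params()] or [rl_params()] matching `model`
#'   (defaults are the committed calibrated parameters).
#' @param facts Scenario facts.
#' @return A `data.frame` with one row per repetition: `repetition`,
#'   `level_used`, `answer`, `feedback`, and the three noise-free
#'   subsymbolic snapshots (`B_level0..2` for IBL, `U_level0..2` for RL)
#'   taken at choice time.
#' @export
#' @examples
#' head(run_child("ibl", n_reps = 3, seed = 1, params = ibl_params(s_act = 0)))
run_child <- function(model = c("ibl", "rl"), n_reps, seed,
                      params = NULL, facts = initial_facts()) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1)
  set.seed(as.integer(seed))
  if (model == "ibl") {
    if (is.null(params)) params <- ibl_params()
    state <- ibl_init(params, facts)
    step <- ibl_trial
  } else {
    if (is.null(params)) params <- rl_params()
    state <- rl_init(params, facts)
    step <- rl_trial
  }
  records <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    out <- step(state)
    records[[r]] <- out$record
    state <- out$state
  }
  do.call(rbind, lapply(records, function(x) {
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
}

# deterministic, order-invariant per-child seed derivation: a fixed-length
# draw under the base seed, so cohorts are reproducible and children
# independent of each other and of cohort size ordering
child_seeds <- function(base_seed, n_children) {
  set.seed(as.integer(base_seed))
  sample.int(.Machine$integer.max - 1L, n_children)
}

#' Simulate a cohort of virtual children
#'
#' Runs `n_children` independent [run_child()] trajectories (child `i`'s
#' seed is derived deterministically from `base_seed` and `i`) and
#' aggregates them into per-repetition strategy-use proportions, wrong-answer
#' counts by level, and mean noise-free subsymbolic traces.
#'
#' @inheritParams run_child
#' @param n_children Number of virtual children (default 100).
#' @param n_reps Repetitions per child (default 100).
#' @param base_seed Integer base seed for the cohort.
#' @param return_trials If `TRUE`, attach the full per-trial table as
#'   `$trials`.
#' @return An object of class `cohort_summary`: a list with `by_rep` (a
#'   `data.frame` with, per repetition, counts `n_level0..2`, proportions
#'   `p_level0..2` summing to 1, wrong-answer counts `n_wrong_level0..2`,
#'   and mean snapshot columns `mean_<snap>`), and `meta` (model kind,
#'   cohort size, seed, parameters).
#' @export
#' @examples
#' cs <- run_cohort("ibl", n_children = 5, n_reps = 10, base_seed = 42)
#' cs$by_rep$p_level0 + cs$by_rep$p_level1 + cs$by_rep$p_level2
run_cohort <- function(model = c("ibl", "rl"), n_children = 100,
                       n_reps = 100, base_seed = 42, params = NULL,
                       facts = initial_facts(), return_trials = FALSE) {
  model <- match.arg(model)
  stopifnot(n_children >= 1)
  seeds <- child_seeds(base_seed, n_children)
  trials <- vector("list", n_children)
  for (i in seq_len(n_children)) {
    tr <- run_child(model, n_reps, seeds[i], params, facts)
    tr$child_id <- i
    trials[[i]] <- tr
  }
  trials <- do.call(rbind, trials)
  snap_cols <- grep("^(B|U)_level", names(trials), value = TRUE)

  by_rep <- data.frame(repetition = seq_len(n_reps))
  for (k in 0:2) {
    used <- matrix(trials$level_used == k, nrow = n_reps)
    wrong <- matrix(trials$level_used == k & trials$feedback == "wrong",
                    nrow = n_reps)
    by_rep[[paste0("n_level", k)]] <- rowSums(used)
    by_rep[[paste0("p_level", k)]] <- rowMeans(used)
    by_rep[[paste0("n_wrong_level", k)]] <- rowSums(wrong)
  }
  for (sc in snap_cols) {
    m <- matrix(trials[[sc]], nrow = n_reps)
    by_rep[[paste0("mean_", sc)]] <- rowMeans(m, na.rm = TRUE)
  }

  out <- structure(
    list(by_rep = by_rep,
         meta = list(model = model, n_children = n_children,
                     n_reps = n_reps, base_seed = as.integer(base_seed),
                     params = unclass(if (is.null(params)) {
                       if (model == "ibl") ibl_params() else rl_params()
                     } else params))),
    class = "cohort_summary"
  )
  if (return_trials) out$trials <- trials
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<cohort_summary: %s model, %d children x %d repetitions, seed %d>\n",
              m$model, m$n_children, m$n_reps, m$base_seed))
  stab <- which(x$by_rep$p_level2 > 0.5)[1]
  if (!is.na(stab)) {
    cat(sprintf("  second-order strategy first used by >50%% of children at repetition %d\n",
                stab))
  }
  invisible(x)
}

#' Locate a persistent crossover between two cohort series
#'
#' Returns the smallest repetition `r` at which `series_a` strictly exceeds
#' `series_b` and stays at or above it for the following `persist`
#' repetitions -- the persistence guard operationalizes "around the r-th
#' repetition" against sampling noise.
#'
#' @param summary A [run_cohort()] summary.
#' @param series_a,series_b Column names in `summary$by_rep` (e.g.
#'   `"mean_B_level1"`, `"mean_B_level0"`, `"p_level2"`).
#' @param persist Number of following repetitions the ordering must hold
#'   (default 5). Repetitions too close to the end of the series to be
#'   checked over the full window are still eligible using the remaining
#'   repetitions.
#' @return The repetition index, or `NA` if the series never cross.
#' @export
#' @examples
#' cs <- run_cohort("ibl", n_children = 10, n_reps = 30, base_seed = 42)
#' crossover_repetition(cs, "mean_B_level1", "mean_B_level0")
crossover_repetition <- function(summary, series_a, series_b, persist = 5) {
  br <- summary$by_rep
  for (nm in c(series_a, series_b)) {
    if (!nm %in% names(br)) {
      stop("query error: unknown series `", nm, "`", call. = FALSE)
    }
  }
  a <- br[[series_a]]
  b <- br[[series_b]]
  n <- length(a)
  for (r in seq_len(n)) {
    w <- r:min(n, r + persist)
    if (!is.na(a[r]) && !is.na(b[r]) && a[r] > b[r] &&
        all(a[w] >= b[w], na.rm = TRUE)) {
      return(r)
    }
  }
  NA_integer_
}

#' Write / read a cohort summary (JSON)
#'
#' The summary round-trips losslessly (to floating-point precision) through
#' this JSON serialization.
#'
#' @param summary A `cohort_summary`.
#' @param path File path.
#' @return `path` invisibly (write); a `cohort_summary` (read).
#' @export
write_cohort_summary <- function(summary, path) {
  payload <- list(meta = summary$meta, by_rep = summary$by_rep)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_summary
#' @export
read_cohort_summary <- function(path) {
  payload <- jsonlite::fromJSON(path)
  structure(list(by_rep = as.data.frame(payload$by_rep),
                 meta = payload$meta),
            class = "cohort_summary")
}

#' Write the per-trial table of a cohort to CSV
#'
#' @param summary A `cohort_summary` created with `return_trials = TRUE`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(summary, path) {
  if (is.null(summary$trials)) {
    stop("summary has no trials; run run_cohort(return_trials = TRUE)",
         call. = FALSE)
  }
  cols <- c("child_id", setdiff(names(summary$trials), "child_id"))
  utils::write.csv(summary$trials[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Plot a cohort trajectory
#'
#' Line plot of per-repetition strategy-use proportions, or of the mean
#' subsymbolic traces (activations / utilities). Requires ggplot2.
#'
#' @param summary A `cohort_summary`.
#' @param what `"proportions"` or `"subsymbolic"`.
#' @return A ggplot object.
#' @export
plot_cohort_summary <- function(summary, what = c("proportions", "subsymbolic")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cohort_summary requires ggplot2", call. = FALSE)
  }
  what <- match.arg(what)
  br <- summary$by_rep
  cols <- if (what == "proportions") {
    paste0("p_level", 0:2)
  } else {
    grep("^mean_", names(br), value = TRUE)
  }
  long <- do.call(rbind, lapply(cols, function(cc) {
    data.frame(repetition = br$repetition, series = cc, value = br[[cc]])
  }))
  ylab <- if (what == "proportions") "proportion of children" else
    if (summary$meta$model == "ibl") "mean activation" else "mean utility"
  ggplot2::ggplot(long, ggplot2::aes(x = repetition, y = value,
                                     colour = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "repetition", y = ylab,
                  title = sprintf("%s model (%d children)",
                                  toupper(summary$meta$model),
                                  summary$meta$n_children)) +
    ggplot2::theme_minimal()
}
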