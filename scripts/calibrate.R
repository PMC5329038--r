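#!/usr/bin/env Rscript

# Calibration of the free parameters the published model description leaves
# open, done once; the committed defaults in ibl_params() / rl_params() are
# the values chosen here.
#
#  * instance-based model: the activation-noise scale s_act and the
#    inter-repetition interval. Only ln(interval) enters activation
#    differences, so the interval is parameterized through the repetition
#    r* at which the first-order chunk's noise-free activation would
#    overtake the zero-order chunk in a noise-free run:
#    interval = 4 r*(r*-1) / e^12.
#  * reinforcement-learning model: the per-production step duration used for
#    reward discounting (chain lengths fixed at 1/2/3).
#
# Selection criterion: proximity of the cohort trajectory to the published
# waypoints (first-order 60% @12; second-order 50% @26, 80% @40; activation
# crossover @10 | zero-order 50% over reps 1-10; second-order 60% @30),
# evaluated on cohorts of `nc` children. Run:
#
#   Rscript scripts/calibrate.R [nc]

suppressPackageStartupMessages(library(tomsim))
nc <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(nc)) nc <- 400

ibl_metrics <- function(s, rstar, seed = 42) {
  interval <- 4 * rstar * (rstar - 1) / exp(12)
  cs <- run_cohort("ibl", nc, 100, base_seed = seed,
                   params = ibl_params(s_act = s, trial_interval = interval))
  br <- cs$by_rep
  c(p1_12 = 100 * br$p_level1[12], p2_26 = 100 * br$p_level2[26],
    p2_40 = 100 * br$p_level2[40],
    xover = crossover_repetition(cs, "mean_B_level1", "mean_B_level0"))
}

rl_metrics <- function(step, seed = 42) {
  cs <- run_cohort("rl", nc, 100, base_seed = seed,
                   params = rl_params(step_time = step))
  br <- cs$by_rep
  c(p0_1_10 = 100 * mean(br$p_level0[1:10]), p2_30 = 100 * br$p_level2[30])
}

cat("== instance-based model: s_act x crossover-repetition grid ==\n")
cat("targets: p1@12 ~ 60, p2@26 ~ 50, p2@40 ~ 80, activation crossover ~ 10\n")
best <- NULL
for (s in c(0.16, 0.20, 0.23, 0.26, 0.30)) {
  for (rstar in c(8.5, 9.5, 10.5, 11.5)) {
    m <- ibl_metrics(s, rstar)
    loss <- abs(m[1] - 60) + abs(m[2] - 50) + abs(m[3] - 80) +
      5 * abs(m[4] - 10)
    cat(sprintf("s_act=%.2f r*=%4.1f (interval=%.5f s): p1@12=%5.1f p2@26=%5.1f p2@40=%5.1f xover=%2d loss=%5.1f\n",
                s, rstar, 4 * rstar * (rstar - 1) / exp(12),
                m[1], m[2], m[3], m[4], loss))
    if (is.null(best) || loss < best$loss) {
      best <- list(s = s, rstar = rstar, loss = loss)
    }
  }
}
cat(sprintf("-> committed: s_act = 0.23, trial_interval = 0.002 s (grid optimum region: s_act=%.2f, r*=%.1f)\n\n",
            best$s, best$rstar))

cat("== reinforcement-learning model: per-production step duration ==\n")
cat("targets: zero-order ~50% over reps 1-10, second-order ~60% @30\n")
for (step in c(0.05, 1, 2, 4, 5.5, 7)) {
  m <- rl_metrics(step)
  cat(sprintf("step=%4.2f s: p0@1-10=%5.1f p2@30=%5.1f\n", step, m[1], m[2]))
}
cat("-> committed: step_time = 5.5 s (centers the second-order waypoint; the\n")
cat("   rep 1-10 zero-order average is insensitive to timing, see vignette)\n")
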