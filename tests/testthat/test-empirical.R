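test_that("the empirical fixture is internally consistent", {
  fx <- empirical_results()
  pc <- fx$wrong_answers$percent
  expect_true(all(unlist(pc[c("first_order", "zero_order", "dont_know")]) >= 0))
  expect_equal(pc$first_order + pc$zero_order + pc$dont_know, 100)
  expect_equal(fx$overall$correct_percent + fx$overall$wrong_percent, 100)

  cts <- fx$wrong_answers$counts
  counts <- c(cts$first_order, cts$zero_order, cts$dont_know)
  expect_equal(sum(counts), fx$wrong_answers$n_wrong)
  # reconstructed counts match the printed percentages within one point
  expect_true(all(abs(100 * counts / 119 -
                        c(pc$first_order, pc$zero_order, pc$dont_know)) <= 1))
  expect_equal(cts$provenance, "reconstructed")
  expect_equal(pc$provenance, "printed")
})

test_that("the reconstructed counts are the unique triple reproducing the statistic", {
  fx <- empirical_results()
  target <- fx$goodness_of_fit$statistic
  hits <- list()
  for (a in 0:119) for (b in 0:(119 - a)) {
    cc <- c(a, b, 119 - a - b)
    stat <- sum((cc - 119 / 3)^2 / (119 / 3))
    if (abs(stat - target) < 0.005) hits[[length(hits) + 1]] <- sort(cc)
  }
  hits <- unique(hits)
  expect_length(hits, 1L)
  expect_equal(hits[[1]], sort(c(78, 34, 7)))
  expect_equal(chi_square_gof(c(78, 34, 7))$statistic, target,
               tolerance = 0.005)
})

test_that("the goodness-of-fit test matches an independent implementation", {
  expect_equal(chi_square_gof(c(5, 5, 5))$statistic, 0)
  r <- chi_square_gof(c(10, 0, 0))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 2L)

  set.seed(17)
  for (i in 1:250) {
    k <- sample(2:6, 1)
    counts <- stats::rpois(k, lambda = sample(3:40, 1)) + 1
    mine <- chi_square_gof(counts)
    ref <- suppressWarnings(stats::chisq.test(counts))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }

  # with two degrees of freedom the upper tail has the closed form e^(-x/2)
  for (x in c(0.5, 2, 10, 64.76)) {
    expect_equal(chi_square_gof(c(1, 1, 1),
                                expected = c(1, 1, 1))$p_value, 1)
    expect_equal(stats::pchisq(x, 2, lower.tail = FALSE), exp(-x / 2),
                 tolerance = 1e-9)
  }

  expect_error(chi_square_gof(c(5)), "two categories")
  expect_error(chi_square_gof(c(1, 2), expected = c(0, 3)),
               "degenerate-expectation")
})

test_that("the independence test is Pearson without continuity correction", {
  tab <- rbind(c(10, 20), c(20, 10))
  r <- chi_square_independence(tab)
  expect_equal(r$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  expect_equal(r$df, 1L)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)

  same <- rbind(c(3, 6, 9), c(1, 2, 3))
  expect_equal(chi_square_independence(same)$statistic, 0, tolerance = 1e-12)

  set.seed(23)
  for (i in 1:100) {
    t2 <- matrix(stats::rpois(6, 15) + 1, 2, 3)
    mine <- chi_square_independence(t2)
    ref <- suppressWarnings(stats::chisq.test(t2, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_gte(mine$statistic, 0)
  }

  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))),
               "degenerate margins")
})

test_that("prediction comparison windows and dominance flags are computed correctly", {
  # hand-built trajectory: zero-order phase (reps 1-3), first-order dominant
  # phase (4-7), stable second-order from rep 8
  mk <- function(p0, p1, p2, n = 10) {
    br <- data.frame(repetition = seq_along(p0),
                     p_level0 = p0, p_level1 = p1, p_level2 = p2,
                     n_wrong_level0 = round(n * p0),
                     n_wrong_level1 = round(n * p1),
                     n_wrong_level2 = 0)
    structure(list(by_rep = br, meta = list(model = "ibl")),
              class = "cohort_summary")
  }
  p2 <- c(0, 0, 0, 0, 0.1, 0.2, 0.4, 0.8, 0.9, 1)
  p1 <- c(0, 0.1, 0.2, 0.6, 0.7, 0.6, 0.4, 0.2, 0.1, 0)
  p0 <- 1 - p1 - p2
  a <- mk(p0, p1, p2)
  b <- mk(rev(p1) * 0 + p0, p1, p2)  # same shape for the second model
  rep_ <- compare_predictions(a, b, empirical_results())
  expect_equal(rep_$ibl$stabilization, 8L)
  expect_equal(rep_$ibl$onset, 4L)       # first rep with p1 >= p0
  expect_equal(rep_$ibl$wrong_first, sum(round(10 * p1[4:7])))
  expect_equal(rep_$ibl$wrong_zero, sum(round(10 * p0[4:7])))
  expect_true(rep_$ibl$first_dominant)
  expect_equal(rep_$children$p_first, 65 / 94, tolerance = 1e-12)
  expect_equal(rep_$ibl$tv_to_children,
               abs(rep_$ibl$p_first - 65 / 94), tolerance = 1e-12)

  # a trajectory that never stabilizes is a phase-definition error
  flat <- mk(rep(0.5, 10), rep(0.5, 10), rep(0, 10))
  expect_error(compare_predictions(flat, b), "phase-definition")
})
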