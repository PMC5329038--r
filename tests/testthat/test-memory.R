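test_that("base-level activation matches the closed form on a parameter grid", {
  p0 <- memory_params(s_act = 0)
  ch <- chunk("strategy", list(level = 0), creation_time = 0)
  expect_equal(base_level(ch, now = 1, p0), log(2), tolerance = 1e-12)

  ch2 <- chunk("strategy", list(level = 0), creation_time = 0, presentations = 2)
  expect_equal(base_level(ch2, now = 4, p0), log(2), tolerance = 1e-12)

  # independent re-derivation: B = ln(n) - ln(1 - d) - d ln(L) + offset
  for (n in c(1, 2, 5, 40)) for (L in c(0.01, 1, 30)) for (d in c(0.1, 0.5, 0.9)) {
    pk <- memory_params(d = d, s_act = 0)
    cc <- chunk("fact", list(a = "x"), creation_time = 2, presentations = n,
                base_offset = 1.25)
    expect_equal(base_level(cc, now = 2 + L, pk),
                 log(n) - log(1 - d) - d * log(L) + 1.25,
                 tolerance = 1e-12)
  }

  # decay-free limit: value tends to ln(n), independent of L
  pk <- memory_params(d = 1e-12, s_act = 0)
  c3 <- chunk("fact", list(a = "x"), creation_time = 0, presentations = 7)
  expect_equal(base_level(c3, now = 5, pk), log(7), tolerance = 1e-9)
  expect_equal(base_level(c3, now = 5000, pk), log(7), tolerance = 1e-7)
})

test_that("base level is increasing in presentations and decreasing in time", {
  p <- memory_params(s_act = 0)
  mk <- function(n) chunk("fact", list(a = "x"), presentations = n)
  b <- vapply(1:6, function(n) base_level(mk(n), now = 2, p), numeric(1))
  expect_true(all(diff(b) > 0))
  times <- c(0.5, 1, 5, 50)
  bt <- vapply(times, function(t) base_level(mk(3), now = t, p), numeric(1))
  expect_true(all(diff(bt) < 0))
})

test_that("non-positive lifetime signals an invalid-time error", {
  ch <- chunk("fact", list(a = "x"), creation_time = 3)
  expect_error(base_level(ch, now = 3), "invalid-time")
  expect_error(base_level(ch, now = 2.5), "invalid-time")
})

test_that("activation noise is zero-mean logistic with the requested scale", {
  ch <- chunk("fact", list(a = "x"), creation_time = 0)
  p0 <- memory_params(s_act = 0)
  expect_identical(noisy_activation(ch, 1, p0), base_level(ch, 1, p0))

  s <- 0.4
  p <- memory_params(s_act = s)
  set.seed(11)
  dev <- replicate(10000, noisy_activation(ch, 1, p)) - base_level(ch, 1, p)
  expect_equal(mean(dev), 0, tolerance = 0.02)
  expect_equal(stats::var(dev), s^2 * pi^2 / 3, tolerance = 0.05)

  # symmetry: two chunks with equal base level each win about half the time
  set.seed(12)
  wins <- mean(replicate(10000, noisy_activation(ch, 1, p) >
                           noisy_activation(ch, 1, p)))
  expect_equal(wins, 0.5, tolerance = 0.02)
})

test_that("negative noise scale is rejected", {
  expect_error(memory_params(s_act = -0.1), "s_act")
})

test_that("encoding merges identical chunks and keeps distinct ones apart", {
  st <- dm_store()
  st <- dm_encode(st, chunk("strategy", list(level = 1)), now = 1)
  st <- dm_encode(st, chunk("strategy", list(level = 1)), now = 3)
  expect_equal(dm_size(st), 1L)
  ch <- dm_chunks(st)[[1]]
  expect_equal(ch$presentations, 2L)
  expect_equal(ch$creation_time, 1)   # creation time unchanged by merging

  st <- dm_encode(st, chunk("strategy", list(level = 2)), now = 3)
  expect_equal(dm_size(st), 2L)

  # merging raises base-level activation at a fixed evaluation time
  p0 <- memory_params(s_act = 0)
  st1 <- dm_encode(dm_store(), chunk("strategy", list(level = 1)), now = 1)
  before <- base_level(dm_chunks(st1)[[1]], now = 10, p0)
  st2 <- dm_encode(st1, chunk("strategy", list(level = 1)), now = 3)
  after <- base_level(dm_chunks(st2)[[1]], now = 10, p0)
  expect_gt(after, before)
})

test_that("retrieval returns the noisy-activation argmax above threshold", {
  p0 <- memory_params(s_act = 0)
  st <- dm_store()
  st <- dm_encode(st, chunk("strategy", list(level = 0), base_offset = 6), now = 0)
  st <- dm_encode(st, chunk("strategy", list(level = 1), base_offset = 0.7), now = 0)
  got <- dm_retrieve(st, retrieval_request("strategy"), now = 1, p0)
  expect_equal(as.integer(got$slots$level), 0L)

  # a single matching chunk below threshold fails
  low <- dm_encode(dm_store(), chunk("fact", list(a = "x"), base_offset = -20),
                   now = 0)
  expect_null(dm_retrieve(low, retrieval_request("fact"), now = 1, p0))

  # story facts are always retrievable at tau = -5
  st2 <- tomsim:::encode_facts(dm_store(), initial_facts(), now = 0)
  for (seed in 1:10) {
    set.seed(seed)
    got <- dm_retrieve(st2, retrieval_request("fact", verb = "put"),
                       now = 0.002, memory_params())
    expect_false(is.null(got))
  }

  expect_error(dm_retrieve(st, list(kind = "x"), now = 1, p0), "request error")
  expect_error(retrieval_request(), "request error")
})

test_that("noise-free retrieval is a pure function; seeded runs repeat exactly", {
  st <- tomsim:::encode_facts(dm_store(), initial_facts(), now = 0)
  p0 <- memory_params(s_act = 0)
  a <- dm_retrieve(st, retrieval_request("fact", verb = "put"), 1, p0)
  b <- dm_retrieve(st, retrieval_request("fact", verb = "put"), 1, p0)
  expect_identical(a, b)

  p <- memory_params(s_act = 0.3)
  seq1 <- {
    set.seed(5)
    replicate(20, dm_retrieve(st, retrieval_request("fact"), 1, p)$id)
  }
  seq2 <- {
    set.seed(5)
    replicate(20, dm_retrieve(st, retrieval_request("fact"), 1, p)$id)
  }
  expect_identical(seq1, seq2)
})

test_that("a memory store serializes to JSON with full chunk metadata", {
  st <- tomsim:::encode_facts(dm_store(), initial_facts(), now = 0)
  js <- jsonlite::fromJSON(dm_to_json(st), simplifyVector = FALSE)
  expect_length(js, 5L)
  expect_setequal(names(js[[1]]),
                  c("id", "kind", "slots", "creation_time", "presentations",
                    "base_offset"))
})
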