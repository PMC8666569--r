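# Tone pools, sequences, probes, and the constrained experiment design.

test_that("tone pool is the maximal geometric ladder within the bounds", {
  # oracle: iterate f <- ratio * f from the base until exceeding the cap
  iterate_pool <- function(base, ratio, cap) {
    f <- base
    out <- c()
    while (f <= cap * (1 + 1e-12)) {
      out <- c(out, f)
      f <- f * ratio
    }
    out
  }
  cases <- list(c(300, 1.3, 2600), c(300, 1.3, 300), c(300, 2.0, 2600),
                c(100, 1.5, 5000))
  for (cs in cases) {
    pool <- build_tone_pool(cs[1], cs[2], cs[3])
    expect_equal(pool$frequencies, iterate_pool(cs[1], cs[2], cs[3]))
  }
  pool <- build_tone_pool(300, 1.3, 2600)
  expect_length(pool$frequencies, 9L)
  expect_equal(max(pool$frequencies), 300 * 1.3^8, tolerance = 1e-12)
  expect_equal(build_tone_pool(300, 2, 2600)$frequencies,
               c(300, 600, 1200, 2400))
  # invariants: geometric within 1e-9, one more step would exceed the cap
  r <- pool$frequencies[-1] / pool$frequencies[-9]
  expect_true(all(abs(r - 1.3) < 1e-9))
  expect_gt(max(pool$frequencies) * 1.3, 2600)
  expect_error(build_tone_pool(-1, 1.3, 2600), "positive")
  expect_error(build_tone_pool(300, 0.9, 2600), "step_ratio")
  expect_error(build_tone_pool(300, 1.3, 200), "max_hz")
})

test_that("sequences are deterministic permutations of the pool", {
  s1 <- make_sequence(default_pool, seed = 7)
  s2 <- make_sequence(default_pool, seed = 7)
  s3 <- make_sequence(default_pool, seed = 8)
  expect_identical(s1$freqs_hz, s2$freqs_hz)
  expect_false(identical(s1$freqs_hz, s3$freqs_hz))
  expect_setequal(s1$freqs_hz, default_pool$frequencies)
  expect_length(s1$freqs_hz, 9L)
  small <- build_tone_pool(300, 1.3, 600)
  expect_error(make_sequence(small), "fewer than")
  swr <- make_sequence(small, seed = 1, policy = "with_replacement")
  expect_true(all(swr$freqs_hz %in% small$frequencies))
  expect_equal(sequence_duration(s1), 3.0)
})

test_that("adjacent transposition probes preserve the frequency multiset", {
  s <- make_sequence(default_pool, seed = 1)
  p1 <- transpose_probe(s, position = 1)
  expect_identical(p1$freqs_hz[1:2], s$freqs_hz[2:1])
  expect_identical(p1$freqs_hz[3:9], s$freqs_hz[3:9])
  # involution
  expect_identical(transpose_probe(p1, position = 1)$freqs_hz, s$freqs_hz)
  # multiset preserved over random draws
  for (k in 1:200) {
    p <- transpose_probe(s, seed = k)
    expect_identical(sort(p$freqs_hz), sort(s$freqs_hz))
    expect_false(identical(p$freqs_hz, s$freqs_hz))
  }
  expect_error(transpose_probe(s, position = 9), "position")
  const <- make_sequence(build_tone_pool(300, 1.3, 300), seed = 1,
                         policy = "with_replacement")
  expect_error(transpose_probe(const), "no valid probe")
})

test_that("default design reproduces the printed trial counts", {
  d <- build_design(seed = 42)
  tr <- d$trials
  expect_equal(nrow(tr), 144L)
  expect_true(all(table(tr$seq_type, tr$probe_type) == 36L))
  expect_true(all(table(tr$seq_id[tr$seq_type == "repeat"]) == 24L))
  expect_true(all(table(tr$condition) == 12L))
  expect_length(unique(tr$condition), 12L)
  expect_true(all(tr$iti_s >= 4 & tr$iti_s <= 10))
  # mismatch probes differ by exactly one adjacent transposition
  mm <- tr[tr$probe_type == "mismatch", ][1:10, ]
  for (i in seq_len(nrow(mm))) {
    study <- d$sequences[[mm$seq_id[i]]]
    probe <- probe_sequence(d, mm$trial_id[i])
    diffs <- which(study$freqs_hz != probe$freqs_hz)
    expect_identical(diffs, c(mm$probe_swap_pos[i], mm$probe_swap_pos[i] + 1L))
    expect_identical(sort(probe$freqs_hz), sort(study$freqs_hz))
  }
  mt <- tr[tr$probe_type == "match", ][1, ]
  expect_identical(probe_sequence(d, mt$trial_id)$freqs_hz,
                   d$sequences[[mt$seq_id]]$freqs_hz)
  # novel sequences are unique and never collide with S1-S3
  keys <- vapply(d$sequences, function(s) paste(s$freqs_hz, collapse = ","),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("the same repeating sequence never occurs on successive trials", {
  for (seed in 1:100) {
    tr <- build_design(seed = seed)$trials
    sid <- ifelse(tr$seq_type == "repeat", tr$seq_id, NA)
    same <- !is.na(sid[-1]) & !is.na(sid[-144]) & sid[-1] == sid[-144]
    expect_equal(sum(same), 0L)
  }
})

test_that("infeasible balance requests are rejected", {
  expect_error(build_design(trials_per_run = 17), "even")
  expect_error(build_design(trials_per_run = 8), "divisible by 3")
  expect_error(build_design(n_runs = 1, trials_per_run = 6), "balanced")
})

test_that("event tables have one row per phase with correct durations", {
  d <- build_design(seed = 3)
  ev <- design_to_events(d)
  expect_equal(nrow(ev), 432L)
  expect_true(all(ev$duration[ev$trial_type == "encoding"] == 3))
  expect_true(all(ev$duration[ev$trial_type == "probe"] == 3))
  del <- ev[ev$trial_type == "delay", ]
  expect_true(all(del$duration %in% c(3, 6, 9)))
  expect_equal(del$duration[match(d$trials$trial_id, del$trial_id)],
               d$trials$delay_s)
  # phases tile the trial contiguously
  tr1 <- d$trials[1, ]
  ph <- ev[ev$trial_id == tr1$trial_id, ]
  expect_equal(ph$onset, tr1$onset_s + c(0, 3, 3 + tr1$delay_s))
})

test_that("events round-trip losslessly and are byte-identical by seed", {
  d <- build_design(seed = 11)
  ev <- design_to_events(d)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_events(ev, f1)
  expect_equal(read_events(f1), ev)
  write_events(design_to_events(build_design(seed = 11)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  f3 <- tempfile(fileext = ".tsv")
  write_events(design_to_events(build_design(seed = 12)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})
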