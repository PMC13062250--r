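test_that("no decision fires before the minimum window", {
  params <- decision_params()
  fb <- fbcca_params("low")
  stream <- ssvep_block_stream(8.57, channel_montage(), noise_free_cfg(1, 4),
                               rng = 1)
  state <- engine_new(params)
  for (i in 1:9) {
    step <- ingest_block(state, stream(), params, fb)
    state <- step$state
    expect_null(step$event)
    expect_length(state$evaluation_log, 0)
  }
  # 10th block completes 300 samples of clean signal: decision, latency 300
  step <- ingest_block(state, stream(), params, fb)
  expect_false(is.null(step$event))
  expect_equal(step$event$latency_samples, 300L)
  expect_gte(step$event$margin, params$threshold)
  expect_equal(step$event$frequency, 8.57)
})

test_that("buffer caps at the sliding-window limit and stays pinned", {
  params <- decision_params(threshold = 99)   # unreachable: margin <= max score
  fb <- fbcca_params("low")
  stream <- noise_block_stream(channel_montage("Oz"), sim_config(seed = 2), rng = 2)
  state <- engine_new(params)
  lens <- integer(0)
  for (i in 1:70) {
    step <- ingest_block(state, stream(), params, fb)
    state <- step$state
    expect_null(step$event)
    lens <- c(lens, ncol(state$buffer))
  }
  expect_equal(lens[1:60], seq(30L, 1800L, by = 30L))
  expect_true(all(lens[60:70] == 1800L))
})

test_that("evaluations happen only on the block grid, at or past the minimum", {
  params <- decision_params(threshold = 99)
  fb <- fbcca_params("low")
  stream <- noise_block_stream(channel_montage("Oz"), sim_config(seed = 3), rng = 3)
  state <- engine_new(params)
  for (i in 1:40) state <- ingest_block(state, stream(), params, fb)$state
  ts <- vapply(state$evaluation_log, function(r) r$t_sample, integer(1))
  expect_true(all(ts %% 30L == 0L))
  expect_true(all(ts >= 300L))
  expect_equal(ts, seq(300L, 1200L, by = 30L))
  # all undecided evaluations sit below the threshold
  expect_true(all(vapply(state$evaluation_log, function(r) r$margin, numeric(1)) <
                  params$threshold))
})

test_that("reset clears the buffer and gaze shift discards exactly 0.5 s", {
  params <- decision_params()
  fb <- fbcca_params("low")
  stream <- ssvep_block_stream(6.67, channel_montage(), noise_free_cfg(1, 4),
                               rng = 4)
  state <- engine_new(params)
  state <- reset_for_next_digit(state, params)
  expect_equal(state$phase, "gaze_shift")
  expect_equal(state$gaze_shift_remaining, 300L)   # 0.5 s at 600 Hz
  expect_null(state$buffer)
  # idempotent on buffer emptiness
  state2 <- reset_for_next_digit(state, params)
  expect_null(state2$buffer)
  expect_equal(state2$samples_since_reset, 0L)
  # exactly 10 blocks are discarded before collection resumes
  discarded <- 0L
  while (state$phase == "gaze_shift") {
    state <- ingest_block(state, stream(), params, fb)$state
    discarded <- discarded + 1L
  }
  expect_equal(discarded, 10L)
  expect_null(state$buffer)
  # after the reset, a decision needs min_samples of fresh signal again
  decided <- FALSE
  n_blocks <- 0L
  while (!decided) {
    step <- ingest_block(state, stream(), params, fb)
    state <- step$state
    n_blocks <- n_blocks + 1L
    decided <- !is.null(step$event)
  }
  expect_equal(n_blocks, 10L)
  expect_equal(step$event$latency_samples, 300L)
})

test_that("ingest validates block size and channel consistency", {
  params <- decision_params()
  fb <- fbcca_params("low")
  state <- engine_new(params)
  bad <- eeg_segment(matrix(rnorm(29), 1), 600)
  expect_error(ingest_block(state, bad, params, fb), "block_size")
  ok <- eeg_segment(matrix(rnorm(90), 3), 600)
  state <- ingest_block(state, ok, params, fb)$state
  one_ch <- eeg_segment(matrix(rnorm(30), 1), 600)
  expect_error(ingest_block(state, one_ch, params, fb), "channel")
})

test_that("run_digit decodes clean streams and scores mismatches", {
  params <- decision_params()
  set <- frequency_set("low")
  cfg <- noise_free_cfg(1, 4)
  ev <- run_digit(ssvep_block_stream(7.5, channel_montage(), cfg, rng = 5),
                  true_digit = 2, params, set$fbcca)
  expect_true(ev$correct)
  expect_equal(ev$decided_digit, 2L)
  expect_equal(ev$latency_samples, 300L)
  # stream synthesized at a non-target frequency: decoded as that digit,
  # scored incorrect
  ev2 <- run_digit(ssvep_block_stream(8.57, channel_montage(), cfg, rng = 5),
                   true_digit = 2, params, set$fbcca)
  expect_false(ev2$correct)
  expect_equal(ev2$decided_digit, 3L)
  # seeded reruns are identical
  mk <- function() run_digit(
    ssvep_block_stream(7.5, channel_montage(), sim_config(snr_db = 4, seed = 6),
                       rng = 6),
    true_digit = 2, params, set$fbcca)
  a <- mk(); b <- mk()
  expect_identical(a$latency_samples, b$latency_samples)
  expect_identical(a$decided_digit, b$decided_digit)
  expect_identical(a$margin, b$margin)
})

test_that("the timeout guard errors or force-decides as configured", {
  params <- decision_params(threshold = 99)
  set <- frequency_set("low")
  stream_factory <- function(seed) {
    noise_block_stream(channel_montage("Oz"), sim_config(seed = seed), rng = seed)
  }
  expect_error(run_digit(stream_factory(7), 1, params, set$fbcca,
                         max_duration_s = 1), "no decision")
  ev <- run_digit(stream_factory(7), 1, params, set$fbcca,
                  max_duration_s = 1, on_timeout = "decide")
  expect_true(ev$forced)
  expect_equal(ev$latency_samples, 600L)
})

test_that("pure-noise selection at threshold 0 is uniform over classes", {
  # decisions fire at exactly the minimum window; over many digits, each of
  # the 3 classes should be chosen at ~1/3
  params <- decision_params(threshold = 0)
  fb <- fbcca_params("low")
  n_digits <- 300
  picks <- integer(n_digits)
  for (i in seq_len(n_digits)) {
    stream <- noise_block_stream(channel_montage("Oz"),
                                 sim_config(seed = 1), rng = 20000 + i)
    ev <- run_digit(stream, 1, params, fb)
    expect_equal(ev$latency_samples, 300L)
    picks[i] <- ev$decided_index
  }
  bounds <- binom99(n_digits, 1 / 3)
  for (k in 1:3) {
    rate <- mean(picks == k)
    expect_gte(rate, bounds[1])
    expect_lte(rate, bounds[2])
  }
})

test_that("mean latency decreases with SNR", {
  params <- decision_params()
  set <- frequency_set("low")
  m <- channel_montage("Oz")
  snrs <- c(-2, 2, 6, 10)
  mean_lat <- sapply(seq_along(snrs), function(j) {
    lats <- sapply(1:25, function(i) {
      cfg <- sim_config(snr_db = snrs[j], seed = 1)
      run_digit(ssvep_block_stream(7.5, m, cfg, rng = 3000 + 97 * i + j),
                2, params, set$fbcca, max_duration_s = 10,
                on_timeout = "decide")$latency_s
    })
    mean(lats)
  })
  # non-increasing in expectation across the grid (small tolerance for
  # sampling noise at the flat high-SNR end)
  expect_true(all(diff(mean_lat) <= 0.05))
  expect_lt(mean_lat[4], mean_lat[1])
})
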