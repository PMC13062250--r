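test_that("noise-free synthesis is a sinusoid at the stimulation frequency", {
  cfg <- noise_free_cfg(seed = 7)
  m <- channel_montage(ssvep_gains = c(0.5, 1, 0.8))
  seg <- generate_ssvep_segment(40, 600, m, cfg, rng = 7)
  for (ch in 1:3) {
    expect_equal(dominant_frequency(seg$samples[ch, ], 600), 40)
  }
  # channels are scaled copies of the shared evoked waveform
  expect_equal(seg$samples[1, ] / 0.5, seg$samples[2, ], tolerance = 1e-12)
})

test_that("generation is bit-reproducible given the seed", {
  cfg <- sim_config(seed = 7)
  a <- generate_ssvep_segment(8.57, 900, cfg = cfg, rng = 7)
  b <- generate_ssvep_segment(8.57, 900, cfg = cfg, rng = 7)
  expect_identical(a$samples, b$samples)
  c <- generate_ssvep_segment(8.57, 900, cfg = cfg, rng = 8)
  expect_false(identical(a$samples, c$samples))
})

test_that("harmonic structure matches an independently summed sinusoid", {
  cfg <- noise_free_cfg(seed = 11, harmonic_count = 4, harmonic_decay = 0.6)
  m <- channel_montage("Oz")
  n <- 6000   # 10 s: fine frequency resolution
  seg <- generate_ssvep_segment(8.57, n, m, cfg, rng = 11)
  # oracle: direct synthesis with the phases recovered from the generator's
  # own stream (same seed, same draw order)
  rng <- ssvepauth::rng_stream(11)
  ph <- ssvepauth:::with_rng(rng, function() {
    list(harm = runif(4, 0, 2 * pi), distract = runif(2, 0, 2 * pi),
         alpha = runif(1, 0, 2 * pi), line = runif(1, 0, 2 * pi))
  })
  t <- (0:(n - 1)) / 600
  direct <- rowSums(sapply(1:4, function(h) {
    0.6^(h - 1) * sin(2 * pi * h * 8.57 * t + ph$harm[h])
  }))
  expect_equal(seg$samples[1, ], direct, tolerance = 1e-10,
               ignore_attr = TRUE)
  # spectral peaks at the four harmonics with decaying amplitude ratios
  amps <- sapply(1:4, function(h) fitted_amplitude(seg$samples[1, ], h * 8.57, 600))
  expect_equal(amps / amps[1], 0.6^(0:3), tolerance = 0.02)
})

test_that("broadband noise has the configured spectral slope", {
  m <- channel_montage("Oz")
  # beta = 0: flat (white) spectrum; slope of log-periodogram ~ 0
  cfg0 <- sim_config(alpha_amp = 0, line_amp = 0, noise_exponent = 0, seed = 2)
  x <- generate_noise(72000, m, cfg0, rng = 2)$samples[1, ]
  pg <- spec.pgram(ts(x, frequency = 600), spans = 31, plot = FALSE, taper = 0)
  keep <- pg$freq >= 1 & pg$freq <= 60
  fit0 <- coef(lm(log10(pg$spec[keep]) ~ log10(pg$freq[keep])))[2]
  expect_lt(abs(fit0), 0.1)
  # beta = 1: slope ~ -1 on a log-log periodogram over 1-60 Hz
  cfg1 <- sim_config(alpha_amp = 0, line_amp = 0, noise_exponent = 1, seed = 2)
  x <- generate_noise(72000, m, cfg1, rng = 2)$samples[1, ]
  pg <- spec.pgram(ts(x, frequency = 600), spans = 31, plot = FALSE, taper = 0)
  keep <- pg$freq >= 1 & pg$freq <= 60
  fit1 <- coef(lm(log10(pg$spec[keep]) ~ log10(pg$freq[keep])))[2]
  expect_equal(unname(fit1), -1, tolerance = 0.15)
})

test_that("dominant interferers appear where configured", {
  m <- channel_montage("Oz")
  cfg <- sim_config(noise_sd = 0.01, alpha_amp = 0, line_amp = 5, seed = 3)
  x <- generate_noise(6000, m, cfg, rng = 3)$samples[1, ]
  expect_equal(dominant_frequency(x, 600), 50)
  cfg <- sim_config(noise_sd = 0.01, alpha_amp = 5, line_amp = 0, seed = 3)
  x <- generate_noise(6000, m, cfg, rng = 3)$samples[1, ]
  expect_equal(dominant_frequency(x, 600), 10)
})

test_that("narrowband SNR calibration is within 1 dB of target", {
  m <- channel_montage()
  for (target in c(0, 6)) {
    cfg <- sim_config(snr_db = target, seed = 5)
    n <- 36000   # 60 s
    sig <- generate_ssvep_segment(8.57, n, m, cfg, rng = 5)
    noi <- generate_noise(n, m, cfg, rng = 5)
    for (ch in 1:3) {
      evoked <- sig$samples[ch, ] - noi$samples[ch, ]
      t <- (0:(n - 1)) / 600
      a <- 2 * mean(evoked * sin(2 * pi * 8.57 * t))
      b <- 2 * mean(evoked * cos(2 * pi * 8.57 * t))
      p_sig <- (a^2 + b^2) / 2
      f <- (0:(n - 1)) * 600 / n
      band <- abs(pmin(f, 600 - f) - 8.57) <= 1
      p_noise <- sum(Mod(fft(noi$samples[ch, ])[band])^2) / n^2
      expect_equal(10 * log10(p_sig / p_noise), target, tolerance = 1)
    }
  }
})

test_that("superposition: composite = evoked + background, exactly", {
  m <- channel_montage(ssvep_gains = c(0.7, 1, 0.9), noise_gains = c(1.1, 1, 0.9))
  cfg <- sim_config(snr_db = 3, seed = 9)
  n <- 1200
  composite <- generate_ssvep_segment(7.5, n, m, cfg, rng = 9)
  background <- generate_noise(n, m, cfg, rng = 9)
  silent <- channel_montage(ssvep_gains = 0, noise_gains = m$noise_gains)
  expect_identical(generate_ssvep_segment(7.5, n, silent, cfg, rng = 9)$samples,
                   background$samples)
  evoked_only <- generate_ssvep_segment(
    7.5, n, channel_montage(ssvep_gains = m$ssvep_gains, noise_gains = 0),
    cfg, rng = 9)
  expect_equal(composite$samples, evoked_only$samples + background$samples,
               tolerance = 1e-12)
})

test_that("blockwise streaming equals single-shot synthesis", {
  m <- channel_montage()
  cfg <- sim_config(snr_db = 6, seed = 13)
  stream <- ssvep_block_stream(6.67, m, cfg, rng = 13)
  blocks <- lapply(1:10, function(i) stream())
  expect_true(all(vapply(blocks, function(b) ncol(b$samples) == 30, logical(1))))
  expect_equal(vapply(blocks, function(b) b$onset_index, integer(1)),
               seq(0L, 270L, by = 30L))
  whole <- generate_ssvep_segment(6.67, 300, m, cfg, rng = 13)
  expect_identical(do.call(cbind, lapply(blocks, function(b) b$samples)),
                   whole$samples)
  other <- ssvep_block_stream(6.67, m, cfg, rng = 14)()
  expect_false(identical(blocks[[1]]$samples, other$samples))
})

test_that("subject profiles are deterministic and within population ranges", {
  pop <- population_config()
  p1 <- sample_subject_profile(4, pop, seed = 1)
  p2 <- sample_subject_profile(4, pop, seed = 1)
  expect_identical(p1$montage, p2$montage)
  expect_identical(p1$cfg, p2$cfg)
  for (s in 1:21) {
    p <- sample_subject_profile(s, pop, seed = 1)
    expect_gte(p$snr_db, pop$snr_db_range[1])
    expect_lte(p$snr_db, pop$snr_db_range[2])
    expect_true(all(p$montage$ssvep_gains >= pop$ssvep_gain_range[1] &
                    p$montage$ssvep_gains <= pop$ssvep_gain_range[2]))
    expect_true(all(p$montage$noise_gains >= pop$noise_gain_range[1] &
                    p$montage$noise_gains <= pop$noise_gain_range[2]))
  }
  # degenerate ranges collapse the cohort to identical subjects
  degen <- population_config(snr_db_range = c(5, 5), ssvep_gain_range = c(1, 1),
                             noise_gain_range = c(1, 1), alpha_amp_range = c(0.5, 0.5))
  a <- sample_subject_profile(1, degen, seed = 1)
  b <- sample_subject_profile(2, degen, seed = 1)
  expect_identical(a$montage, b$montage)
  expect_equal(a$cfg$snr_db, b$cfg$snr_db)
  expect_equal(a$cfg$alpha_amp, b$cfg$alpha_amp)
})

test_that("generator validates its inputs", {
  expect_error(generate_ssvep_segment(-1, 100), "positive")
  expect_error(generate_ssvep_segment(8.57, 0), "n_samples")
  expect_error(channel_montage(character(0)), "at least one")
  expect_error(channel_montage(c("Oz", "Oz")), "unique")
  expect_error(channel_montage("Oz", ssvep_gains = -1), "gains")
  expect_error(sim_config(noise_exponent = -0.5), "noise_exponent")
  # Nyquist: 4 harmonics of 80 Hz exceed 300 Hz
  expect_error(generate_ssvep_segment(80, 100, cfg = sim_config(harmonic_count = 4)),
               "Nyquist|twice")
  expect_error(population_config(snr_db_range = c(10, 2)), "range")
})
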