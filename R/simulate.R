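#' Occipital channel montage
#'
#' Describes the recording channels and per-channel gains used by the
#' synthetic EEG generator. The defaults follow the standard three-electrode
#' occipital layout (O1, Oz, O2); the single-electrode condition uses Oz
#' alone. `ssvep_gains` multiply the evoked (stimulus-locked) component and
#' `noise_gains` multiply the background activity, modelling electrode-to-
#' electrode differences in SSVEP pickup and noise level.
#'
#' @param channels Character vector of unique channel names.
#' @param ssvep_gains Per-channel multipliers on the SSVEP component
#'   (recycled to the number of channels).
#' @param noise_gains Per-channel multipliers on background noise (recycled).
#' @return An object of class `channel_montage`.
#' @export
channel_montage <- function(channels = c("O1", "Oz", "O2"),
                            ssvep_gains = 1, noise_gains = 1) {
  if (length(channels) < 1L) stop("montage needs at least one channel", call. = FALSE)
  if (anyDuplicated(channels)) stop("channel names must be unique", call. = FALSE)
  ssvep_gains <- rep_len(as.numeric(ssvep_gains), length(channels))
  noise_gains <- rep_len(as.numeric(noise_gains), length(channels))
  if (any(!is.finite(ssvep_gains)) || any(ssvep_gains < 0) ||
      any(!is.finite(noise_gains)) || any(noise_gains < 0)) {
    stop("gains must be finite and >= 0", call. = FALSE)
  }
  structure(list(channels = as.character(channels),
                 ssvep_gains = ssvep_gains,
                 noise_gains = noise_gains),
            class = "channel_montage")
}

#' Simulation configuration for the synthetic SSVEP generator
#'
#' The generator superimposes a deterministic steady-state response
#' (fundamental plus `harmonic_count` harmonics with geometrically decaying
#' amplitudes and random phases) on structured background activity:
#' 1/f^beta broadband noise, an alpha rhythm near 10 Hz, and optional mains
#' interference at 50 Hz. Signal strength is set through `snr_db`, the ratio
#' of fundamental-component power to background-noise power inside a
#' +/- 1 Hz band around the fundamental -- the narrow band the decoder
#' actually competes in.
#'
#' @param fs Sampling rate in Hz.
#' @param snr_db Target narrowband SNR (dB) of the SSVEP fundamental.
#' @param harmonic_count Number of simulated harmonics (fundamental = 1).
#' @param harmonic_decay Amplitude ratio between consecutive harmonics, in (0, 1].
#' @param alpha_amp,alpha_freq Amplitude and frequency (Hz) of the alpha rhythm.
#' @param line_amp,line_freq Amplitude and frequency (Hz) of mains interference.
#' @param distractor_amps Amplitudes of the two non-target flicker frequencies
#'   (the non-fixated stimuli keep flickering; default 0 models pure fixation).
#' @param noise_exponent Spectral slope beta of the 1/f^beta broadband noise.
#' @param noise_sd Standard deviation of the broadband noise (nominal uV).
#' @param noise_chunk_samples Internal synthesis block length for the
#'   spectrally shaped noise; fixed per configuration so that streamed and
#'   single-shot output are sample-identical.
#' @param seed Default integer seed used when no stream is supplied.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 600, snr_db = 6, harmonic_count = 3,
                       harmonic_decay = 0.5, alpha_amp = 0.5, alpha_freq = 10,
                       line_amp = 0.1, line_freq = 50,
                       distractor_amps = c(0, 0), noise_exponent = 1,
                       noise_sd = 1, noise_chunk_samples = 7200, seed = 1) {
  stopifnot(fs > 0, harmonic_count >= 1, harmonic_decay > 0, harmonic_decay <= 1)
  amps <- c(alpha_amp, line_amp, distractor_amps, noise_sd)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("amplitudes must be finite and >= 0", call. = FALSE)
  }
  if (noise_exponent < 0) stop("noise_exponent must be >= 0", call. = FALSE)
  if (alpha_freq >= fs / 2 || line_freq >= fs / 2) {
    stop("alpha/line frequencies must be below Nyquist", call. = FALSE)
  }
  structure(list(fs = fs, snr_db = snr_db, harmonic_count = as.integer(harmonic_count),
                 harmonic_decay = harmonic_decay, alpha_amp = alpha_amp,
                 alpha_freq = alpha_freq, line_amp = line_amp, line_freq = line_freq,
                 distractor_amps = rep_len(as.numeric(distractor_amps), 2L),
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 noise_chunk_samples = as.integer(noise_chunk_samples),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Multichannel EEG segment
#'
#' @param samples Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param onset_index First sample's index relative to stimulus onset (0-based).
#' @param channels Optional channel names (defaults to rownames).
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, fs, onset_index = 0L, channels = rownames(samples)) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 1L) stop("segment needs at least one sample", call. = FALSE)
  if (any(!is.finite(samples))) stop("segment contains non-finite values", call. = FALSE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(samples)))
  rownames(samples) <- channels
  structure(list(samples = samples, fs = fs, onset_index = as.integer(onset_index),
                 channels = channels),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channel(s) x %d samples @ %g Hz (%s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

# Two-sided fraction of broadband-noise power that falls within +/- 1 Hz of
# f0, on the FFT grid of the synthesis chunk. Used to convert snr_db into a
# fundamental amplitude without measuring any realization.
noise_band_share <- function(f0, fs, n_fft, beta) {
  k <- 0:(n_fft - 1)
  f <- k * fs / n_fft
  f <- pmin(f, fs - f)
  w2 <- ifelse(f > 0, f^(-beta), 0)
  sum(w2[abs(f - f0) <= 1]) / sum(w2)
}

# Expected background power (per unit noise gain) in the +/- 1 Hz band
# around f0: shaped broadband noise plus any sinusoidal interferer that
# falls inside the band.
band_noise_power <- function(f0, cfg) {
  p <- cfg$noise_sd^2 *
    noise_band_share(f0, cfg$fs, cfg$noise_chunk_samples, cfg$noise_exponent)
  if (abs(cfg$alpha_freq - f0) <= 1) p <- p + cfg$alpha_amp^2 / 2
  if (abs(cfg$line_freq - f0) <= 1) p <- p + cfg$line_amp^2 / 2
  p
}

# One spectrally shaped noise chunk (unit variance scale applied here).
shaped_noise_chunk <- function(cfg) {
  n_fft <- cfg$noise_chunk_samples
  k <- 0:(n_fft - 1)
  f <- k * cfg$fs / n_fft
  f <- pmin(f, cfg$fs - f)
  w <- ifelse(f > 0, f^(-cfg$noise_exponent / 2), 0)
  scale <- if (all(w == 0)) 0 else cfg$noise_sd / sqrt(sum(w^2) / n_fft)
  x <- stats::rnorm(n_fft)
  Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n_fft * scale
}

# Core streaming synthesizer. Draw order is fixed (harmonic phases,
# distractor phases, per-channel alpha and line phases, then noise chunks in
# order) so that signal-free and noise-free variants of the same seed are
# sample-identical on the shared components, and so that any prefix of the
# stream equals the same-seed single-shot synthesis.
ssvep_source <- function(frequency, montage, cfg, rng,
                         distractor_freqs = NULL, signal_on = TRUE) {
  n_ch <- length(montage$channels)
  if (signal_on) {
    if (!is.numeric(frequency) || frequency <= 0) {
      stop("frequency must be positive", call. = FALSE)
    }
    if (cfg$harmonic_count * frequency >= cfg$fs / 2) {
      stop("fs must exceed twice the highest simulated harmonic", call. = FALSE)
    }
  }
  if (!is.null(distractor_freqs) && any(distractor_freqs >= cfg$fs / 2)) {
    stop("distractor frequencies must be below Nyquist", call. = FALSE)
  }
  rng <- rng_stream(rng)
  ph <- with_rng(rng, function() {
    list(harm = stats::runif(cfg$harmonic_count, 0, 2 * pi),
         distract = stats::runif(2L, 0, 2 * pi),
         alpha = stats::runif(n_ch, 0, 2 * pi),
         line = stats::runif(n_ch, 0, 2 * pi))
  })
  # Fundamental amplitude from the target narrowband SNR; when the
  # configuration carries no background power the amplitude defaults to 1.
  amp0 <- 1
  if (signal_on) {
    p_noise <- band_noise_power(frequency, cfg)
    if (p_noise > 0) amp0 <- sqrt(2 * p_noise * 10^(cfg$snr_db / 10))
  }
  pos <- 0L                      # absolute sample index of next output sample
  chunk <- matrix(numeric(0), nrow = n_ch, ncol = 0)
  chunk_used <- 0L

  take <- function(n) {
    n <- as.integer(n)
    out <- matrix(0, nrow = n_ch, ncol = n)
    idx <- pos + seq_len(n) - 1L      # 0-based absolute indices
    t <- idx / cfg$fs
    det <- numeric(n)                  # channel-shared deterministic part
    if (signal_on) {
      for (h in seq_len(cfg$harmonic_count)) {
        det <- det + amp0 * cfg$harmonic_decay^(h - 1) *
          sin(2 * pi * h * frequency * t + ph$harm[h])
      }
    }
    if (!is.null(distractor_freqs)) {
      for (j in seq_along(distractor_freqs)) {
        a <- cfg$distractor_amps[j]
        if (a > 0) det <- det + a * sin(2 * pi * distractor_freqs[j] * t + ph$distract[j])
      }
    }
    filled <- 0L
    noise <- matrix(0, nrow = n_ch, ncol = n)
    while (filled < n) {
      if (chunk_used >= ncol(chunk)) {
        chunk <<- with_rng(rng, function() {
          t(vapply(seq_len(n_ch), function(i) shaped_noise_chunk(cfg),
                   numeric(cfg$noise_chunk_samples)))
        })
        chunk_used <<- 0L
      }
      m <- min(n - filled, ncol(chunk) - chunk_used)
      noise[, filled + seq_len(m)] <- chunk[, chunk_used + seq_len(m), drop = FALSE]
      chunk_used <<- chunk_used + m
      filled <- filled + m
    }
    for (c_i in seq_len(n_ch)) {
      bg <- noise[c_i, ] +
        cfg$alpha_amp * sin(2 * pi * cfg$alpha_freq * t + ph$alpha[c_i]) +
        cfg$line_amp * sin(2 * pi * cfg$line_freq * t + ph$line[c_i])
      out[c_i, ] <- montage$ssvep_gains[c_i] * det + montage$noise_gains[c_i] * bg
    }
    pos <<- pos + n
    out
  }
  list(take = take, onset = function() pos)
}

#' Generate a synthetic SSVEP epoch
#'
#' Returns `n_samples` of multichannel EEG containing a steady-state response
#' at `frequency` and its harmonics over structured background noise, per the
#' forward model described in [sim_config()]. With all background amplitudes
#' zero the output is the pure evoked component (unit fundamental amplitude).
#'
#' @param frequency Stimulation frequency in Hz.
#' @param n_samples Number of samples to generate.
#' @param montage A [channel_montage()].
#' @param cfg A [sim_config()].
#' @param rng An [rng_stream()] or integer seed; defaults to `cfg$seed`.
#' @param distractor_freqs Optional frequencies of the two non-target stimuli.
#' @return An [eeg_segment()].
#' @export
generate_ssvep_segment <- function(frequency, n_samples,
                                   montage = channel_montage(),
                                   cfg = sim_config(), rng = NULL,
                                   distractor_freqs = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  src <- ssvep_source(frequency, montage, cfg,
                      rng = if (is.null(rng)) cfg$seed else rng,
                      distractor_freqs = distractor_freqs, signal_on = TRUE)
  eeg_segment(src$take(n_samples), fs = cfg$fs, onset_index = 0L,
              channels = montage$channels)
}

#' Generate background EEG noise only
#'
#' Same background model as [generate_ssvep_segment()] (1/f^beta broadband
#' noise, alpha rhythm, mains line) with the evoked component absent. For a
#' given seed, the background is sample-identical to the background embedded
#' in the corresponding SSVEP segment.
#'
#' @inheritParams generate_ssvep_segment
#' @return An [eeg_segment()].
#' @export
generate_noise <- function(n_samples, montage = channel_montage(),
                           cfg = sim_config(), rng = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  src <- ssvep_source(NA_real_, montage, cfg,
                      rng = if (is.null(rng)) cfg$seed else rng,
                      signal_on = FALSE)
  eeg_segment(src$take(n_samples), fs = cfg$fs, onset_index = 0L,
              channels = montage$channels)
}

#' Stream a digit's EEG as fixed-size acquisition blocks
#'
#' Returns a generator function producing consecutive blocks (default 30
#' samples, i.e. 50 ms at 600 Hz) of one continuous SSVEP realization.
#' Concatenating the blocks reproduces, sample for sample, the single-shot
#' segment of the same seed and total length: synthesis is phase- and
#' noise-continuous across block boundaries.
#'
#' @inheritParams generate_ssvep_segment
#' @param block_size Samples per block.
#' @return A function of no arguments; each call yields the next block as an
#'   [eeg_segment()] whose `onset_index` gives its position in the stream.
#' @export
ssvep_block_stream <- function(frequency, montage = channel_montage(),
                               cfg = sim_config(), rng = NULL,
                               distractor_freqs = NULL, block_size = 30L) {
  stopifnot(block_size >= 1)
  src <- ssvep_source(frequency, montage, cfg,
                      rng = if (is.null(rng)) cfg$seed else rng,
                      distractor_freqs = distractor_freqs,
                      signal_on = is.finite(frequency))
  function() {
    onset <- src$onset()
    eeg_segment(src$take(block_size), fs = cfg$fs, onset_index = onset,
                channels = montage$channels)
  }
}

#' Noise-only block stream
#'
#' Convenience wrapper over [ssvep_block_stream()] with the evoked component
#' absent, for chance-level and control experiments.
#'
#' @inheritParams ssvep_block_stream
#' @return A block generator function, as in [ssvep_block_stream()].
#' @export
noise_block_stream <- function(montage = channel_montage(), cfg = sim_config(),
                               rng = NULL, block_size = 30L) {
  ssvep_block_stream(NA_real_, montage, cfg, rng = rng, block_size = block_size)
}

#' Population-level parameter ranges for an in-silico cohort
#'
#' Defines the uniform sampling ranges from which per-subject simulation
#' parameters are drawn. Defaults model a cohort with moderate narrowband
#' SNR, Oz-dominant SSVEP pickup, mild channel-to-channel noise differences,
#' and variable alpha power; high-frequency stimulation is given a small SNR
#' penalty reflecting the weaker gamma-band SSVEP response.
#'
#' @param snr_db_range Range of narrowband SNR (dB) for low-frequency stimuli.
#' @param high_snr_offset_db Additive SNR offset (dB) applied under
#'   high-frequency stimulation.
#' @param ssvep_gain_range Per-channel SSVEP gain range (Oz is fixed at the
#'   range maximum; lateral channels are drawn from the range).
#' @param noise_gain_range Per-channel noise gain range.
#' @param alpha_amp_range Alpha-rhythm amplitude range.
#' @param line_amp Mains interference amplitude (fixed across subjects).
#' @return An object of class `population_config`.
#' @export
population_config <- function(snr_db_range = c(2, 10), high_snr_offset_db = -2,
                              ssvep_gain_range = c(0.6, 1.0),
                              noise_gain_range = c(0.8, 1.2),
                              alpha_amp_range = c(0.2, 0.8), line_amp = 0.1) {
  chk <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("invalid range for %s", nm), call. = FALSE)
    }
  }
  chk(snr_db_range, "snr_db_range"); chk(ssvep_gain_range, "ssvep_gain_range")
  chk(noise_gain_range, "noise_gain_range"); chk(alpha_amp_range, "alpha_amp_range")
  structure(list(snr_db_range = snr_db_range,
                 high_snr_offset_db = high_snr_offset_db,
                 ssvep_gain_range = ssvep_gain_range,
                 noise_gain_range = noise_gain_range,
                 alpha_amp_range = alpha_amp_range, line_amp = line_amp),
            class = "population_config")
}

#' Sample a synthetic subject's montage and simulation parameters
#'
#' Deterministic given (`subject_index`, `seed`): each subject draws from a
#' private stream derived from the master seed, so cohorts are reproducible
#' and subjects can be regenerated individually.
#'
#' @param subject_index Positive integer subject number.
#' @param population A [population_config()].
#' @param seed Master integer seed (or [rng_stream()] source seedling value).
#' @param frequency_set `"low"` or `"high"`; selects the SNR offset.
#' @return A list with elements `montage` ([channel_montage()]), `cfg`
#'   ([sim_config()]), and `snr_db`.
#' @export
sample_subject_profile <- function(subject_index, population = population_config(),
                                   seed = 1, frequency_set = c("low", "high")) {
  stopifnot(subject_index >= 1)
  frequency_set <- match.arg(frequency_set)
  rng <- rng_stream(derive_seed(seed, subject_index))
  draws <- with_rng(rng, function() {
    list(snr = stats::runif(1, population$snr_db_range[1], population$snr_db_range[2]),
         g_lat = stats::runif(2, population$ssvep_gain_range[1],
                              population$ssvep_gain_range[2]),
         g_noise = stats::runif(3, population$noise_gain_range[1],
                                population$noise_gain_range[2]),
         alpha = stats::runif(1, population$alpha_amp_range[1],
                              population$alpha_amp_range[2]))
  })
  snr <- draws$snr + if (frequency_set == "high") population$high_snr_offset_db else 0
  montage <- channel_montage(
    channels = c("O1", "Oz", "O2"),
    ssvep_gains = c(draws$g_lat[1], population$ssvep_gain_range[2], draws$g_lat[2]),
    noise_gains = draws$g_noise)
  cfg <- sim_config(snr_db = snr, alpha_amp = draws$alpha,
                    line_amp = population$line_amp,
                    seed = derive_seed(seed, 1000L + subject_index))
  list(montage = montage, cfg = cfg, snr_db = snr, subject_index = subject_index)
}

#' Restrict a montage to a subset of channels
#'
#' @param montage A [channel_montage()].
#' @param channels Channel names to keep (e.g. `"Oz"` for the
#'   single-electrode condition).
#' @return A [channel_montage()] over the selected channels.
#' @export
subset_montage <- function(montage, channels) {
  idx <- match(channels, montage$channels)
  if (anyNA(idx)) stop("unknown channel in subset", call. = FALSE)
  channel_montage(montage$channels[idx], montage$ssvep_gains[idx],
                  montage$noise_gains[idx])
}
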