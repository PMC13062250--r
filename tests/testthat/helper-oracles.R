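# Shared fixtures and independent oracles used across the suite.

# Noise-free simulation config: pure evoked component, unit fundamental.
noise_free_cfg <- function(seed = 1, harmonic_count = 1, ...) {
  sim_config(noise_sd = 0, alpha_amp = 0, line_amp = 0,
             harmonic_count = harmonic_count, seed = seed, ...)
}

# Single-channel pure tone as an eeg_segment.
tone_segment <- function(f, n, fs = 600, amp = 1, phase = 0, channels = "Oz") {
  t <- (0:(n - 1)) / fs
  eeg_segment(matrix(amp * sin(2 * pi * f * t + phase), 1), fs,
              channels = channels)
}

# Frequency (Hz) of the largest DFT magnitude of a single channel.
dominant_frequency <- function(x, fs) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[1:(n %/% 2 + 1)]
  (which.max(mag) - 1) * fs / n
}

# DFT amplitude at one frequency (assumes f on the DFT grid).
dft_amplitude <- function(x, f, fs) {
  n <- length(x)
  k <- round(f * n / fs)
  2 * Mod(stats::fft(x)[k + 1]) / n
}

# Leakage-free sinusoid amplitude at f: least-squares projection onto the
# sin/cos pair (valid off the DFT grid).
fitted_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(sum(co[2:3]^2))
}

# Brute-force first canonical correlation: explicitly form the covariance
# blocks and solve the generalized eigenvalue problem
# Sxx^-1 Sxy Syy^-1 Syx. Independent of the QR/SVD implementation.
cca_bruteforce <- function(X, Y) {
  Xc <- t(X - rowMeans(X))
  Yc <- t(Y - rowMeans(Y))
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  sqrt(max(0, max(Re(eigen(M, only.values = TRUE)$values))))
}

# RMS of the second half of a vector (past any filter transient).
steady_rms <- function(x) {
  tail_part <- x[(length(x) %/% 2 + 1):length(x)]
  sqrt(mean(tail_part^2))
}

# dB magnitude of a filter at given frequencies.
resp_db <- function(spec, f) 20 * log10(Mod(filter_response(spec, f)))

# Two-sided 99% binomial acceptance interval for a proportion.
binom99 <- function(n, p) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p)) / n
}

# Textbook summary statistics, written independently of summary_stats().
summary_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  list(mean = m, sd = s, ci = c(m - half, m + half))
}
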