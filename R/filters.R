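#' Design a Butterworth band-pass filter
#'
#' Digital Butterworth design with the conventional -3 dB band edges at
#' `low` and `high`. `order` counts poles of the final band-pass filter
#' (an order-4 band-pass comes from an order-2 low-pass prototype), so it
#' must be even.
#'
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Total filter order (even, default 4).
#' @return An object of class `filter_spec` with fields `kind`, `low`,
#'   `high`, `order`, `fs` and coefficient vectors `b`, `a`.
#' @export
design_bandpass <- function(low, high, fs, order = 4) {
  design_iir(low, high, fs, order, kind = "bandpass")
}

#' Design a Butterworth band-stop (notch) filter
#'
#' Default band 48-52 Hz: the mains notch of the amplifier front end.
#'
#' @inheritParams design_bandpass
#' @return A `filter_spec` of kind `"bandstop"`.
#' @export
design_notch <- function(low = 48, high = 52, fs, order = 4) {
  design_iir(low, high, fs, order, kind = "bandstop")
}

design_iir <- function(low, high, fs, order, kind) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low) {
    stop("need 0 < low < high", call. = FALSE)
  }
  if (high >= fs / 2) stop("upper cutoff must be below Nyquist (fs/2)", call. = FALSE)
  if (order < 2 || order %% 2 != 0) stop("order must be a positive even number", call. = FALSE)
  flt <- signal::butter(order / 2, c(low, high) / (fs / 2),
                        type = if (kind == "bandpass") "pass" else "stop")
  spec <- structure(list(kind = kind, low = low, high = high, order = order,
                         fs = fs, b = as.numeric(flt$b), a = as.numeric(flt$a)),
                    class = "filter_spec")
  if (!filter_stable(spec)) stop("designed filter is unstable", call. = FALSE)
  spec
}

#' Filter stability check
#'
#' @param spec A `filter_spec`.
#' @return `TRUE` when all poles lie strictly inside the unit circle.
#' @export
filter_stable <- function(spec) {
  a <- spec$a
  if (length(a) <= 1) return(TRUE)
  all(Mod(polyroot(rev(a))) < 1)
}

#' Complex frequency response of a designed filter
#'
#' @param spec A `filter_spec`.
#' @param f Frequencies in Hz at which to evaluate the response.
#' @return Complex vector `H(f)`; use `20*log10(Mod(...))` for dB magnitude.
#' @export
filter_response <- function(spec, f) {
  z <- exp(-1i * 2 * pi * f / spec$fs)
  pv <- function(coef) {
    acc <- 0 + 0i
    for (k in seq_along(coef)) acc <- acc + coef[k] * z^(k - 1)
    acc
  }
  pv(spec$b) / pv(spec$a)
}

# Single-pass causal IIR filtering via stats::filter (convolution for the MA
# part, recursion for the AR part); zero initial conditions.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v[nb - 1 + seq_along(x)])
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v / a[1], -a[-1] / a[1], method = "recursive"))
  } else {
    v <- v / a[1]
  }
  v
}

#' Apply a filter to a signal
#'
#' Zero-phase mode (the default) runs the filter forward and backward over
#' the signal extended at both ends by odd-reflection padding, then discards
#' the padding: the effective magnitude response is `|H|^2` and the group
#' delay is zero. Causal mode is a single forward pass with zero initial
#' state. The padding length is deterministic and part of the call, so
#' results are bit-reproducible.
#'
#' @param spec A `filter_spec`.
#' @param x Numeric vector (one channel).
#' @param zero_phase Use forward-backward filtering (default `TRUE`).
#' @param pad Reflection padding length per end; default
#'   `3 * (length(spec$a) - 1)`.
#' @return Filtered numeric vector of the same length as `x`.
#' @export
apply_filter <- function(spec, x, zero_phase = TRUE, pad = NULL) {
  if (!zero_phase) return(iir_filter(spec$b, spec$a, x))
  if (is.null(pad)) pad <- 3L * (length(spec$a) - 1L)
  n <- length(x)
  if (n <= pad) {
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)", pad),
         call. = FALSE)
  }
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter(spec$b, spec$a, xp)
  y <- rev(iir_filter(spec$b, spec$a, rev(y)))
  y[pad + seq_len(n)]
}

#' Amplifier digital front end
#'
#' Bundles the acquisition-side digital filters: a 48-52 Hz mains notch
#' followed by a 2-60 Hz band-pass, both 4th-order Butterworth. The
#' application order is fixed for reproducibility (it is immaterial for
#' linear time-invariant filters).
#'
#' @param fs Sampling rate in Hz.
#' @param notch,bandpass Band edges in Hz.
#' @param order Filter order for both stages.
#' @return A list of two `filter_spec`s, class `front_end`.
#' @export
front_end <- function(fs = 600, notch = c(48, 52), bandpass = c(2, 60), order = 4) {
  structure(list(notch = design_notch(notch[1], notch[2], fs, order),
                 bandpass = design_bandpass(bandpass[1], bandpass[2], fs, order)),
            class = "front_end")
}

#' Apply the acquisition front end to a segment
#'
#' @param segment An [eeg_segment()].
#' @param fe A [front_end()]; defaults to the standard one at the segment's rate.
#' @param zero_phase Zero-phase (forward-backward) application; set `FALSE`
#'   for the causal single-pass variant.
#' @return The filtered [eeg_segment()], same dimensions.
#' @export
apply_front_end <- function(segment, fe = NULL, zero_phase = TRUE) {
  if (is.null(fe)) fe <- front_end(fs = segment$fs)
  if (fe$notch$fs != segment$fs) stop("front end designed at a different fs", call. = FALSE)
  y <- segment$samples
  for (i in seq_len(nrow(y))) {
    v <- apply_filter(fe$notch, y[i, ], zero_phase = zero_phase)
    y[i, ] <- apply_filter(fe$bandpass, v, zero_phase = zero_phase)
  }
  eeg_segment(y, fs = segment$fs, onset_index = segment$onset_index,
              channels = segment$channels)
}

#' Sub-band filter bank
#'
#' An ordered set of Butterworth band-pass filters used to decompose the EEG
#' buffer before canonical correlation. The low-frequency stimulation set
#' uses three sub-bands (2-60, 12-60, 20-60 Hz) targeting the fundamental
#' and progressively the harmonics; the high-frequency set uses the single
#' band 35-60 Hz.
#'
#' @param ranges List of `c(low, high)` pairs in Hz, in sub-band order.
#' @param fs Sampling rate in Hz.
#' @param order Filter order for each sub-band.
#' @return An object of class `subband_bank`.
#' @export
subband_bank <- function(ranges, fs = 600, order = 4) {
  if (length(ranges) < 1L) stop("need at least one sub-band", call. = FALSE)
  specs <- lapply(ranges, function(r) design_bandpass(r[1], r[2], fs, order))
  structure(list(ranges = ranges, specs = specs, fs = fs, order = order),
            class = "subband_bank")
}

#' @rdname subband_bank
#' @param set `"low"` or `"high"` stimulation frequency set.
#' @export
standard_subband_bank <- function(set = c("low", "high"), fs = 600, order = 4) {
  set <- match.arg(set)
  ranges <- if (set == "low") {
    list(c(2, 60), c(12, 60), c(20, 60))
  } else {
    list(c(35, 60))
  }
  subband_bank(ranges, fs = fs, order = order)
}

#' Extract one sub-band of a buffer
#'
#' Zero-phase forward-backward filtering of the whole buffer snapshot with
#' the indexed sub-band filter (see [apply_filter()] for edge handling).
#'
#' @param segment An [eeg_segment()].
#' @param subband_index 1-based sub-band index.
#' @param bank A [subband_bank()].
#' @return The filtered [eeg_segment()].
#' @export
apply_subband <- function(segment, subband_index, bank) {
  if (subband_index < 1 || subband_index > length(bank$specs)) {
    stop("subband_index out of range", call. = FALSE)
  }
  if (bank$fs != segment$fs) stop("bank designed at a different fs", call. = FALSE)
  spec <- bank$specs[[subband_index]]
  y <- segment$samples
  for (i in seq_len(nrow(y))) y[i, ] <- apply_filter(spec, y[i, ])
  eeg_segment(y, fs = segment$fs, onset_index = segment$onset_index,
              channels = segment$channels)
}

#' Serialize filter specifications to JSON
#'
#' @param specs A `filter_spec`, `front_end`, or `subband_bank`.
#' @param path Optional output file; when `NULL`, the JSON string is returned.
#' @return JSON (invisibly when written to file).
#' @export
filters_to_json <- function(specs, path = NULL) {
  unclassify <- function(x) {
    if (is.list(x)) lapply(unclass(x), unclassify) else x
  }
  js <- jsonlite::toJSON(unclassify(specs), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
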