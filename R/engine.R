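#' Streaming decision-engine parameters
#'
#' Constants of the online classifier loop: EEG arrives in `block_size`
#' sample blocks (30 samples = 50 ms at 600 Hz, a 20 Hz evaluation rate);
#' no decision is issued before `min_samples` have accumulated since the
#' last reset; the buffer slides once it reaches `max_buffer` samples; a
#' decision requires the FBCCA margin to reach `threshold`; each decision is
#' followed by a `gaze_shift_s` second pause during which incoming blocks
#' are discarded and the buffer stays empty.
#'
#' @param block_size Samples per acquisition block.
#' @param min_samples Minimum buffered samples before any evaluation.
#' @param max_buffer Sliding-window cap in samples.
#' @param threshold Margin threshold in combined-score units.
#' @param gaze_shift_s Post-decision pause in seconds.
#' @param fs Sampling rate in Hz.
#' @return An object of class `decision_params`.
#' @export
decision_params <- function(block_size = 30L, min_samples = 300L,
                            max_buffer = 1800L, threshold = 0.30,
                            gaze_shift_s = 0.5, fs = 600) {
  block_size <- as.integer(block_size)
  min_samples <- as.integer(min_samples)
  max_buffer <- as.integer(max_buffer)
  stopifnot(block_size > 0, min_samples > 0, max_buffer > 0,
            threshold >= 0, gaze_shift_s >= 0, fs > 0)
  if (min_samples > max_buffer) stop("min_samples must be <= max_buffer", call. = FALSE)
  if (min_samples %% block_size != 0) {
    stop("block_size must divide min_samples (evaluation grid)", call. = FALSE)
  }
  structure(list(block_size = block_size, min_samples = min_samples,
                 max_buffer = max_buffer, threshold = threshold,
                 gaze_shift_s = gaze_shift_s, fs = fs),
            class = "decision_params")
}

#' Fresh engine state
#'
#' @param params A [decision_params()].
#' @param phase `"collecting"` (default) or `"gaze_shift"` to start inside
#'   the post-decision pause.
#' @param log Record every evaluation in `evaluation_log` (default `TRUE`).
#' @return An object of class `engine_state`.
#' @export
engine_new <- function(params, phase = c("collecting", "gaze_shift"), log = TRUE) {
  phase <- match.arg(phase)
  structure(list(buffer = NULL, samples_since_reset = 0L, phase = phase,
                 gaze_shift_remaining = if (phase == "gaze_shift") {
                   as.integer(round(params$gaze_shift_s * params$fs))
                 } else 0L,
                 evaluation_log = list(), log = isTRUE(log)),
            class = "engine_state")
}

#' Clear the engine for the next digit
#'
#' Empties the buffer, zeroes the sample counter, and enters the gaze-shift
#' phase, during which incoming blocks are discarded. Idempotent on buffer
#' emptiness.
#'
#' @param state An `engine_state`.
#' @param params A [decision_params()].
#' @return The reset `engine_state`.
#' @export
reset_for_next_digit <- function(state, params) {
  state$buffer <- NULL
  state$samples_since_reset <- 0L
  state$phase <- "gaze_shift"
  state$gaze_shift_remaining <- as.integer(round(params$gaze_shift_s * params$fs))
  state$evaluation_log <- list()
  state
}

#' Ingest one acquisition block
#'
#' The engine's single step. In the gaze-shift phase the block is discarded
#' and the countdown decremented. Otherwise the block is appended (dropping
#' the oldest samples beyond `max_buffer`), and once at least `min_samples`
#' have accumulated since the last reset, FBCCA scores are computed on the
#' current buffer and the margin rule applied. On acceptance the
#' classification event is returned, the buffer cleared, and the gaze-shift
#' phase entered.
#'
#' @param state An `engine_state`.
#' @param block An [eeg_segment()] of exactly `block_size` samples.
#' @param params A [decision_params()].
#' @param fbcca An [fbcca_params()].
#' @return A list `(state, event)`; `event` is `NULL` or a
#'   `classification_event` with `decided_index`, `frequency`, `margin`,
#'   `latency_samples`, `latency_s`.
#' @export
ingest_block <- function(state, block, params, fbcca) {
  if (ncol(block$samples) != params$block_size) {
    stop("block must have exactly block_size samples", call. = FALSE)
  }
  if (!is.null(state$buffer) && nrow(block$samples) != nrow(state$buffer)) {
    stop("channel count changed mid-stream", call. = FALSE)
  }
  if (state$phase == "gaze_shift") {
    state$gaze_shift_remaining <- state$gaze_shift_remaining - params$block_size
    if (state$gaze_shift_remaining <= 0L) {
      state$phase <- "collecting"
      state$gaze_shift_remaining <- 0L
    }
    return(list(state = state, event = NULL))
  }
  state$buffer <- if (is.null(state$buffer)) block$samples else
    cbind(state$buffer, block$samples)
  if (ncol(state$buffer) > params$max_buffer) {
    keep <- ncol(state$buffer) - params$max_buffer
    state$buffer <- state$buffer[, -seq_len(keep), drop = FALSE]
  }
  state$samples_since_reset <- state$samples_since_reset + params$block_size
  event <- NULL
  if (state$samples_since_reset >= params$min_samples) {
    scores <- fbcca_scores(eeg_segment(state$buffer, fs = params$fs), fbcca)
    hit <- select_target(scores, params$threshold)
    if (state$log) {
      state$evaluation_log[[length(state$evaluation_log) + 1L]] <-
        list(t_sample = state$samples_since_reset, combined = scores$combined,
             margin = scores$margin, decided = !is.null(hit))
    }
    if (!is.null(hit)) {
      event <- structure(list(decided_index = hit$index,
                              frequency = hit$frequency, margin = hit$margin,
                              latency_samples = state$samples_since_reset,
                              latency_s = state$samples_since_reset / params$fs),
                         class = "classification_event")
      log_kept <- state$evaluation_log
      state <- reset_for_next_digit(state, params)
      state$evaluation_log <- log_kept   # keep the decided digit's trace
    }
  }
  list(state = state, event = event)
}

#' Run the engine on one digit's block stream
#'
#' Pulls blocks from `stream` until a classification event fires, then
#' annotates it with the decoded digit and its correctness. Latency counts
#' only the collecting phase (gaze-shift blocks consumed at the start of a
#' stream, if the state begins in that phase, are excluded), matching the
#' definition of per-digit latency used in trial timing.
#'
#' @param stream A block generator as returned by [ssvep_block_stream()].
#' @param true_digit The digit actually encoded by the stream (for scoring).
#' @param params A [decision_params()].
#' @param fbcca An [fbcca_params()].
#' @param digits Digit alphabet mapped to frequency indices (default 1:3).
#' @param state Optional starting `engine_state` (e.g. one inside the
#'   gaze-shift phase after a previous decision).
#' @param max_duration_s Optional guard: raise an error if no decision fires
#'   within this many seconds of collected signal (default `Inf`, i.e. off).
#' @param on_timeout `"error"` (default) or `"decide"` to force the current
#'   best-scoring frequency when the guard trips.
#' @return A `classification_event` with added fields `decided_digit`,
#'   `true_digit`, `correct`, `evaluation_log`, `forced`.
#' @export
run_digit <- function(stream, true_digit, params, fbcca, digits = 1:3,
                      state = NULL, max_duration_s = Inf,
                      on_timeout = c("error", "decide")) {
  on_timeout <- match.arg(on_timeout)
  if (is.null(state)) state <- engine_new(params)
  max_samples <- if (is.finite(max_duration_s)) {
    as.integer(round(max_duration_s * params$fs))
  } else NA_integer_
  forced <- FALSE
  repeat {
    step <- ingest_block(state, stream(), params, fbcca)
    state <- step$state
    if (!is.null(step$event)) {
      event <- step$event
      break
    }
    if (!is.na(max_samples) && state$samples_since_reset >= max_samples) {
      if (on_timeout == "error") {
        stop(sprintf("no decision within %.1f s of signal", max_duration_s),
             call. = FALSE)
      }
      scores <- fbcca_scores(eeg_segment(state$buffer, fs = params$fs), fbcca)
      event <- structure(list(decided_index = scores$winner,
                              frequency = scores$frequencies[scores$winner],
                              margin = scores$margin,
                              latency_samples = state$samples_since_reset,
                              latency_s = state$samples_since_reset / params$fs),
                         class = "classification_event")
      forced <- TRUE
      log_kept <- state$evaluation_log
      state <- reset_for_next_digit(state, params)
      state$evaluation_log <- log_kept
      break
    }
  }
  event$decided_digit <- digits[event$decided_index]
  event$true_digit <- true_digit
  event$correct <- identical(as.integer(event$decided_digit), as.integer(true_digit))
  event$evaluation_log <- state$evaluation_log
  event$forced <- forced
  event
}
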