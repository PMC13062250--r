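#' Stimulation frequency set and digit codebook
#'
#' The one-time code alphabet {1, 2, 3} maps to flicker frequencies that are
#' integer divisors of the 360 Hz monitor refresh rate: the low set
#' 1 -> 6.67 Hz, 2 -> 7.50 Hz, 3 -> 8.57 Hz (360/54, 360/48, 360/42) and the
#' high set 1 -> 36 Hz, 2 -> 40 Hz, 3 -> 45 Hz. Each set carries its
#' matching [fbcca_params()] (H = 4 with three sub-bands for the low set;
#' H = 1 with the single 35-60 Hz band for the high set, whose second
#' harmonics start at 72 Hz, above the 60 Hz front-end limit).
#'
#' @param name `"low"` or `"high"`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `frequency_set` with fields `name`, `digits`,
#'   `frequencies`, and `fbcca`.
#' @export
frequency_set <- function(name = c("low", "high"), fs = 600) {
  name <- match.arg(name)
  freqs <- if (name == "low") c(6.67, 7.50, 8.57) else c(36, 40, 45)
  structure(list(name = name, digits = 1:3, frequencies = freqs,
                 fbcca = fbcca_params(name, fs = fs)),
            class = "frequency_set")
}

#' Digit/frequency codebook lookups
#'
#' @param digit A digit in the code alphabet.
#' @param set A [frequency_set()].
#' @return `digit_to_frequency`: the flicker frequency in Hz.
#' @export
digit_to_frequency <- function(digit, set) {
  i <- match(as.integer(digit), set$digits)
  if (is.na(i)) stop(sprintf("digit %s not in codebook", format(digit)), call. = FALSE)
  set$frequencies[i]
}

#' @rdname digit_to_frequency
#' @param frequency A flicker frequency in Hz.
#' @return `frequency_to_digit`: the encoded digit.
#' @export
frequency_to_digit <- function(frequency, set) {
  i <- which(abs(set$frequencies - frequency) < 1e-6)
  if (length(i) != 1L) {
    stop(sprintf("frequency %g not in codebook", frequency), call. = FALSE)
  }
  set$digits[i]
}

#' Generate a random one-time code
#'
#' i.i.d. uniform symbols over the alphabet, reproducible given the seed.
#'
#' @param length Code length (default 8).
#' @param alphabet Symbol set (default 1:3).
#' @param rng An [rng_stream()] or integer seed.
#' @return Integer vector of code symbols.
#' @export
generate_code <- function(length = 8L, alphabet = 1:3, rng = 1) {
  if (length < 1) stop("code length must be >= 1", call. = FALSE)
  if (base::length(alphabet) < 1) stop("alphabet must be non-empty", call. = FALSE)
  rng <- rng_stream(rng)
  with_rng(rng, function() sample(alphabet, length, replace = TRUE))
}

#' Run one authentication trial
#'
#' Simulates the full decoding of one 8-digit code: for each digit a fresh
#' SSVEP block stream at the digit's flicker frequency (with the two
#' non-target frequencies available as distractors) is pushed through the
#' streaming engine until its margin rule fires. An incorrect decision still
#' advances to the next digit. Accuracy is the fraction of the 8 digits
#' decoded correctly; completion time is the sum of per-digit latencies plus
#' the inter-digit gaze-shift windows (the trial clock runs from first
#' stimulus onset to the final classification, spanning the 7 resets).
#'
#' @param set A [frequency_set()] (or `"low"`/`"high"`).
#' @param montage A [channel_montage()] (1 channel = Oz condition,
#'   3 channels = O1/Oz/O2 condition).
#' @param cfg A [sim_config()] for the subject.
#' @param params A [decision_params()].
#' @param rng An [rng_stream()] or integer seed.
#' @param code Optional fixed code (default: freshly generated from `rng`).
#' @param n_digits Code length when generating.
#' @param max_duration_s Per-digit guard passed to [run_digit()]
#'   (default `Inf`: no timeout).
#' @param on_timeout See [run_digit()].
#' @return An object of class `trial_result` with fields `code`, `decoded`,
#'   `per_digit_latency_s`, `accuracy`, `completion_time_s`, `condition`,
#'   `events`.
#' @export
run_trial <- function(set, montage = channel_montage(), cfg = sim_config(),
                      params = decision_params(), rng = 1, code = NULL,
                      n_digits = 8L, max_duration_s = Inf,
                      on_timeout = c("error", "decide")) {
  if (is.character(set)) set <- frequency_set(set)
  on_timeout <- match.arg(on_timeout)
  rng <- rng_stream(rng)
  if (is.null(code)) code <- generate_code(n_digits, set$digits, rng)
  events <- vector("list", length(code))
  for (i in seq_along(code)) {
    f_target <- digit_to_frequency(code[i], set)
    stream <- ssvep_block_stream(
      f_target, montage, cfg, rng = rng,
      distractor_freqs = setdiff(set$frequencies, f_target),
      block_size = params$block_size)
    events[[i]] <- run_digit(stream, code[i], params, set$fbcca,
                             digits = set$digits,
                             max_duration_s = max_duration_s,
                             on_timeout = on_timeout)
  }
  decoded <- vapply(events, function(e) as.integer(e$decided_digit), integer(1))
  lat <- vapply(events, function(e) e$latency_s, numeric(1))
  structure(list(code = as.integer(code), decoded = decoded,
                 per_digit_latency_s = lat,
                 accuracy = mean(decoded == code),
                 completion_time_s = sum(lat) +
                   (length(code) - 1L) * params$gaze_shift_s,
                 condition = list(electrodes = length(montage$channels),
                                  set = set$name),
                 events = events),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s set, %d electrode(s)\n", x$condition$set,
              x$condition$electrodes))
  cat(sprintf("  code:    %s\n", paste(x$code, collapse = "")))
  cat(sprintf("  decoded: %s\n", paste(x$decoded, collapse = "")))
  cat(sprintf("  accuracy %.3f, completion %.2f s\n", x$accuracy,
              x$completion_time_s))
  invisible(x)
}

#' Calibration search configuration
#'
#' @param thresholds Threshold grid (default 0.20 to 0.50 in 0.05 steps).
#' @param window_step Minimum-window extension per round, in samples.
#' @param window_max Largest minimum window tried, in samples.
#' @param n_digits Calibration digits evaluated per (window, threshold) cell.
#' @param target_accuracy Accuracy at which the search stops (default 1).
#' @param max_duration_s Per-digit cap during calibration; timed-out digits
#'   are force-decided so that a cell always yields an accuracy.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(thresholds = seq(0.20, 0.50, by = 0.05),
                               window_step = 30L, window_max = 600L,
                               n_digits = 8L, target_accuracy = 1,
                               max_duration_s = 5) {
  if (length(thresholds) < 1) stop("empty threshold grid", call. = FALSE)
  if (window_step < 1 || window_max < 300L) stop("invalid window grid", call. = FALSE)
  structure(list(thresholds = thresholds, window_step = as.integer(window_step),
                 window_max = as.integer(window_max), n_digits = as.integer(n_digits),
                 target_accuracy = target_accuracy, max_duration_s = max_duration_s),
            class = "calibration_config")
}

#' Per-subject calibration of threshold and minimum window
#'
#' Greedy search mirroring the experimenter's procedure: at the current
#' minimum window, sweep the threshold grid over a batch of calibration
#' digits; if no threshold reaches the target accuracy, extend the minimum
#' window by `window_step` samples and repeat, stopping at the target or
#' when the window grid is exhausted, returning the best cell seen.
#'
#' @param set A [frequency_set()] (or name).
#' @param montage,cfg Subject simulation parameters.
#' @param calib A [calibration_config()].
#' @param params Base [decision_params()] supplying the non-searched constants.
#' @param rng An [rng_stream()] or integer seed.
#' @return An object of class `calibration_result`: `threshold`,
#'   `min_samples`, `achieved_accuracy`, `search_trace` (data.frame with one
#'   row per evaluated cell, in evaluation order).
#' @export
calibrate <- function(set, montage = channel_montage(), cfg = sim_config(),
                      calib = calibration_config(), params = decision_params(),
                      rng = 1) {
  if (is.character(set)) set <- frequency_set(set)
  rng <- rng_stream(rng)
  windows <- seq(params$min_samples, calib$window_max, by = calib$window_step)
  trace <- list()
  best <- list(acc = -1, threshold = NA_real_, window = NA_integer_)
  for (w in windows) {
    for (th in calib$thresholds) {
      p <- decision_params(block_size = params$block_size, min_samples = w,
                           max_buffer = max(params$max_buffer, w),
                           threshold = th, gaze_shift_s = params$gaze_shift_s,
                           fs = params$fs)
      digits <- generate_code(calib$n_digits, set$digits, rng)
      correct <- vapply(digits, function(d) {
        stream <- ssvep_block_stream(
          digit_to_frequency(d, set), montage, cfg, rng = rng,
          distractor_freqs = setdiff(set$frequencies, digit_to_frequency(d, set)),
          block_size = p$block_size)
        run_digit(stream, d, p, set$fbcca, digits = set$digits,
                  max_duration_s = calib$max_duration_s,
                  on_timeout = "decide")$correct
      }, logical(1))
      acc <- mean(correct)
      trace[[length(trace) + 1L]] <- data.frame(window = w, threshold = th,
                                                accuracy = acc)
      if (acc > best$acc) best <- list(acc = acc, threshold = th, window = w)
      if (best$acc >= calib$target_accuracy) break
    }
    if (best$acc >= calib$target_accuracy) break
  }
  structure(list(threshold = best$threshold, min_samples = best$window,
                 achieved_accuracy = best$acc,
                 search_trace = do.call(rbind, trace)),
            class = "calibration_result")
}

#' Cohort configuration for an in-silico experiment
#'
#' @param n_subjects Number of synthetic subjects (default 21).
#' @param trials_per_condition Trials per subject per condition (default 4).
#' @param seed Master seed.
#' @param population A [population_config()].
#' @param params A [decision_params()].
#' @param max_duration_s Per-digit cap (timed-out digits are force-decided),
#'   bounding cohort runtime for low-SNR subjects.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 21L, trials_per_condition = 4L,
                          seed = 1, population = population_config(),
                          params = decision_params(), max_duration_s = 20) {
  stopifnot(n_subjects >= 1, trials_per_condition >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 seed = seed, population = population, params = params,
                 max_duration_s = max_duration_s),
            class = "cohort_config")
}

# The four experimental conditions, in reporting order.
experiment_conditions <- function() {
  list(list(set = "low", electrodes = 3L, label = "lf3"),
       list(set = "high", electrodes = 3L, label = "hf3"),
       list(set = "low", electrodes = 1L, label = "lf1"),
       list(set = "high", electrodes = 1L, label = "hf1"))
}

#' Run a full in-silico cohort experiment
#'
#' For each synthetic subject and each of the four conditions (3 or 1
#' occipital electrodes crossed with the low/high frequency set), runs the
#' configured number of 8-digit authentication trials and tabulates accuracy
#' and completion time. Counterbalancing of condition order (odd-numbered
#' subjects starting with the high-frequency set) is recorded as metadata;
#' it does not alter the simulation, which has no fatigue model.
#'
#' @param cohort A [cohort_config()].
#' @param progress Print one line per subject.
#' @return A list with `trials` (one row per trial), `subjects` (per-subject
#'   per-condition means), and `summary` (per-condition cohort mean, SD and
#'   95\% CI, via [summary_stats()]).
#' @export
run_experiment <- function(cohort = cohort_config(), progress = FALSE) {
  conds <- experiment_conditions()
  rows <- list()
  for (s in seq_len(cohort$n_subjects)) {
    started_high <- s %% 2L == 1L
    for (cond in conds) {
      prof <- sample_subject_profile(s, cohort$population, seed = cohort$seed,
                                     frequency_set = cond$set)
      montage <- if (cond$electrodes == 1L) subset_montage(prof$montage, "Oz")
                 else prof$montage
      fset <- frequency_set(cond$set)
      for (tr in seq_len(cohort$trials_per_condition)) {
        trial_seed <- derive_seed(cohort$seed,
                                  s * 10000L + match(cond$label, c("lf3", "hf3", "lf1", "hf1")) * 100L + tr)
        res <- run_trial(fset, montage, prof$cfg, cohort$params,
                         rng = trial_seed,
                         max_duration_s = cohort$max_duration_s,
                         on_timeout = "decide")
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = cond$label, set = cond$set,
          electrodes = cond$electrodes, trial = tr,
          accuracy_pct = 100 * res$accuracy,
          time_s = res$completion_time_s,
          snr_db = prof$snr_db, started_high = started_high)
      }
    }
    if (progress) message(sprintf("subject %d/%d done", s, cohort$n_subjects))
  }
  trials <- do.call(rbind, rows)
  subjects <- stats::aggregate(cbind(accuracy_pct, time_s) ~ subject + condition,
                               data = trials, FUN = mean)
  summary <- summarize_conditions(subjects)
  list(trials = trials, subjects = subjects, summary = summary)
}

#' Mean, SD and 95 percent confidence interval of per-subject values
#'
#' Sample mean, sample SD (n - 1 denominator) and the Student-t 95\% CI
#' `mean +/- t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param x Numeric vector of per-subject values (n >= 2).
#' @return A list with `mean`, `sd`, `ci` (length-2), `n`.
#' @export
summary_stats <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least two values for SD and CI", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  list(mean = m, sd = s, ci = c(m - half, m + half), n = n)
}

#' Per-condition summary table from per-subject means
#'
#' @param subjects Data frame with columns `subject`, `condition`,
#'   `accuracy_pct`, `time_s` (one row per subject per condition).
#' @return Data frame with one row per condition: mean/SD/CI of accuracy and
#'   completion time across subjects.
#' @export
summarize_conditions <- function(subjects) {
  out <- lapply(split(subjects, subjects$condition), function(d) {
    a <- summary_stats(d$accuracy_pct)
    t_ <- summary_stats(d$time_s)
    data.frame(condition = d$condition[1], n_subjects = a$n,
               mean_accuracy_pct = a$mean, sd_accuracy_pct = a$sd,
               ci_lo_accuracy = a$ci[1], ci_hi_accuracy = a$ci[2],
               mean_time_s = t_$mean, sd_time_s = t_$sd,
               ci_lo_time = t_$ci[1], ci_hi_time = t_$ci[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  ord <- match(c("lf3", "hf3", "lf1", "hf1"), res$condition)
  res[ord[!is.na(ord)], , drop = FALSE]
}

#' Published per-subject reference results
#'
#' The transcribed per-subject accuracies (%) and completion times (s) of
#' the 21-participant online study, for the four conditions: LF/HF
#' stimulation crossed with 3/1 electrodes. Used to recompute the reported
#' condition summaries.
#'
#' @return A data.frame with columns `subject`, `condition`
#'   (lf3/hf3/lf1/hf1), `accuracy_pct`, `time_s`.
#' @export
reference_results <- function() {
  path <- system.file("extdata", "reference_study_results.csv",
                      package = "ssvepauth", mustWork = TRUE)
  wide <- utils::read.csv(path, check.names = FALSE)
  long <- do.call(rbind, lapply(c("lf3", "hf3", "lf1", "hf1"), function(cc) {
    data.frame(subject = wide$subject, condition = cc,
               accuracy_pct = wide[[paste0("acc_", cc)]],
               time_s = wide[[paste0("time_", cc)]])
  }))
  long
}
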