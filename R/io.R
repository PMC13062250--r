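#' Write an EEG segment to CSV with a JSON sidecar
#'
#' The CSV holds one row per sample with a `time` column (seconds) followed
#' by one column per channel; the sidecar `<path>.json` records the sampling
#' rate, montage and any provenance passed in `meta`, so the file pair is
#' self-describing and diffable.
#'
#' @param segment An [eeg_segment()].
#' @param path Output CSV path.
#' @param montage Optional [channel_montage()] stored in the sidecar.
#' @param meta Optional named list merged into the sidecar (e.g. seed,
#'   simulation config).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(segment, path, montage = NULL, meta = list()) {
  n <- ncol(segment$samples)
  df <- data.frame(time = (seq_len(n) - 1 + segment$onset_index) / segment$fs)
  for (i in seq_along(segment$channels)) df[[segment$channels[i]]] <- segment$samples[i, ]
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- c(list(fs = segment$fs, channels = segment$channels,
                    onset_index = segment$onset_index,
                    montage = if (!is.null(montage)) unclass(montage)), meta)
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EEG segment written by [write_eeg()]
#'
#' @param path CSV path; the sidecar `<path>.json` must exist.
#' @param format Only `"csv"` is supported.
#' @return A list with `segment` ([eeg_segment()]) and `meta` (sidecar list).
#' @export
read_eeg <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("missing JSON sidecar: %s", sidecar_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  channels <- as.character(meta$channels)
  missing <- setdiff(channels, names(df))
  if (length(missing)) {
    stop(sprintf("channels in sidecar absent from CSV: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  samples <- t(as.matrix(df[, channels, drop = FALSE]))
  seg <- eeg_segment(samples, fs = meta$fs,
                     onset_index = if (is.null(meta$onset_index)) 0L
                                   else meta$onset_index,
                     channels = channels)
  list(segment = seg, meta = meta)
}

#' Write an engine evaluation log as JSON lines
#'
#' One record per evaluation: buffered sample count, combined scores, margin
#' and whether a decision fired.
#'
#' @param log The `evaluation_log` list from an engine state or event.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in log) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Round-trip a run configuration through YAML
#'
#' @param config Named list of run settings.
#' @param path YAML file path.
#' @return For `write_run_config`, `path` invisibly; for `read_run_config`,
#'   the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}

#' Default numeric constants of the shipped configuration
#'
#' Reads the packaged constants manifest (acquisition, engine and FBCCA
#' defaults) used to cross-check that the exported constructors agree with
#' the shipped example configuration.
#'
#' @return Nested list of default constants.
#' @export
default_constants <- function() {
  jsonlite::read_json(system.file("extdata", "default_constants.json",
                                  package = "ssvepauth", mustWork = TRUE),
                      simplifyVector = TRUE)
}
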