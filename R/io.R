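sidecar_path <- function(path) paste0(path, ".json")
csv_path <- function(path) paste0(path, ".csv")

#' Write a session to a CSV file with a JSON sidecar
#'
#' The session format is a delimited-text file `<path>.csv` with a
#' `time_s` column (seconds, 6 decimal places) plus one column per channel,
#' and a JSON sidecar `<path>.json` holding the exercise configuration
#' (exercise id, scored channel, units, nominal sampling rate, movement
#' minimum, directionality).
#'
#' @param signals A [raw_signal()] or a named list of them sharing
#'   timestamps.
#' @param config An [exercise_config()].
#' @param path Base path without extension.
#'
#' @return `path`, invisibly.
#' @export
write_session <- function(signals, config, path) {
  stopifnot(inherits(config, "exercise_config"))
  if (inherits(signals, "raw_signal")) {
    signals <- setNames(list(signals), signals$channel_label)
  }
  t0 <- signals[[1]]$timestamps
  df <- data.frame(time_s = sprintf("%.6f", t0), stringsAsFactors = FALSE)
  for (nm in names(signals)) {
    s <- signals[[nm]]
    if (!identical(length(s$timestamps), length(t0))) {
      stop("all channels must share the same timestamps", call. = FALSE)
    }
    df[[nm]] <- s$values
  }
  write.csv(df, csv_path(path), row.names = FALSE, quote = FALSE)
  sidecar <- list(
    exercise_id = config$exercise_id, channel_label = config$channel_label,
    units = config$units,
    sampling_rate = signals[[config$channel_label]]$sampling_rate %||%
      signals[[1]]$sampling_rate,
    movement_minimum = config$movement_minimum,
    directionality = config$directionality
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a session CSV and its JSON sidecar
#'
#' Validates the schema strictly: the sidecar must exist and name a channel
#' present in the CSV, `time_s` must be strictly increasing, and no channel
#' may contain missing values; each failure names the offending column.
#'
#' @param path Base path without extension (expects `<path>.csv` and
#'   `<path>.json`).
#'
#' @return List with `signals` (named list of [raw_signal()]) and `config`
#'   (an [exercise_config()]).
#' @export
read_session <- function(path) {
  csvf <- csv_path(path)
  scf <- sidecar_path(path)
  if (!file.exists(csvf)) stop("session file not found: ", csvf,
                               call. = FALSE)
  if (!file.exists(scf)) stop("missing sidecar: ", scf, call. = FALSE)
  sc <- jsonlite::read_json(scf, simplifyVector = TRUE)
  df <- read.csv(csvf)
  if (!"time_s" %in% names(df)) {
    stop("session CSV lacks a `time_s` column", call. = FALSE)
  }
  t <- df$time_s
  if (anyNA(t)) stop("column `time_s` contains missing values",
                     call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("column `time_s` is not strictly increasing", call. = FALSE)
  }
  channels <- setdiff(names(df), "time_s")
  if (!sc$channel_label %in% channels) {
    stop(sprintf("sidecar channel '%s' not in CSV columns (%s)",
                 sc$channel_label, paste(channels, collapse = ", ")),
         call. = FALSE)
  }
  config <- exercise_config(sc$exercise_id, sc$channel_label,
                            movement_minimum = sc$movement_minimum %||% 0,
                            directionality = sc$directionality %||% "both",
                            units = sc$units %||% "units")
  signals <- lapply(channels, function(ch) {
    v <- df[[ch]]
    if (anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("column `%s` contains missing or non-finite values", ch),
           call. = FALSE)
    }
    raw_signal(t, v, channel_label = ch,
               sampling_rate = sc$sampling_rate %||% 60,
               units = if (ch == sc$channel_label) config$units else "units")
  })
  list(signals = setNames(signals, channels), config = config)
}

#' Write a trigger log
#'
#' CSV with columns `time_s`, `paired_value`, `threshold`, `algorithm`,
#' `direction`, `buffer_rank`.
#'
#' @param triggers Trigger data frame (or a `dynamic_run`).
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_trigger_log <- function(triggers, path) {
  if (inherits(triggers, "dynamic_run")) triggers <- triggers$events
  out <- data.frame(time_s = sprintf("%.6f", triggers$time),
                    paired_value = triggers$paired_value,
                    threshold = triggers$threshold,
                    algorithm = triggers$algorithm,
                    direction = triggers$direction,
                    buffer_rank = triggers$buffer_rank,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trigger log written by [write_trigger_log()]
#'
#' @param path CSV path.
#'
#' @return Trigger data frame.
#' @export
read_trigger_log <- function(path) {
  if (!file.exists(path)) stop("trigger log not found: ", path,
                               call. = FALSE)
  df <- read.csv(path)
  trigger_events(time = df$time_s, paired_value = df$paired_value,
                 threshold = df$threshold, algorithm = df$algorithm,
                 direction = df$direction, buffer_rank = df$buffer_rank)
}

#' Write a dynamic threshold trace
#'
#' CSV with columns `time_s`, `threshold_pos`, `threshold_neg` (empty when
#' not applicable).
#'
#' @param trace Threshold data frame from [run_dynamic()].
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_threshold_trace <- function(trace, path) {
  if (inherits(trace, "dynamic_run")) trace <- trace$thresholds
  out <- data.frame(time_s = sprintf("%.6f", trace$time),
                    threshold_pos = trace$threshold_pos,
                    threshold_neg = trace$threshold_neg,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write ground-truth burst annotations
#'
#' @param annotations Annotation data frame from [generate_session()].
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort summary as JSON
#'
#' @param summaries A `cohort_summary` or named list of them (typically one
#'   per algorithm).
#' @param path Output JSON path.
#'
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summaries, path) {
  if (inherits(summaries, "cohort_summary")) {
    summaries <- list(cohort = summaries)
  }
  jsonlite::write_json(lapply(summaries, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
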