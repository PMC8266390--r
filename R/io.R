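#' Read and write behavioral event logs (TSV)
#'
#' The event-log dialect is a 3-column tab-separated file with header
#' `time_s  event  label`: times in seconds from session start (written with
#' 3 decimals), `event` drawn from the closed vocabulary
#' `session_start, session_end, cs_on, cs_off, reward_delivery,
#' foodport_entry, lever_press`, and `label` a CS, outcome or lever id
#' (empty otherwise). Unknown event kinds are rejected with the offending
#' line number.
#'
#' @param log an `event_log` tibble.
#' @param path file path.
#' @return `read_event_log()` returns an `event_log`; writers return `path`
#'   invisibly.
#' @export
write_event_log <- function(log, path) {
  out <- tibble::tibble(
    time_s = sprintf("%.3f", log$time_s),
    event = log$event,
    label = log$label
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    event = readr::col_character(),
    label = readr::col_character()
  ), na = character(), progress = FALSE)
  bad <- which(!df$event %in% event_kinds)
  if (length(bad)) {
    stop("unknown event kind '", df$event[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path, call. = FALSE)
  }
  if (is.unsorted(df$time_s)) {
    stop("event times must be non-decreasing in ", path, call. = FALSE)
  }
  df$label[is.na(df$label)] <- ""
  as_event_log(df)
}

#' Read and write two-channel photometry recordings (CSV)
#'
#' Long-format CSV with header `time_s,channel,fluorescence`; `channel` is
#' 415 or 470. Values are written with 6 significant digits, so a round trip
#' is lossless to that precision.
#'
#' @param rec a `two_channel_recording`.
#' @param path file path.
#' @param sample_rate_hz per-channel sampling rate to attach on read
#'   (inferred from the timestamps when omitted).
#' @export
write_recording <- function(rec, path) {
  out <- tibble::tibble(
    time_s = signif(rec$time_s, 6),
    channel = rec$channel,
    fluorescence = signif(rec$fluorescence, 6)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, sample_rate_hz = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    channel = readr::col_integer(),
    fluorescence = readr::col_double()
  ), progress = FALSE)
  bad <- which(!df$channel %in% c(415L, 470L))
  if (length(bad)) {
    stop("unknown channel '", df$channel[bad[1]], "' at line ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  }
  if (is.null(sample_rate_hz)) {
    t470 <- df$time_s[df$channel == 470L]
    sample_rate_hz <- if (length(t470) > 1L) {
      1 / stats::median(diff(t470))
    } else NA_real_
  }
  attr(df, "sample_rate_hz") <- sample_rate_hz
  class(df) <- c("two_channel_recording", class(df))
  df
}

#' Read and write session schedules (TSV)
#'
#' One row per trial with columns `session_kind`, `session_index`, `trial`,
#' `cs_id`, `onset_s`, `offset_s`, `outcome_id`, `reward_times_s`
#' (semicolon-joined seconds), plus `extinction_end_s` and `session_end_s`
#' carried as constant columns.
#'
#' @param schedule a `session_schedule`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  out <- tibble::tibble(
    session_kind = attr(schedule, "session_kind"),
    session_index = attr(schedule, "session_index"),
    trial = schedule$trial,
    cs_id = schedule$cs_id,
    onset_s = signif(schedule$onset_s, 6),
    offset_s = signif(schedule$offset_s, 6),
    outcome_id = schedule$outcome_id,
    reward_times_s = vapply(schedule$reward_times_s, function(x) {
      paste(signif(x, 6), collapse = ";")
    }, character(1)),
    extinction_end_s = attr(schedule, "extinction_end_s"),
    session_end_s = attr(schedule, "session_end_s")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    session_kind = readr::col_character(),
    session_index = readr::col_integer(),
    trial = readr::col_integer(),
    cs_id = readr::col_character(),
    onset_s = readr::col_double(),
    offset_s = readr::col_double(),
    outcome_id = readr::col_character(),
    reward_times_s = readr::col_character(),
    extinction_end_s = readr::col_double(),
    session_end_s = readr::col_double()
  ), na = "NA", progress = FALSE)
  kinds <- c("conditioning", "unpaired", "pit", "instrumental", "magazine")
  bad <- which(!df$session_kind %in% kinds)
  if (length(bad)) {
    stop("unknown session_kind '", df$session_kind[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path, call. = FALSE)
  }
  rewards <- lapply(df$reward_times_s, function(s) {
    if (is.na(s) || s == "") numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  new_schedule(
    list(trial = df$trial, cs_id = df$cs_id, onset_s = df$onset_s,
         offset_s = df$offset_s, outcome_id = df$outcome_id,
         reward_times_s = rewards),
    session_kind = df$session_kind[1],
    session_index = df$session_index[1],
    extinction_end_s = df$extinction_end_s[1],
    session_end_s = df$session_end_s[1]
  )
}
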