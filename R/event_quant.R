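#' Derive analysis events from a schedule and behavioral log
#'
#' Resolves the event classes the peri-event analysis aligns to:
#' CS onsets, reward deliveries, reward retrievals (the first food-port entry
#' at or after each delivery, searched up to the next delivery of the same
#' trial or the session end, so one entry cannot serve two deliveries), and
#' probe entries (food-port entries after CS onset and before that trial's
#' first delivery, or before CS offset when no reward was delivered).
#'
#' @param schedule a `session_schedule`.
#' @param log the matching `event_log`.
#' @return List of tibbles: `cs_onsets` (`cs_id`, `time_s`, `trial`),
#'   `reward_deliveries` (`time_s`, `outcome_id`, `trial`),
#'   `reward_retrievals` (`time_s`, `delivery_time_s`, `trial`),
#'   `probe_entries` (`time_s`, `trial`).
#' @examples
#' cfg <- sim_config(n_subjects = 1)
#' ct <- make_contingency(0)
#' sch <- generate_conditioning_session(cfg, ct, 1, seed = 1)
#' log <- simulate_behavior(sch, cfg, ct, seed = 2)
#' ev <- derive_events(sch, log)
#' head(ev$reward_retrievals)
#' @export
derive_events <- function(schedule, log) {
  stopifnot(inherits(schedule, "session_schedule"))
  cs_trials <- schedule[!is.na(schedule$cs_id), , drop = FALSE]
  log_on <- log[log$event == "cs_on", , drop = FALSE]
  if (nrow(log_on) != nrow(cs_trials) ||
      (nrow(cs_trials) &&
       (!isTRUE(all.equal(sort(log_on$time_s), sort(cs_trials$onset_s))) ||
        !identical(sort(log_on$label), sort(cs_trials$cs_id))))) {
    stop("cs_on markers in the log do not match the schedule", call. = FALSE)
  }
  n_off <- sum(log$event == "cs_off")
  if (n_off != nrow(log_on)) {
    stop("every cs_on must have a matching cs_off", call. = FALSE)
  }

  deliveries <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(schedule), "trial", "outcome_id",
                  "reward_times_s"),
    "reward_times_s"
  )
  deliveries <- tibble::tibble(
    time_s = deliveries$reward_times_s %||% numeric(0),
    outcome_id = deliveries$outcome_id %||% character(0),
    trial = deliveries$trial %||% integer(0)
  )

  entries <- log$time_s[log$event == "foodport_entry"]
  probe <- purrr::map_dfr(seq_len(nrow(cs_trials)), function(i) {
    first_rw <- cs_trials$reward_times_s[[i]]
    probe_end <- if (length(first_rw)) min(first_rw) else cs_trials$offset_s[i]
    hit <- entries[entries >= cs_trials$onset_s[i] & entries < probe_end]
    if (!length(hit)) return(NULL)
    tibble::tibble(time_s = hit, trial = cs_trials$trial[i])
  })
  if (!nrow(probe)) probe <- tibble::tibble(time_s = numeric(0),
                                            trial = integer(0))

  list(
    cs_onsets = tibble::tibble(cs_id = cs_trials$cs_id,
                               time_s = cs_trials$onset_s,
                               trial = cs_trials$trial),
    reward_deliveries = deliveries,
    reward_retrievals = derive_retrievals(schedule, log),
    probe_entries = probe
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align a corrected trace to event times
#'
#' Extracts one row of Z-scored dF/F per event on a fixed relative-time grid
#' spanning `[-window_pre_s, window_post_s]`, sampled at the trace's own
#' grid spacing. Events whose window extends beyond the recording are
#' dropped; the drop count is recorded in attribute `n_dropped`.
#'
#' @param trace a `corrected_trace`.
#' @param event_times numeric event times, seconds, sorted.
#' @param window_pre_s,window_post_s baseline and response window lengths,
#'   seconds (default 3 and 3).
#' @return A `peri_event_tensor`: matrix (events x samples) of zdff with
#'   attributes `relative_time_s`, `event_times`, `n_dropped`,
#'   `window_pre_s`, `window_post_s`.
#' @export
extract_peri_event <- function(trace, event_times, window_pre_s = 3,
                               window_post_s = 3) {
  stopifnot(inherits(trace, "corrected_trace"))
  if (is.unsorted(event_times)) stop("event_times must be sorted",
                                     call. = FALSE)
  dt <- stats::median(diff(trace$time_s))
  n_pre <- round(window_pre_s / dt)
  n_post <- round(window_post_s / dt)
  rel <- (-n_pre:n_post) * dt
  n_samp <- length(trace$time_s)

  rows <- list()
  kept <- numeric(0)
  dropped <- 0L
  for (t0 in event_times) {
    i0 <- which.min(abs(trace$time_s - t0))
    if (i0 - n_pre < 1L || i0 + n_post > n_samp) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- trace$zdff[(i0 - n_pre):(i0 + n_post)]
    kept <- c(kept, t0)
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), nrow = 0, ncol = length(rel))
  structure(mat,
            relative_time_s = rel,
            event_times = kept,
            n_dropped = dropped,
            window_pre_s = window_pre_s,
            window_post_s = window_post_s,
            class = c("peri_event_tensor", "matrix", "array"))
}

#' Per-trial peak and AUC from a peri-event tensor
#'
#' For each aligned event: `peak_pre` is the maximum of zdff over
#' `[-window_pre_s, 0)`, `peak_post` the maximum over `(0, window_post_s]`;
#' `auc_pre` and `auc_post` are trapezoidal integrals of zdff over
#' `[-window_pre_s, 0]` and `[0, window_post_s]` (equal window lengths, units
#' Z·s). No baseline subtraction is applied inside the windows — pre and
#' post are compared downstream.
#'
#' @param tensor a `peri_event_tensor` from [extract_peri_event()].
#' @return Tibble, one row per event: `trial`, `event_time_s`, `peak_pre`,
#'   `peak_post`, `auc_pre`, `auc_post`.
#' @export
quantify_trials <- function(tensor) {
  stopifnot(inherits(tensor, "peri_event_tensor"))
  if (nrow(tensor) == 0L) {
    stop("cannot quantify an empty peri-event tensor", call. = FALSE)
  }
  rel <- attr(tensor, "relative_time_s")
  pre_peak_cols <- which(rel < 0)
  post_peak_cols <- which(rel > 0)
  pre_auc_cols <- which(rel <= 0)
  post_auc_cols <- which(rel >= 0)
  purrr::map_dfr(seq_len(nrow(tensor)), function(i) {
    row <- tensor[i, ]
    tibble::tibble(
      trial = i,
      event_time_s = attr(tensor, "event_times")[i],
      peak_pre = max(row[pre_peak_cols]),
      peak_post = max(row[post_peak_cols]),
      auc_pre = pracma::trapz(rel[pre_auc_cols], row[pre_auc_cols]),
      auc_post = pracma::trapz(rel[post_auc_cols], row[post_auc_cols])
    )
  })
}

#' Average trial quantities within, then across, CSs
#'
#' Implements the two-stage averaging of per-trial measures: mean within each
#' CS, then the unweighted mean of the per-CS means, so unequal trial counts
#' do not bias the session summary toward either stimulus.
#'
#' @param quant tibble of per-trial values with a `cs_id` column and one or
#'   more numeric measure columns.
#' @param measures character vector of measure column names (default: all
#'   numeric columns except `trial` and `event_time_s`).
#' @return One-row tibble of CS-averaged measures.
#' @export
average_trials <- function(quant, measures = NULL) {
  stopifnot("cs_id" %in% names(quant))
  if (is.null(measures)) {
    measures <- setdiff(names(quant)[vapply(quant, is.numeric, logical(1))],
                        c("trial", "event_time_s"))
  }
  usable <- quant[!is.na(quant$cs_id), , drop = FALSE]
  if (!nrow(usable)) stop("no usable trials to average", call. = FALSE)
  per_cs <- dplyr::summarise(
    dplyr::group_by(usable, .data$cs_id),
    dplyr::across(dplyr::all_of(measures), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  dplyr::summarise(per_cs,
                   dplyr::across(dplyr::all_of(measures), mean))
}

#' Bin per-session summaries into conditioning phases
#'
#' Training sessions 1..8 are binned into the five phases `1`, `2`, `3/4`,
#' `5/6`, `7/8` (single early sessions, then two-session bins). Within each
#' bin the subject's available sessions are averaged. Subjects lacking a
#' usable session in any bin are excluded and listed in the `excluded`
#' attribute (with a message).
#'
#' @param sessions tibble with columns `subject`, `session` (1..8) and
#'   numeric measure columns; QC-failed sessions should already have been
#'   removed.
#' @param measures measure columns to aggregate (default: all numeric except
#'   `subject`, `session`).
#' @return Tibble with `subject`, `bin` (ordered factor) and binned means;
#'   attributes `included` and `excluded` list subject ids.
#' @export
bin_sessions <- function(sessions, measures = NULL) {
  stopifnot(all(c("subject", "session") %in% names(sessions)))
  if (is.null(measures)) {
    measures <- setdiff(
      names(sessions)[vapply(sessions, is.numeric, logical(1))],
      c("subject", "session")
    )
  }
  bin_levels <- c("1", "2", "3/4", "5/6", "7/8")
  bin_of <- function(s) {
    dplyr::case_when(
      s == 1 ~ "1", s == 2 ~ "2",
      s %in% c(3, 4) ~ "3/4", s %in% c(5, 6) ~ "5/6",
      s %in% c(7, 8) ~ "7/8",
      TRUE ~ NA_character_
    )
  }
  df <- dplyr::mutate(sessions, bin = factor(bin_of(.data$session),
                                             levels = bin_levels))
  if (anyNA(df$bin)) stop("sessions must be labeled 1..8", call. = FALSE)
  binned <- dplyr::summarise(
    dplyr::group_by(df, .data$subject, .data$bin),
    dplyr::across(dplyr::all_of(measures), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  complete <- dplyr::summarise(dplyr::group_by(binned, .data$subject),
                               n_bins = dplyr::n_distinct(.data$bin),
                               .groups = "drop")
  included <- complete$subject[complete$n_bins == length(bin_levels)]
  excluded <- setdiff(unique(sessions$subject), included)
  if (length(excluded)) {
    rlang::inform(paste0("bin_sessions: excluded subject(s) without data in ",
                         "every bin: ", paste(excluded, collapse = ", ")))
  }
  out <- binned[binned$subject %in% included, , drop = FALSE]
  attr(out, "included") <- included
  attr(out, "excluded") <- excluded
  out
}

#' Peri-event quantification of one photometry session
#'
#' Aligns a corrected trace to CS onsets and reward retrievals and returns
#' trial-level peak/AUC tables plus the CS-averaged session summary for each
#' event class.
#'
#' @param trace a `corrected_trace`.
#' @param schedule,log the session schedule and event log.
#' @param window_pre_s,window_post_s peri-event windows, seconds.
#' @return List: `trials` (tibble with `event_kind`, `cs_id`, per-trial
#'   measures) and `summary` (tibble with one row per event class of
#'   CS-averaged measures).
#' @export
quantify_session <- function(trace, schedule, log, window_pre_s = 3,
                             window_post_s = 3) {
  ev <- derive_events(schedule, log)
  quant_one <- function(times, kind, cs_ids) {
    if (!length(times)) return(NULL)
    ord <- order(times)
    tensor <- extract_peri_event(trace, times[ord], window_pre_s,
                                 window_post_s)
    if (nrow(tensor) == 0L) return(NULL)
    kept <- attr(tensor, "event_times")
    q <- quantify_trials(tensor)
    q$cs_id <- cs_ids[ord][match(kept, times[ord])]
    q$event_kind <- kind
    q
  }
  cs_trials <- ev$cs_onsets
  retr <- ev$reward_retrievals
  retr_cs <- if (nrow(retr)) {
    schedule$cs_id[match(retr$trial, schedule$trial)]
  } else character(0)
  trials <- dplyr::bind_rows(
    quant_one(cs_trials$time_s, "cs_onset", cs_trials$cs_id),
    quant_one(retr$time_s, "reward_retrieval", retr_cs)
  )
  if (is.null(trials) || !nrow(trials)) {
    return(list(trials = tibble::tibble(), summary = tibble::tibble()))
  }
  summary <- purrr::map_dfr(split(trials, trials$event_kind), function(df) {
    out <- average_trials(df)
    out$event_kind <- df$event_kind[1]
    out
  })
  list(trials = trials, summary = summary)
}
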