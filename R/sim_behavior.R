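event_kinds <- c("session_start", "session_end", "cs_on", "cs_off",
                 "reward_delivery", "foodport_entry", "lever_press")

as_event_log <- function(df) {
  out <- tibble::as_tibble(df)
  stopifnot(all(c("time_s", "event", "label") %in% names(out)))
  bad <- setdiff(unique(out$event), event_kinds)
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out$label[is.na(out$label)] <- ""
  out <- dplyr::arrange(out, .data$time_s,
                        match(.data$event, event_kinds))
  class(out) <- c("event_log", class(out))
  out
}

# Piecewise-constant inhomogeneous Poisson process over parallel segment
# vectors; returns sorted arrival times.
piecewise_arrivals <- function(from_s, to_s, rate_per_s) {
  lens <- pmax(to_s - from_s, 0)
  n <- stats::rpois(length(from_s), rate_per_s * lens)
  sort(stats::runif(sum(n), rep(from_s, n), rep(to_s, n)))
}

# Split [0, end] into CS and non-CS segments with the given rate multipliers.
cs_segments <- function(schedule, end_s, base_rate_per_s, cs_mult) {
  on <- schedule$onset_s[!is.na(schedule$cs_id)]
  off <- schedule$offset_s[!is.na(schedule$cs_id)]
  bounds <- sort(unique(c(0, on, off, end_s)))
  from <- bounds[-length(bounds)]
  to <- bounds[-1]
  in_cs <- vapply(from, function(t) any(t >= on & t < off), logical(1))
  list(from_s = from, to_s = to,
       rate_per_s = base_rate_per_s * ifelse(in_cs, cs_mult, 1))
}

#' Simulate behavioral events for a session schedule
#'
#' Generates the timestamped behavioral event stream that a conditioning
#' chamber would log for a given session: CS on/off markers and reward
#' deliveries from the schedule, food-port entries as an inhomogeneous
#' arrival process, a retrieval entry after each reward delivery, and, for
#' PIT sessions, lever presses on both levers.
#'
#' The generative model of behavior: food-port entries occur at
#' `entry_rate_base_per_min` outside CSs; inside a CS the rate is multiplied
#' by `1 + entry_gain_per_session * session_index`, producing a conditional
#' approach response that grows over training. Each reward delivery is
#' followed by one retrieval entry at an exponential latency (mean
#' `retrieval_latency_mean_s`), skipped if the latency would run past the CS
#' offset. In PIT sessions each lever is pressed at
#' `press_rate_base_per_min`, multiplied during a CS by `1 + tau_same` on the
#' lever whose training outcome matches the presented CS and `1 + tau_diff`
#' on the other lever; PIT entry rates use the fully-trained CS multiplier
#' (`session_index = n_conditioning_sessions`).
#'
#' @param schedule a `session_schedule`.
#' @param config a [sim_config()].
#' @param contingency a [make_contingency()] assignment (required for PIT
#'   lever pressing; optional for reward-only sessions).
#' @param seed optional integer seed.
#' @return An `event_log` tibble with columns `time_s`, `event`, `label`.
#' @export
simulate_behavior <- function(schedule, config, contingency = NULL,
                              seed = NULL) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(config, "sim_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  kind <- attr(schedule, "session_kind")
  session_index <- attr(schedule, "session_index")
  end_s <- attr(schedule, "session_end_s")

  cs_trials <- schedule[!is.na(schedule$cs_id), , drop = FALSE]
  if (nrow(cs_trials) && kind %in% c("conditioning", "unpaired", "pit")) {
    if (is.null(contingency)) {
      stop("a contingency is required for CS sessions", call. = FALSE)
    }
    check_contingency(contingency)
    unmapped <- setdiff(unique(cs_trials$cs_id),
                        names(contingency$cs_to_outcome))
    if (length(unmapped)) {
      stop("schedule/contingency mismatch: no outcome mapped for CS ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
  }

  markers <- dplyr::bind_rows(
    tibble::tibble(time_s = 0, event = "session_start", label = ""),
    if (nrow(cs_trials)) tibble::tibble(time_s = cs_trials$onset_s,
                                        event = "cs_on",
                                        label = cs_trials$cs_id),
    if (nrow(cs_trials)) tibble::tibble(time_s = cs_trials$offset_s,
                                        event = "cs_off",
                                        label = cs_trials$cs_id),
    tibble::tibble(time_s = end_s, event = "session_end", label = "")
  )

  n_rw <- lengths(schedule$reward_times_s)
  deliveries <- tibble::tibble(
    trial = rep(schedule$trial, n_rw),
    outcome_id = rep(schedule$outcome_id, n_rw),
    reward_times_s = unlist(schedule$reward_times_s, use.names = FALSE) %||%
      numeric(0)
  )
  delivery_events <- tibble::tibble(
    time_s = deliveries$reward_times_s,
    event = "reward_delivery",
    label = deliveries$outcome_id
  )

  # baseline + CS-elevated food-port entries
  entry_mult_session <- if (kind == "pit") config$n_conditioning_sessions
                        else session_index
  entry_mult <- 1 + config$entry_gain_per_session * entry_mult_session
  entry_segments <- cs_segments(schedule, end_s,
                                config$entry_rate_base_per_min / 60,
                                entry_mult)
  entries <- piecewise_arrivals(entry_segments$from_s, entry_segments$to_s,
                                entry_segments$rate_per_s)

  # one retrieval entry per delivery, unless the CS (or reward period) ended;
  # a subject that never approaches the port (base rate 0) retrieves nothing
  if (nrow(deliveries) && config$entry_rate_base_per_min > 0) {
    trial_offset <- schedule$offset_s[match(deliveries$trial, schedule$trial)]
    lat <- stats::rexp(nrow(deliveries),
                       rate = 1 / max(config$retrieval_latency_mean_s, 1e-12))
    retrieval <- deliveries$reward_times_s + lat
    retrieval <- retrieval[retrieval <= trial_offset]
    entries <- sort(c(entries, retrieval))
  }
  entry_events <- tibble::tibble(time_s = entries, event = "foodport_entry",
                                 label = "")

  press_events <- NULL
  if (kind == "pit") {
    press_events <- purrr::map_dfr(c("left", "right"), function(lever) {
      mult_per_trial <- vapply(cs_trials$cs_id, function(cs) {
        if (identical(classify_same_lever(cs, contingency), lever)) {
          1 + config$tau_same
        } else {
          1 + config$tau_diff
        }
      }, numeric(1))
      # piecewise rate: baseline everywhere, trial-specific multiplier in CS
      bounds <- sort(unique(c(0, cs_trials$onset_s, cs_trials$offset_s,
                              end_s)))
      from <- bounds[-length(bounds)]
      to <- bounds[-1]
      mult <- vapply(from, function(t) {
        hit <- which(t >= cs_trials$onset_s & t < cs_trials$offset_s)
        if (length(hit)) mult_per_trial[hit[1]] else 1
      }, numeric(1))
      tibble::tibble(
        time_s = piecewise_arrivals(from, to,
                                    config$press_rate_base_per_min / 60 *
                                      mult),
        event = "lever_press", label = lever)
    })
  }

  as_event_log(dplyr::bind_rows(markers, delivery_events, entry_events,
                                press_events))
}
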